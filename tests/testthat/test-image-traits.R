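make_vol <- function(values, dims = c(8, 8, 8), ...) {
  volume_image(array(values, dims), ...)
}

test_that("MTR map follows the saturation-ratio formula", {
  m0 <- make_vol(2); ms <- make_vol(1)
  expect_equal(unique(as.vector(compute_mtr_map(m0, ms))), 50)
  same <- make_vol(7)
  expect_equal(unique(as.vector(compute_mtr_map(same, same))), 0)
})

test_that("zero or negative M0 maps to missing, not an error", {
  m0 <- make_vol(2); ms <- make_vol(1)
  m0[1, 1, 1] <- 0
  m0[2, 1, 1] <- -5
  mtr <- compute_mtr_map(m0, ms)
  expect_true(is.na(mtr[1, 1, 1]))
  expect_true(is.na(mtr[2, 1, 1]))
  expect_equal(mtr[3, 1, 1], 50)
})

test_that("misaligned inputs are rejected", {
  expect_error(compute_mtr_map(make_vol(2, c(8, 8, 8)), make_vol(1, c(8, 8, 9))),
               "not aligned")
  expect_error(compute_mtr_map(make_vol(2, voxel_size = c(1, 1, 1)),
                               make_vol(1, voxel_size = c(2, 2, 2))),
               "voxel sizes")
  expect_error(compute_mtr_map(make_vol(2, space = "native"),
                               make_vol(1, space = "mni")),
               "space tags")
})

test_that("MTR is invariant under joint positive rescaling of the pair", {
  set.seed(1)
  m0 <- make_vol(runif(512, 1, 3))
  ms <- make_vol(runif(512, 0.2, 1))
  base <- compute_mtr_map(m0, ms)
  for (alpha in c(0.5, 3, 1e4)) {
    scaled <- compute_mtr_map(make_vol(alpha * as.vector(m0)),
                              make_vol(alpha * as.vector(ms)))
    expect_equal(as.vector(scaled), as.vector(base), tolerance = 1e-12)
  }
})

test_that("normal-appearing masks subtract the kappa-0 lesion mask", {
  dims <- c(8, 8, 8)
  hard <- array(sample(0:3, prod(dims), replace = TRUE), dims)
  none <- array(FALSE, dims)
  m <- derive_normal_appearing_masks(hard, none)
  expect_equal(m$nagm, hard == 1)
  expect_equal(m$nawm, hard == 2)

  all_wm <- hard == 2
  m2 <- derive_normal_appearing_masks(hard, all_wm)
  expect_false(any(m2$nawm))
  expect_equal(m2$nagm, hard == 1)
})

test_that("random masks verify the disjointness identities voxel-wise", {
  set.seed(4)
  dims <- c(16, 16, 16)
  hard <- array(sample(0:3, prod(dims), replace = TRUE), dims)
  lesion <- array(runif(prod(dims)) < 0.2, dims)
  m <- derive_normal_appearing_masks(hard, lesion)
  # brute-force voxel enumeration of the set identities
  for (i in which(lesion)) {
    expect_false(m$nagm[i])
    expect_false(m$nawm[i])
  }
  expect_equal(sum(m$nagm), sum(hard == 1 & !lesion))
  expect_equal(sum(m$nawm), sum(hard == 2 & !lesion))
  expect_error(derive_normal_appearing_masks(array(9L, dims), lesion),
               "unknown segmentation labels")
})

test_that("constant histograms collapse to the constant", {
  mtr <- make_vol(38.2)
  mask <- array(TRUE, c(8, 8, 8))
  s <- summarize_mtr_histogram(mtr, mask, bin_width = 1)
  expect_equal(s$median, 38.2)
  expect_equal(s$mean90, 38.2)
  expect_equal(s$peak_height, 100)
  expect_equal(s$peak_location, 38.5)
  expect_equal(s$n_voxels, 512)
})

test_that("five-point histogram matches the explicit percentile oracle", {
  vals <- c(10, 20, 30, 40, 50)
  mtr <- volume_image(array(c(vals, rep(NA, 3)), c(2, 2, 2)))
  mask <- array(c(rep(TRUE, 5), rep(FALSE, 3)), c(2, 2, 2))
  s <- summarize_mtr_histogram(mtr, mask, bin_width = 10)
  expect_equal(s$median, 30)
  expect_equal(s$mean90, oracle_mean90(vals))
  expect_equal(s$n_voxels, 5)
  # each value falls in its own bin; ties broken towards the lowest bin
  expect_equal(s$peak_height, 20)
  expect_equal(s$peak_location, 15)
})

test_that("large normal sample recovers mode and median within tolerance", {
  set.seed(6)
  n <- 1e5
  x <- rnorm(n, 38, 2)
  dims <- c(50, 50, 40)
  mtr <- volume_image(array(x, dims))
  mask <- array(TRUE, dims)
  s <- summarize_mtr_histogram(mtr, mask, bin_width = 1)
  expect_true(s$peak_location %in% c(37.5, 38.5))
  expect_equal(s$median, oracle_percentile(x[x >= 0 & x <= 100], 0.5),
               tolerance = 1e-12)
  expect_equal(s$median, 38, tolerance = 0.05)
  expect_equal(s$mean90, oracle_mean90(x[x >= 0 & x <= 100]),
               tolerance = 1e-12)
})

test_that("histogram summary ignores voxel ordering and is shift-monotone", {
  set.seed(7)
  vals <- rnorm(4096, 35, 3)
  dims <- c(16, 16, 16)
  s1 <- summarize_mtr_histogram(volume_image(array(vals, dims)),
                                array(TRUE, dims))
  s2 <- summarize_mtr_histogram(volume_image(array(sample(vals), dims)),
                                array(TRUE, dims))
  expect_equal(s1[c("median", "peak_height", "peak_location", "mean90")],
               s2[c("median", "peak_height", "peak_location", "mean90")])
  s3 <- summarize_mtr_histogram(volume_image(array(vals + 5, dims)),
                                array(TRUE, dims))
  expect_equal(s3$median, s1$median + 5, tolerance = 1e-9)
  expect_equal(s3$mean90, s1$mean90 + 5, tolerance = 1e-9)
})

test_that("out-of-range voxels are excluded and empty classes flagged", {
  dims <- c(8, 8, 8)
  vals <- rep(40, prod(dims)); vals[1:10] <- -5; vals[11:20] <- 130
  s <- summarize_mtr_histogram(volume_image(array(vals, dims)),
                               array(TRUE, dims))
  expect_equal(s$n_voxels, prod(dims) - 20)
  empty <- summarize_mtr_histogram(volume_image(array(-1, dims)),
                                   array(TRUE, dims))
  expect_true(empty$missing)
  expect_equal(empty$n_voxels, 0L)
  expect_true(is.na(empty$median))
})

test_that("volumetrics follow the soft-segmentation sum rule", {
  dims <- c(10, 10, 10)
  ones <- array(1, dims); zeros <- array(0, dims)
  v <- compute_volumetrics(list(gm = ones, wm = zeros, csf = zeros),
                           array(FALSE, dims), voxel_size = c(1, 1, 1))
  expect_equal(v$gm_volume, 1)       # 1000 voxels of 1 mm^3 = 1 ml
  expect_equal(v$total_brain_volume, 1)
  expect_equal(v$gm_pct, 100)
  third <- array(1 / 3, dims)
  v2 <- compute_volumetrics(list(gm = third, wm = third, csf = third),
                            array(FALSE, dims))
  expect_equal(v2$gm_pct, 100 / 3)
  expect_equal(v2$wm_pct, 100 / 3)
})

test_that("random soft segmentation matches voxel-by-voxel summation", {
  set.seed(8)
  dims <- c(16, 16, 16)
  raw <- matrix(runif(3 * prod(dims)), nrow = 3)
  probs <- sweep(raw, 2, colSums(raw), "/")
  seg <- list(gm = array(probs[1, ], dims), wm = array(probs[2, ], dims),
              csf = array(probs[3, ], dims))
  lesion <- array(runif(prod(dims)) < 0.1, dims)
  vox <- c(0.9, 0.9, 3)
  v <- compute_volumetrics(seg, lesion, vox)
  # brute-force summation oracle
  vol_ml <- prod(vox) / 1000
  gm_o <- 0
  for (i in seq_len(prod(dims))) gm_o <- gm_o + seg$gm[i] * vol_ml
  expect_equal(v$gm_volume, gm_o, tolerance = 1e-12)
  expect_equal(v$lesion_volume, sum(lesion) * vol_ml, tolerance = 1e-12)
  expect_equal(v$total_brain_volume, v$gm_volume + v$wm_volume + v$csf_volume)
  expect_equal(v$gm_pct + v$wm_pct + v$csf_pct, 100, tolerance = 1e-9)
  bad <- seg; bad$gm[1] <- 1.5
  expect_error(compute_volumetrics(bad, lesion, vox), "\\[0, 1\\]")
})

test_that("noise-free scan round trip recovers the latent medians", {
  cfg <- cohort_config(image_shape = c(16, 16, 16))
  set.seed(9)
  img <- simulate_scan_images(c(lesion = 30, nawm = 38, nagm = 32), cfg,
                              noise_sd = 0)
  tr <- extract_scan_traits(img$m0, img$ms, img$hard_seg, img$soft_seg,
                            img$lesion_mask,
                            metadata = list(patient_id = "P001",
                                            days_since_first = 0,
                                            protocol = "prot1"))
  expect_equal(tr$mtr_median_lesion, 30)
  expect_equal(tr$mtr_median_nawm, 38)
  expect_equal(tr$mtr_median_nagm, 32)
  expect_equal(tr$patient_id, "P001")
})

test_that("empty lesion class yields missing MTR traits and zero volume", {
  cfg <- cohort_config(image_shape = c(16, 16, 16))
  set.seed(10)
  img <- simulate_scan_images(c(lesion = 30, nawm = 38, nagm = 32), cfg,
                              noise_sd = 0, n_lesions = 0)
  tr <- extract_scan_traits(img$m0, img$ms, img$hard_seg, img$soft_seg,
                            img$lesion_mask)
  expect_true(is.na(tr$mtr_median_lesion))
  expect_true(is.na(tr$mtr_peakh_lesion))
  expect_equal(tr$lesion_volume, 0)
  expect_false(is.na(tr$mtr_median_nawm))
})

test_that("full trait row equals the component oracles", {
  cfg <- cohort_config(image_shape = c(16, 16, 16))
  set.seed(11)
  img <- simulate_scan_images(c(lesion = 28, nawm = 39, nagm = 33), cfg,
                              noise_sd = 1)
  tr <- extract_scan_traits(img$m0, img$ms, img$hard_seg, img$soft_seg,
                            img$lesion_mask)
  mtr <- compute_mtr_map(img$m0, img$ms)
  masks <- derive_normal_appearing_masks(img$hard_seg, img$lesion_mask)
  for (tis in c("lesion", "nawm", "nagm")) {
    mask <- switch(tis, lesion = masks$lesion, nawm = masks$nawm,
                   nagm = masks$nagm)
    x <- as.vector(mtr)[as.vector(mask)]
    x <- x[is.finite(x) & x >= 0 & x <= 100]
    expect_equal(tr[[paste0("mtr_median_", tis)]], oracle_percentile(x, 0.5),
                 tolerance = 1e-12)
    expect_equal(tr[[paste0("mtr_mean90_", tis)]], oracle_mean90(x),
                 tolerance = 1e-12)
  }
  vol <- compute_volumetrics(img$soft_seg, img$lesion_mask, img$voxel_size)
  expect_equal(tr$total_brain_volume, vol$total_brain_volume)
  expect_equal(tr$wm_pct, vol$wm_pct)
  expect_equal(tr$lesion_volume, vol$lesion_volume)
})

test_that("histogram intercorrelation diagnostic returns the 4x4 matrix", {
  cfg <- cohort_config(image_shape = c(16, 16, 16))
  set.seed(12)
  rows <- lapply(1:6, function(i) {
    img <- simulate_scan_images(c(lesion = 30, nawm = 36 + i * 0.5,
                                  nagm = 32), cfg, noise_sd = 1)
    extract_scan_traits(img$m0, img$ms, img$hard_seg, img$soft_seg,
                        img$lesion_mask)
  })
  cm <- histogram_intercorrelation(do.call(rbind, rows), "nawm")
  expect_equal(dim(cm), c(4, 4))
  expect_equal(diag(cm), rep(1, 4), ignore_attr = TRUE)
  # median and mean90 summarize the same distribution: strongly correlated
  expect_gt(cm["mtr_median_nawm", "mtr_mean90_nawm"], 0.9)
})

test_that("scan image writer emits a readable NIfTI set", {
  cfg <- cohort_config(image_shape = c(8, 8, 8))
  set.seed(14)
  img <- simulate_scan_images(c(lesion = 30, nawm = 38, nagm = 32), cfg,
                              noise_sd = 0, n_lesions = 1)
  dir <- withr::local_tempdir()
  paths <- write_scan_images(img, dir, prefix = "s1")
  expect_length(paths, 7)
  expect_true(all(file.exists(paths)))
  m0_back <- read_volume(paths[["m0"]])
  expect_equal(as.vector(m0_back), as.vector(img$m0), tolerance = 1e-6)
  soft_gm <- read_volume(paths[["soft_gm"]])
  expect_true(all(as.vector(soft_gm) %in% c(0, 1)))
})

test_that("NIfTI round trip preserves data and voxel size", {
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  set.seed(13)
  img <- volume_image(array(rnorm(8^3), c(8, 8, 8)), voxel_size = c(1, 1.5, 2))
  write_volume(img, tmp)
  back <- read_volume(tmp)
  expect_equal(as.vector(back), as.vector(img), tolerance = 1e-6)
  expect_equal(attr(back, "voxel_size"), c(1, 1.5, 2), tolerance = 1e-6)
})
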
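# Per-scan MTR and volumetric trait extraction.
#
# Images are plain 3-D numeric arrays wrapped as `volume_image` objects that
# carry voxel dimensions (mm) and a space tag asserting co-registration; no
# resampling is ever performed, all inputs are assumed voxel-aligned.

#' Create a volume image
#'
#' A `volume_image` is a 3-D scalar grid with voxel dimensions in mm and a
#' space tag asserting co-registration with other volumes of the same scan.
#'
#' @param data numeric 3-D array (NA allowed where masked out).
#' @param voxel_size numeric length-3, mm per axis; all components > 0.
#' @param space character tag; volumes combined voxel-wise must share it.
#' @return object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_size = c(1, 1, 1), space = "aligned") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive values (mm)")
  structure(data, voxel_size = voxel_size, space = as.character(space)[1],
            class = c("volume_image", "array"))
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("volume_image: %s voxels, %s mm, space '%s'\n",
              paste(dim(x), collapse = " x "),
              paste(signif(attr(x, "voxel_size"), 4), collapse = " x "),
              attr(x, "space")))
  invisible(x)
}

voxel_size_of <- function(x, default = c(1, 1, 1)) {
  attr(x, "voxel_size") %||% default
}

check_same_grid <- function(a, b, what = c("volumes")) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s are not aligned: shapes %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  va <- attr(a, "voxel_size"); vb <- attr(b, "voxel_size")
  if (!is.null(va) && !is.null(vb) && !isTRUE(all.equal(va, vb)))
    stop(sprintf("%s have different voxel sizes", what))
  sa <- attr(a, "space"); sb <- attr(b, "space")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb))
    stop(sprintf("%s carry different space tags ('%s' vs '%s'); co-register first",
                 what, sa, sb))
  invisible(TRUE)
}

#' Compute an MTR map from an MT-off / MT-on image pair
#'
#' The magnetization transfer ratio at each voxel is
#' `MTR = 100 * (M0 - Ms) / M0`, where `M0` and `Ms` are the signal
#' intensities without and with the off-resonance saturation pulse.
#' Voxels with `M0 <= 0` (no signal) are set to `NA` rather than raising.
#'
#' @param m0 volume without saturation pulse (`volume_image` or 3-D array).
#' @param ms volume with saturation pulse, same grid and space.
#' @return `volume_image` of MTR values in percent units.
#' @examples
#' m0 <- volume_image(array(2, c(8, 8, 8)))
#' ms <- volume_image(array(1, c(8, 8, 8)))
#' range(compute_mtr_map(m0, ms))  # 50 everywhere
#' @export
compute_mtr_map <- function(m0, ms) {
  check_same_grid(m0, ms, "M0 and Ms")
  mtr <- 100 * (unclass(m0) - unclass(ms)) / unclass(m0)
  mtr[!is.na(m0) & m0 <= 0] <- NA_real_
  volume_image(array(mtr, dim(m0)), voxel_size_of(m0),
               attr(m0, "space") %||% "aligned")
}

# hard segmentation label coding used throughout
SEG_LABELS <- c(background = 0L, gm = 1L, wm = 2L, csf = 3L)

#' Derive normal-appearing tissue masks
#'
#' Normal-appearing grey matter (NAGM) and white matter (NAWM) are the grey
#' and white matter voxels of the hard segmentation that do not belong to
#' the most sensitive (kappa = 0) lesion segmentation. The lesion class
#' analysed downstream uses the specific (kappa = 1) lesion mask, which is
#' passed through unchanged.
#'
#' @param hard_seg integer label grid: 0 background, 1 GM, 2 WM, 3 CSF.
#' @param lesion_kappa0 logical grid, the sensitive lesion segmentation.
#' @param lesion_kappa1 logical grid, the specific lesion segmentation used
#'   as the analysis lesion class; defaults to `lesion_kappa0`.
#' @return list of class `tissue_masks` with logical grids `nagm`, `nawm`,
#'   `lesion` (pairwise disjoint from the kappa-0 mask by construction).
#' @export
derive_normal_appearing_masks <- function(hard_seg, lesion_kappa0,
                                          lesion_kappa1 = lesion_kappa0) {
  if (!identical(dim(hard_seg), dim(lesion_kappa0)))
    stop("hard segmentation and lesion mask shapes differ")
  labs <- unique(as.vector(unclass(hard_seg)))
  labs <- labs[!is.na(labs)]
  if (!all(labs %in% SEG_LABELS))
    stop(sprintf("unknown segmentation labels: %s; expected %s",
                 paste(setdiff(labs, SEG_LABELS), collapse = ", "),
                 paste(sprintf("%d (%s)", SEG_LABELS, names(SEG_LABELS)),
                       collapse = ", ")))
  k0 <- as.logical(lesion_kappa0)
  k0[is.na(k0)] <- FALSE
  nagm <- (unclass(hard_seg) == SEG_LABELS[["gm"]]) & !k0
  nawm <- (unclass(hard_seg) == SEG_LABELS[["wm"]]) & !k0
  lesion <- array(as.logical(lesion_kappa1), dim(hard_seg))
  lesion[is.na(lesion)] <- FALSE
  structure(list(nagm = array(nagm, dim(hard_seg)),
                 nawm = array(nawm, dim(hard_seg)),
                 lesion = lesion),
            class = "tissue_masks")
}

#' Summarize the MTR histogram of a tissue class
#'
#' Voxels under `mask` with finite MTR inside `valid_range` are binned at
#' `bin_width` and summarized by the four standard histogram parameters:
#' median, peak height (modal-bin count as percent of included voxels,
#' "unit percent"), peak location (modal bin center; ties broken towards
#' the lowest bin), and mean90 (mean of the values between the 5th and 95th
#' percentiles, boundaries included). Percentiles use the linear
#' interpolation convention. Voxels outside `valid_range` — noise can push
#' recomputed MTR below 0 or above 100 — are excluded, and the peak-height
#' denominator is the count after this filtering.
#'
#' @param mtr MTR `volume_image` (or array), percent units.
#' @param mask logical grid selecting the tissue class.
#' @param bin_width histogram bin width in MTR units (default 1).
#' @param valid_range MTR values retained for summarisation.
#' @return list of class `mtr_histogram_summary` with `median`,
#'   `peak_height`, `peak_location`, `mean90`, `n_voxels`, `missing`. When
#'   no voxel survives filtering the summary is returned with all
#'   statistics `NA` and `missing = TRUE` (a flagged missing trait, not an
#'   error).
#' @export
summarize_mtr_histogram <- function(mtr, mask, bin_width = 1,
                                    valid_range = c(0, 100)) {
  if (!identical(dim(mtr), dim(mask)))
    stop("MTR map and mask shapes differ")
  stopifnot(bin_width > 0, length(valid_range) == 2, valid_range[1] < valid_range[2])
  msk <- as.logical(mask)
  msk[is.na(msk)] <- FALSE
  x <- as.vector(unclass(mtr))[as.vector(msk)]
  x <- x[is.finite(x) & x >= valid_range[1] & x <= valid_range[2]]
  if (length(x) == 0L)
    return(structure(list(median = NA_real_, peak_height = NA_real_,
                          peak_location = NA_real_, mean90 = NA_real_,
                          n_voxels = 0L, missing = TRUE),
                     class = "mtr_histogram_summary"))
  nbins <- ceiling((valid_range[2] - valid_range[1]) / bin_width)
  breaks <- valid_range[1] + (0:nbins) * bin_width
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)  # top edge inclusive
  counts <- tabulate(idx, nbins = nbins)
  modal <- which.max(counts)  # first max: lowest bin wins ties
  p <- quantile(x, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  structure(list(
    median = p[2],
    peak_height = 100 * counts[modal] / length(x),
    peak_location = breaks[modal] + bin_width / 2,
    mean90 = mean(x[x >= p[1] & x <= p[3]]),
    n_voxels = length(x),
    missing = FALSE
  ), class = "mtr_histogram_summary")
}

#' @export
print.mtr_histogram_summary <- function(x, ...) {
  if (x$missing) cat("MTR histogram summary: empty tissue class (missing trait)\n")
  else cat(sprintf(paste0("MTR histogram summary (n = %d voxels): median %.2f, ",
                          "peak height %.2f%%, peak location %.2f, mean90 %.2f\n"),
                   x$n_voxels, x$median, x$peak_height, x$peak_location, x$mean90))
  invisible(x)
}

#' Compute volumetric traits from a soft segmentation
#'
#' Each tissue volume is the sum of its soft-segmentation probabilities
#' multiplied by the voxel volume; total brain volume is the sum of the GM,
#' WM and CSF compartments, and WM/GM volumes are also expressed as a
#' percentage of total brain volume. Lesion volume is the voxel count of
#' the binary lesion mask times the voxel volume.
#'
#' @param soft_seg list with numeric grids `gm`, `wm`, `csf` of per-voxel
#'   tissue probabilities in \[0, 1\].
#' @param lesion_mask logical grid.
#' @param voxel_size mm per axis (length 3).
#' @return list of class `volumetric_summary`: `gm_volume`, `wm_volume`,
#'   `csf_volume`, `total_brain_volume`, `lesion_volume` (ml), `gm_pct`,
#'   `wm_pct`, `csf_pct` (percent of total brain volume).
#' @export
compute_volumetrics <- function(soft_seg, lesion_mask, voxel_size = c(1, 1, 1)) {
  stopifnot(all(c("gm", "wm", "csf") %in% names(soft_seg)))
  vox_ml <- prod(voxel_size) / 1000  # mm^3 -> ml
  vols <- vapply(soft_seg[c("gm", "wm", "csf")], function(p) {
    p <- as.vector(unclass(p))
    if (any(!is.na(p) & (p < -1e-9 | p > 1 + 1e-9)))
      stop("soft segmentation probabilities must lie in [0, 1]")
    sum(p, na.rm = TRUE) * vox_ml
  }, numeric(1))
  total <- sum(vols)
  lesion <- sum(as.logical(lesion_mask), na.rm = TRUE) * vox_ml
  structure(list(
    gm_volume = vols[["gm"]], wm_volume = vols[["wm"]], csf_volume = vols[["csf"]],
    total_brain_volume = total, lesion_volume = lesion,
    gm_pct = if (total > 0) 100 * vols[["gm"]] / total else NA_real_,
    wm_pct = if (total > 0) 100 * vols[["wm"]] / total else NA_real_,
    csf_pct = if (total > 0) 100 * vols[["csf"]] / total else NA_real_
  ), class = "volumetric_summary")
}

#' Names of the 10 analysed MRI traits
#'
#' Median and peak-height MTR in lesions, NAWM and NAGM, plus total brain
#' volume, white- and grey-matter percentage of total brain volume, and
#' lesion volume.
#'
#' @return character vector of length 10 (the stable ScanTraits schema).
#' @export
trait_names <- function() {
  c("mtr_median_lesion", "mtr_median_nawm", "mtr_median_nagm",
    "mtr_peakh_lesion", "mtr_peakh_nawm", "mtr_peakh_nagm",
    "total_brain_volume", "wm_pct", "gm_pct", "lesion_volume")
}

#' Extract the full trait vector for one scan
#'
#' Composes MTR-map computation, normal-appearing mask derivation, per-tissue
#' histogram summarisation and volumetrics into the 10-trait row analysed
#' downstream. The lesion MTR class uses the specific (kappa = 1) lesion
#' mask; NAGM/NAWM exclude the sensitive (kappa = 0) mask. Supplementary
#' histogram parameters (mean90, peak location) are emitted alongside the
#' 10 analysed traits. Empty tissue classes yield `NA` MTR traits and are
#' flagged, not errors.
#'
#' @param m0,ms MT-off / MT-on `volume_image`s.
#' @param hard_seg label grid (0 background, 1 GM, 2 WM, 3 CSF).
#' @param soft_seg list of probability grids `gm`, `wm`, `csf`.
#' @param lesion_kappa0 sensitive lesion mask (defines NAGM/NAWM).
#' @param lesion_kappa1 specific lesion mask (the analysed lesion class);
#'   defaults to `lesion_kappa0`.
#' @param metadata list with `patient_id`, `days_since_first`, `protocol`.
#' @param bin_width,valid_range passed to [summarize_mtr_histogram()].
#' @return one-row `data.frame`: metadata, the 10 traits of
#'   [trait_names()], and supplementary `mtr_mean90_*` / `mtr_peakloc_*`
#'   columns.
#' @export
extract_scan_traits <- function(m0, ms, hard_seg, soft_seg, lesion_kappa0,
                                lesion_kappa1 = lesion_kappa0,
                                metadata = list(), bin_width = 1,
                                valid_range = c(0, 100)) {
  mtr <- compute_mtr_map(m0, ms)
  masks <- derive_normal_appearing_masks(hard_seg, lesion_kappa0, lesion_kappa1)
  hs <- lapply(list(lesion = masks$lesion, nawm = masks$nawm, nagm = masks$nagm),
               function(m) summarize_mtr_histogram(mtr, m, bin_width, valid_range))
  vol <- compute_volumetrics(soft_seg, masks$lesion, voxel_size_of(m0))
  out <- data.frame(
    patient_id = as.character(metadata$patient_id %||% NA_character_),
    days_since_first = as.numeric(metadata$days_since_first %||% NA_real_),
    protocol = as.character(metadata$protocol %||% NA_character_),
    mtr_median_lesion = hs$lesion$median,
    mtr_median_nawm = hs$nawm$median,
    mtr_median_nagm = hs$nagm$median,
    mtr_peakh_lesion = hs$lesion$peak_height,
    mtr_peakh_nawm = hs$nawm$peak_height,
    mtr_peakh_nagm = hs$nagm$peak_height,
    total_brain_volume = vol$total_brain_volume,
    wm_pct = vol$wm_pct,
    gm_pct = vol$gm_pct,
    lesion_volume = vol$lesion_volume,
    mtr_mean90_lesion = hs$lesion$mean90,
    mtr_mean90_nawm = hs$nawm$mean90,
    mtr_mean90_nagm = hs$nagm$mean90,
    mtr_peakloc_lesion = hs$lesion$peak_location,
    mtr_peakloc_nawm = hs$nawm$peak_location,
    mtr_peakloc_nagm = hs$nagm$peak_location,
    stringsAsFactors = FALSE
  )
  out
}

#' Inter-correlation of MTR histogram parameters (diagnostic)
#'
#' The four histogram parameters are strongly inter-correlated within a
#' tissue class, which motivates restricting formal analysis to median and
#' peak height; this diagnostic reports the correlation matrix so the
#' redundancy can be inspected rather than silently assumed.
#'
#' @param scans data.frame of per-scan trait rows from
#'   [extract_scan_traits()] (must include the supplementary columns).
#' @param tissue one of "lesion", "nawm", "nagm".
#' @return correlation matrix of median, peak height, mean90, peak location.
#' @export
histogram_intercorrelation <- function(scans, tissue = c("nawm", "nagm", "lesion")) {
  tissue <- match.arg(tissue)
  cols <- paste0(c("mtr_median_", "mtr_peakh_", "mtr_mean90_", "mtr_peakloc_"), tissue)
  missing_cols <- setdiff(cols, names(scans))
  if (length(missing_cols))
    stop("scan table lacks columns: ", paste(missing_cols, collapse = ", "))
  stats::cor(scans[cols], use = "pairwise.complete.obs")
}

#' Read / write a NIfTI volume
#'
#' Thin wrappers over RNifti that attach / use the `volume_image` voxel
#' size; the space tag is user metadata only (NIfTI orientation handling is
#' out of scope — volumes are assumed voxel-aligned).
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param space space tag to attach on read.
#' @return `read_volume`: a `volume_image`; `write_volume`: `path`, invisibly.
#' @export
read_volume <- function(path, space = "aligned") {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[seq_len(3)]
  volume_image(array(as.numeric(img), dim(img)[seq_len(3)]), vox, space)
}

#' @rdname read_volume
#' @param img a `volume_image` (or 3-D array) to write.
#' @export
write_volume <- function(img, path) {
  nii <- RNifti::asNifti(unclass(img))
  RNifti::pixdim(nii) <- voxel_size_of(img)
  RNifti::writeNifti(nii, path)
  invisible(path)
}
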
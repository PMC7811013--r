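test_that("QC boundaries fire exactly as specified", {
  dos <- cbind(rep(0, 100),                       # monomorphic
               c(rep(NA, 3), rep(c(0, 1, 2), length.out = 97)),  # 97% calls
               rep(c(0, 1, 2, 1), 25))            # clean variant
  geno <- make_geno(dos, rep("A", 3), rep("G", 3))
  qc <- variant_qc(geno)
  expect_equal(qc$kept, c(FALSE, FALSE, TRUE))
  expect_equal(qc$reason[1], "maf")
  expect_equal(qc$maf[1], 0)
  expect_equal(qc$reason[2], "call_rate")
  expect_equal(qc$call_rate[2], 0.97)
  # all-missing variant excluded with its own reason
  geno2 <- make_geno(cbind(rep(NA_real_, 10)), "A", "G")
  qc2 <- variant_qc(geno2)
  expect_false(qc2$kept)
  expect_equal(qc2$reason, "no data")
})

test_that("HWE exact p for (10, 80, 10) equals full enumeration", {
  expect_equal(hwe_exact_test(10, 80, 10), oracle_hwe_p(10, 80, 10),
               tolerance = 1e-10)
  # spot checks across regimes, including boundary genotype tables
  cases <- list(c(25, 50, 25), c(0, 1, 0), c(5, 0, 95), c(0, 0, 50),
                c(50, 0, 0), c(1, 1, 1), c(12, 3, 85), c(40, 20, 40))
  for (cs in cases)
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 oracle_hwe_p(cs[1], cs[2], cs[3]), tolerance = 1e-10)
})

test_that("HWE exact test matches enumeration for all counts up to 200 chromosomes", {
  worst <- 0
  for (n in 1:100) {            # n genotypes = 2n chromosomes <= 200
    for (n_rare in 1:n) {
      pmf <- oracle_hwe_pmf(n, n_rare)
      hets <- as.integer(names(pmf))
      for (h in hets) {
        naa <- (n_rare - h) / 2
        nbb <- n - naa - h
        p_oracle <- min(1, sum(pmf[pmf <= pmf[[as.character(h)]] * (1 + 1e-12)]))
        p_impl <- hwe_exact_test(naa, h, nbb)
        worst <- max(worst, abs(p_impl - p_oracle))
      }
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("QC kept-set ignores patient and variant ordering", {
  cfg <- tiny_cs_config(seed = 70)
  gen <- simulate_genotypes(cfg, sprintf("P%03d", 1:80))
  g <- gen$genotypes
  qc1 <- variant_qc(g)
  perm_p <- sample(nrow(g$dosages)); perm_v <- sample(ncol(g$dosages))
  g2 <- genotype_matrix(g$dosages[perm_p, perm_v], g$variants[perm_v, ])
  qc2 <- variant_qc(g2)
  expect_equal(qc2$kept[match(qc1$variant_id, qc2$variant_id)], qc1$kept)
})

test_that("allele alignment handles the canonical cases", {
  dos <- cbind(c(0, 1, 2, 1), c(0, 1, 2, 1))
  geno <- make_geno(dos, c("A", "A"), c("G", "G"))
  w <- data.frame(variant_id = c("v01", "v02"),
                  effect_allele = c("G", "G"), other_allele = c("A", "A"),
                  odds_ratio = c(2.0, 0.5), stringsAsFactors = FALSE)
  al <- align_effect_alleles(geno, w)
  # OR 2.0, effect = allele B: dosages unchanged, weight ln 2
  expect_equal(unname(al$dosages[, "v01"]), c(0, 1, 2, 1))
  expect_equal(al$weights$log_or[1], log(2))
  expect_equal(al$weights$risk_allele[1], "G")
  # OR 0.5, effect = allele B: reflected dosage, inverted OR, weight ln 2
  expect_equal(unname(al$dosages[, "v02"]), c(2, 1, 0, 1))
  expect_equal(al$weights$log_or[2], log(2))
  expect_equal(al$weights$risk_allele[2], "A")
})

test_that("allele-set mismatches drop the variant with a reason", {
  geno <- make_geno(cbind(c(0, 1, 2)), "A", "G")
  w <- data.frame(variant_id = "v01", effect_allele = "C", other_allele = "T",
                  odds_ratio = 1.5)
  w2 <- rbind(w, data.frame(variant_id = "vXX", effect_allele = "A",
                            other_allele = "G", odds_ratio = 1.2))
  w3 <- rbind(w2, data.frame(variant_id = "v01", effect_allele = "G",
                             other_allele = "A", odds_ratio = 1.1))
  expect_message(al <- align_effect_alleles(geno, w3), "dropped 2 variant")
  expect_setequal(al$dropped$reason, c("allele mismatch", "not genotyped"))
  expect_equal(al$weights$variant_id, "v01")
})

test_that("PRS equals the per-variant enumeration oracle under random flips", {
  set.seed(71)
  n <- 30; m <- 20
  p <- runif(m, 0.1, 0.5)
  dos <- vapply(p, function(pp) rbinom(n, 2, pp), numeric(n))
  pairs <- matrix(c("A", "G", "T", "C", "A", "C", "T", "G"), ncol = 2,
                  byrow = TRUE)
  sel <- sample(4, m, replace = TRUE)
  geno <- make_geno(dos, pairs[sel, 1], pairs[sel, 2])
  flip <- runif(m) < 0.5
  w <- data.frame(
    variant_id = colnames(geno$dosages),
    effect_allele = ifelse(flip, pairs[sel, 1], pairs[sel, 2]),
    other_allele = ifelse(flip, pairs[sel, 2], pairs[sel, 1]),
    odds_ratio = exp(rnorm(m, 0, 0.3)), stringsAsFactors = FALSE)
  al <- align_effect_alleles(geno, w)
  expect_equal(unname(compute_prs(al, "all")), unname(oracle_prs(geno, w)),
               tolerance = 1e-12)
})

test_that("PRS unit cases and additivity hold exactly", {
  geno <- make_geno(cbind(c(0, 2), c(0, 0)), c("A", "A"), c("G", "G"),
                    hla = c(TRUE, FALSE))
  w <- data.frame(variant_id = c("v01", "v02"),
                  effect_allele = "G", other_allele = "A",
                  odds_ratio = c(exp(1), 2), category = c("HLA", "non-HLA"),
                  stringsAsFactors = FALSE)
  al <- align_effect_alleles(geno, w)
  s <- compute_prs(al, "all")
  expect_equal(unname(s), c(0, 2))  # all-zero dosages -> 0; d=2, OR=e -> 2
  expect_equal(compute_prs(al, "all"),
               compute_prs(al, "HLA") + compute_prs(al, "non-HLA"))
  expect_error(compute_prs(align_effect_alleles(geno, w[2, ]), "HLA"),
               "empty variant subset")
})

test_that("155-variant panel satisfies score additivity and flip invariance", {
  cfg <- cross_sectional_config(seed = 72)
  gen <- simulate_genotypes(cfg, sprintf("P%03d", 1:100))
  al <- align_effect_alleles(gen$genotypes, gen$weights)
  expect_equal(compute_prs(al, "all"),
               compute_prs(al, "HLA") + compute_prs(al, "non-HLA"),
               tolerance = 1e-12)
  # relabel every variant's alleles (swap A/B, reflect dosages): the PRS
  # must be unchanged once alignment is applied
  g <- gen$genotypes
  swapped <- genotype_matrix(
    2 - g$dosages,
    transform(g$variants, allele_a = allele_b, allele_b = allele_a))
  al2 <- align_effect_alleles(swapped, gen$weights)
  expect_equal(compute_prs(al2, "all"), compute_prs(al, "all"),
               tolerance = 1e-12)
})

test_that("missing dosages are skipped in the score", {
  geno <- make_geno(cbind(c(1, NA), c(2, 2)), c("A", "A"), c("G", "G"))
  w <- data.frame(variant_id = c("v01", "v02"), effect_allele = "G",
                  other_allele = "A", odds_ratio = c(2, 3))
  s <- compute_prs(align_effect_alleles(geno, w), "all")
  expect_equal(unname(s), c(log(2) + 2 * log(3), 2 * log(3)))
})

test_that("planted PRS effect is detected and permutation destroys it", {
  cfg <- cross_sectional_config(n_patients = 150, seed = 73)
  co <- simulate_cohort(cfg)
  tab <- cross_sectional_table(co)
  gen <- simulate_genotypes(cfg, tab$patient_id)
  al <- align_effect_alleles(gen$genotypes, gen$weights)
  scores <- data.frame(patient_id = rownames(al$dosages),
                       prs_total = compute_prs(al, "all"),
                       prs_hla = compute_prs(al, "HLA"),
                       prs_nonhla = compute_prs(al, "non-HLA"))
  # trait as an exact linear function of the score
  tab$planted <- 2 + 0.5 * scores$prs_total[match(tab$patient_id,
                                                  scores$patient_id)]
  res <- prs_trait_association(scores, tab, traits = "planted")
  row <- res[res$predictor == "prs_total", ]
  expect_lt(row$p, 1e-12)
  expect_equal(row$beta, 0.5, tolerance = 1e-6)
  # permuted scores: association destroyed
  set.seed(74)
  ps <- replicate(20, {
    perm <- scores
    perm[2:4] <- perm[sample(nrow(perm)), 2:4]
    prs_trait_association(perm, tab, traits = "planted")$p[1]
  })
  expect_gt(mean(ps > 0.05), 0.7)
})

test_that("single-variant scan counts tests per category and skips monomorphics", {
  cfg <- cross_sectional_config(n_patients = 60, n_variants = 12, n_hla = 4,
                                seed = 75)
  co <- simulate_cohort(cfg)
  tab <- cross_sectional_table(co)
  gen <- simulate_genotypes(cfg, tab$patient_id)
  al <- align_effect_alleles(gen$genotypes, gen$weights)
  al$dosages[, 5] <- 1  # force one non-HLA variant monomorphic
  scan <- single_variant_scan(al, tab, traits = c("gm_pct", "wm_pct"))
  expect_equal(scan$n_skipped, 2L)  # 1 variant x 2 traits
  nom <- scan$nominal
  expect_equal(nom$n_tests[nom$category == "HLA"], 4 * 2)
  expect_equal(nom$n_tests[nom$category == "non-HLA"], 7 * 2)
  expect_equal(nom$nominal_fraction,
               100 * nom$n_nominal / nom$n_tests, tolerance = 1e-12)
})

test_that("dosage TSV and VCF round trips preserve the genotype matrix", {
  cfg <- tiny_cs_config(seed = 76)
  gen <- simulate_genotypes(cfg, sprintf("P%03d", 1:12))
  g <- gen$genotypes
  g$dosages[2, 3] <- NA

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dosage_tsv(g, tsv)
  back <- read_dosage_tsv(tsv)
  expect_equal(back$dosages, g$dosages)
  expect_equal(back$variants$variant_id, g$variants$variant_id)
  expect_equal(back$variants$hla, g$variants$hla)

  vcf <- withr::local_tempfile(fileext = ".vcf.gz")
  write_genotypes_vcf(g, vcf)
  back2 <- read_genotypes_vcf(vcf)
  expect_equal(back2$dosages, g$dosages)
  expect_equal(back2$variants$allele_a, g$variants$allele_a)
  expect_equal(back2$variants$allele_b, g$variants$allele_b)
  expect_equal(back2$variants$hla, g$variants$hla)

  wtsv <- withr::local_tempfile(fileext = ".tsv")
  write_weights_tsv(gen$weights, wtsv)
  wback <- read_weights_tsv(wtsv)
  expect_equal(wback$odds_ratio, gen$weights$odds_ratio)
  expect_error(read_weights_tsv(tsv), "weight table needs columns")
})

test_that("VCF reader falls back to GT when DS is absent", {
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("chr1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "1/1", sep = "\t"),
    paste("chr1", "200", "HLA_rs2", "T", "C", ".", "PASS", ".", "GT",
          "0/0", "./.", sep = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines, f)
  g <- read_genotypes_vcf(f)
  expect_equal(unname(g$dosages["S1", ]), c(1, 0))
  expect_equal(unname(g$dosages["S2", "rs1"]), 2)
  expect_true(is.na(g$dosages["S2", "HLA_rs2"]))
  expect_equal(g$variants$hla, c(FALSE, TRUE))
})
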
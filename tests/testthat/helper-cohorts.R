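# Small fixture builders.

tiny_long_config <- function(seed = 42, ...) {
  cohort_config(n_patients = 10, scans_per_patient = c("2" = 8, "3" = 2),
                seed = seed, ...)
}

study_long_config <- function(seed = 42, ...) {
  cohort_config(seed = seed, ...)  # 33 patients / 72 scans design
}

tiny_cs_config <- function(seed = 42, n_patients = 60, ...) {
  cross_sectional_config(n_patients = n_patients, n_variants = 24, n_hla = 6,
                         n_related_excluded = 2, n_no_genetic = 1,
                         seed = seed, ...)
}

# patients x variants genotype fixture with explicit alleles
make_geno <- function(dos, alleles_a, alleles_b, hla = NULL,
                      ids = sprintf("v%02d", seq_len(ncol(dos)))) {
  colnames(dos) <- ids
  rownames(dos) <- sprintf("P%03d", seq_len(nrow(dos)))
  genotype_matrix(dos, data.frame(variant_id = ids, allele_a = alleles_a,
                                  allele_b = alleles_b,
                                  hla = hla %||% rep(FALSE, ncol(dos)),
                                  stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
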
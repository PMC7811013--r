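# Readers and writers for genotype dosage matrices (TSV and VCF) and
# risk-variant weight tables.

#' Write / read a dosage matrix as TSV
#'
#' The TSV layout is one row per variant: `variant_id`, `allele_a`,
#' `allele_b`, `hla`, then one dosage column per patient. Dosages count
#' copies of `allele_b`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output TSV path.
#' @return `write_dosage_tsv`: `path` invisibly; `read_dosage_tsv`: a
#'   `genotype_matrix`.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  tab <- cbind(v[, c("variant_id", "allele_a", "allele_b")],
               hla = if ("hla" %in% names(v)) v$hla else FALSE,
               as.data.frame(t(genotypes$dosages)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("variant_id", "allele_a", "allele_b", "hla")
  stopifnot(all(meta_cols %in% names(tab)))
  dos <- t(as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE]))
  colnames(dos) <- tab$variant_id
  genotype_matrix(dos, tab[, meta_cols])
}

#' Write / read a risk-variant weight table as TSV
#'
#' Columns: `variant_id`, `effect_allele`, `other_allele`, `odds_ratio`,
#' `category` (HLA / non-HLA).
#'
#' @param weights weight data.frame.
#' @param path TSV path.
#' @return `write_weights_tsv`: `path` invisibly; `read_weights_tsv`: the
#'   data.frame.
#' @export
write_weights_tsv <- function(weights, path) {
  write.table(weights, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights_tsv
#' @export
read_weights_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "odds_ratio")
  if (!all(need %in% names(tab)))
    stop("weight table needs columns: ", paste(need, collapse = ", "))
  tab
}

#' Read genotypes from a VCF
#'
#' Dosages are taken from the `DS` FORMAT field when present, otherwise
#' computed from hard `GT` calls (count of ALT alleles; `./.` is missing).
#' REF maps to `allele_a`, the first ALT to `allele_b`; multi-allelic
#' records are not supported. Variants whose ID contains `HLA`
#' (case-insensitive) are flagged as HLA-region variants.
#'
#' @param path VCF path (plain or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multi-allelic VCF records are not supported")
  fmt <- vcf@gt[, 1]
  has_ds <- all(grepl("DS", fmt))
  if (has_ds) {
    dos <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || grepl("\\.", g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
  }
  dos <- t(dos)  # patients x variants
  ids <- fix[, "ID"]
  colnames(dos) <- ids
  variants <- data.frame(variant_id = ids, allele_a = fix[, "REF"],
                         allele_b = fix[, "ALT"],
                         hla = grepl("hla", ids, ignore.case = TRUE),
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants)
}

#' Write genotypes to a VCF (GT:DS)
#'
#' Emits one record per variant on a synthetic contig, REF = `allele_a`,
#' ALT = `allele_b`, with hard `GT` calls where the dosage is integral
#' (`./.` otherwise) and the dosage in `DS`. Written via vcfR; the output
#' is bgzip-compressed (`.vcf.gz`).
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output path, should end in `.vcf.gz`.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  d <- genotypes$dosages
  m <- nrow(v)
  fix <- cbind(CHROM = "chrS", POS = as.character(seq_len(m)),
               ID = v$variant_id, REF = v$allele_a, ALT = v$allele_b,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  gt_of <- function(x) {
    out <- rep("./.", length(x))
    hard <- !is.na(x) & abs(x - round(x)) < 1e-6
    out[hard] <- c("0/0", "0/1", "1/1")[round(x[hard]) + 1L]
    out
  }
  cells <- vapply(seq_len(m), function(j) {
    x <- d[, j]
    paste(gt_of(x), ifelse(is.na(x), ".", format(x, trim = TRUE)), sep = ":")
  }, character(nrow(d)))
  if (!is.matrix(cells)) cells <- matrix(cells, nrow = 1)
  gt <- cbind(FORMAT = "GT:DS", t(cells))
  colnames(gt) <- c("FORMAT", rownames(d))
  meta <- c("##fileformat=VCFv4.2",
            "##contig=<ID=chrS>",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">")
  requireNamespace("vcfR", quietly = TRUE)
  vcf <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file = path)
  invisible(path)
}
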
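# Independent oracles used across the suite. Each reimplements the quantity
# from first principles (normal equations, log-factorial enumeration,
# explicit sort-and-interpolate percentiles, per-variant counting) so the
# production path is checked against a different route.

# OLS by explicit normal equations, with r2 / adjusted r2 / overall F from
# their closed forms.
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  fitted <- X %*% beta
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y)
  p <- ncol(X) - 1  # X includes the intercept column
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  f <- ((tss - rss) / p) / (rss / (n - p - 1))
  list(beta = as.vector(beta), r2 = r2, adj_r2 = adj, f = f,
       p = pf(f, p, n - p - 1, lower.tail = FALSE))
}

# full conditional distribution of the heterozygote count given allele
# counts, via log-factorials (no recurrence)
oracle_hwe_pmf <- function(n_genotypes, n_rare) {
  n_common <- 2 * n_genotypes - n_rare
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  lp <- vapply(hets, function(h) {
    naa <- (n_rare - h) / 2
    nbb <- n_genotypes - naa - h
    lfactorial(n_genotypes) - lfactorial(naa) - lfactorial(h) -
      lfactorial(nbb) + h * log(2) +
      lfactorial(n_rare) + lfactorial(n_common) - lfactorial(2 * n_genotypes)
  }, numeric(1))
  p <- exp(lp - max(lp))
  setNames(p / sum(p), hets)
}

oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_rare <- min(n_a, 2 * n - n_a)
  if (n_rare == 0) return(1)
  pmf <- oracle_hwe_pmf(n, n_rare)
  obs <- pmf[[as.character(n_ab)]]
  min(1, sum(pmf[pmf <= obs * (1 + 1e-12)]))
}

# type-7 percentile by explicit sort-and-interpolate
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_mean90 <- function(x) {
  p5 <- oracle_percentile(x, 0.05)
  p95 <- oracle_percentile(x, 0.95)
  mean(x[x >= p5 & x <= p95])
}

# PRS by per-variant risk-allele counting straight from the raw genotype
# and weight tables (no alignment code shared with the implementation)
oracle_prs <- function(genotypes, weights) {
  d <- genotypes$dosages
  v <- genotypes$variants
  score <- setNames(numeric(nrow(d)), rownames(d))
  for (i in seq_len(nrow(weights))) {
    w <- weights[i, ]
    j <- match(w$variant_id, v$variant_id)
    if (is.na(j)) next
    if (!setequal(c(w$effect_allele, w$other_allele),
                  c(v$allele_a[j], v$allele_b[j]))) next
    risk <- if (w$odds_ratio >= 1) w$effect_allele else w$other_allele
    lor <- abs(log(w$odds_ratio))
    cnt <- if (risk == v$allele_b[j]) d[, j] else 2 - d[, j]
    cnt[is.na(cnt)] <- 0
    score <- score + cnt * lor
  }
  score
}
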
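# Cross-sectional statistics: covariate-adjusted associations, explained
# variance by age and gender, cross-tissue MTR correlations, Bonferroni
# thresholds.

#' Bonferroni significance threshold
#'
#' `alpha / n_tests`. Monotone decreasing in the number of tests and
#' linear in alpha. Full precision is used for decisions; display rounding
#' (e.g. 0.05/106 = 4.717e-4, shown as 0.00047) is left to reporting.
#'
#' @param alpha family-wise type I error rate, in (0, 1).
#' @param n_tests number of tests, >= 1.
#' @return the per-test threshold.
#' @examples
#' bonferroni_threshold(0.05, 20)   # 0.0025
#' bonferroni_threshold(0.05, 106)  # 4.717e-04
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(n_tests) || n_tests < 1)
    stop("domain error: n_tests must be >= 1")
  alpha / n_tests
}

# partial F-test of nested OLS fits, from residual sums of squares (robust
# to response-name differences that trip up anova())
partial_f_p <- function(fit0, fit1) {
  rss0 <- sum(residuals(fit0)^2); df0 <- stats::df.residual(fit0)
  rss1 <- sum(residuals(fit1)^2); df1 <- stats::df.residual(fit1)
  if (df0 <= df1 || rss1 <= 0) {
    if (rss1 <= 0 && rss0 > 0) return(0)  # saturated full model
    return(NA_real_)
  }
  f <- ((rss0 - rss1) / (df0 - df1)) / (rss1 / df1)
  pf(f, df0 - df1, df1, lower.tail = FALSE)
}

association_row <- function(trait, predictor, beta, se, p, adj_r2_full,
                            adj_r2_baseline, n) {
  data.frame(trait = trait, predictor = predictor, beta = beta, se = se,
             p = p, adj_r2_full = adj_r2_full,
             adj_r2_baseline = adj_r2_baseline,
             delta_adj_r2 = adj_r2_full - adj_r2_baseline, n = n,
             stringsAsFactors = FALSE)
}

# one covariate-adjusted test: trait ~ predictor + covariates, with the
# baseline model dropping the predictor. Wald t-test for a single-column
# predictor, partial F-test for a multi-level categorical one.
covariate_adjusted_association <- function(table, trait, predictor,
                                           covariates = c("age", "gender",
                                                          "protocol"),
                                           predictor_label = predictor) {
  covariates <- setdiff(covariates, predictor)
  covariates <- covariates[vapply(covariates, function(cl)
    length(unique(na.omit(table[[cl]]))) > 1, logical(1))]
  full <- fit_trait_model(table, trait, c(predictor, covariates))
  base <- if (length(covariates))
    fit_trait_model(table[complete.cases(table[, c(trait, predictor, covariates)]), ],
                    trait, covariates)
  else NULL
  cn <- rownames(full$coefficients)
  hit <- cn[startsWith(cn, predictor) & cn != "(Intercept)"]
  if (length(hit) == 1) {
    beta <- full$coefficients[hit, 1]
    se <- full$coefficients[hit, 2]
    p <- full$coefficients[hit, 4]
  } else {
    base_fit <- if (is.null(base)) lm(full$fit$model[[1]] ~ 1) else base$fit
    beta <- NA_real_; se <- NA_real_
    p <- partial_f_p(base_fit, full$fit)
  }
  association_row(trait, predictor_label, beta, se, p, full$adj_r2,
                  if (is.null(base)) 0 else base$adj_r2, full$n)
}

#' Variance in a trait explained by age and gender
#'
#' The increment in adjusted r-squared of the full model
#' `trait ~ age + gender + protocol` over the baseline
#' `trait ~ protocol` (protocol always enters as a categorical covariate;
#' with a single protocol level the baseline degrades to intercept-only and
#' this is logged). The p-value is the partial F-test of the joint
#' age + gender block.
#'
#' @param table cross-sectional analysis table with `age`, `gender`,
#'   `protocol` and the trait.
#' @param trait trait column name.
#' @return one association row; `delta_adj_r2` is the explained-variance
#'   increment (fraction; multiply by 100 for the percent scale used in
#'   summaries).
#' @export
explained_variance_by_age_gender <- function(table, trait) {
  single_protocol <- length(unique(na.omit(table$protocol))) < 2
  if (single_protocol)
    message("explained_variance_by_age_gender: single protocol level, ",
            "baseline is intercept-only")
  used <- c(trait, "age", "gender", if (!single_protocol) "protocol")
  df <- table[complete.cases(table[, used]), , drop = FALSE]
  full <- fit_trait_model(df, trait, c("age", "gender",
                                       if (!single_protocol) "protocol"))
  base <- if (single_protocol) NULL else fit_trait_model(df, trait, "protocol")
  base_adj <- if (single_protocol) 0 else base$adj_r2
  base_fit <- if (single_protocol) lm(df[[trait]] ~ 1) else base$fit
  p <- partial_f_p(base_fit, full$fit)
  association_row(trait, "age+gender", NA_real_, NA_real_, p, full$adj_r2,
                  base_adj, full$n)
}

#' Cross-tissue MTR correlation
#'
#' Regresses one MTR trait on another with age, gender and protocol as
#' covariates; reports the adjusted r-squared of the full model and the
#' Wald t-test p-value for the paired trait.
#'
#' @param table cross-sectional analysis table.
#' @param trait_a response MTR trait.
#' @param trait_b predictor MTR trait (same scans).
#' @return one association row (`adj_r2_baseline` is the covariates-only
#'   model, so `delta_adj_r2` isolates the cross-tissue relation).
#' @export
cross_tissue_correlation <- function(table, trait_a, trait_b) {
  pred <- trait_b
  if (trait_a == trait_b) {  # self-regression: avoid a response/term clash
    table$.paired_trait <- table[[trait_b]]
    pred <- ".paired_trait"
  }
  res <- covariate_adjusted_association(table, trait_a, pred,
                                        predictor_label = trait_b)
  res$predictor <- trait_b
  res
}

#' The six cross-tissue MTR tests
#'
#' Median and peak-height MTR for the pairs lesion-NAWM, lesion-NAGM and
#' NAWM-NAGM (6 tests counted in the cross-sectional multiplicity budget).
#'
#' @param table cross-sectional analysis table.
#' @return data.frame of 6 association rows.
#' @export
cross_tissue_scan <- function(table) {
  pairs <- list(c("nawm", "nagm"), c("lesion", "nawm"), c("lesion", "nagm"))
  rows <- list()
  for (stat in c("mtr_median_", "mtr_peakh_")) for (pr in pairs) {
    a <- paste0(stat, pr[1]); b <- paste0(stat, pr[2])
    rows[[paste(a, b)]] <- cross_tissue_correlation(table, a, b)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted clinical / demographic / genetic association scan
#'
#' One covariate-adjusted test per (trait, predictor) pair: each model is
#' `trait ~ predictor + age + gender + protocol` (the predictor itself is
#' removed from the covariate set when it is age or gender). Constant
#' predictors are skipped and counted as untested; all-missing columns are
#' skipped with a log entry. Bonferroni correction is applied over
#' `performed tests + n_extra_tests` (the cross-tissue tests are budgeted
#' into the same family).
#'
#' @param table cross-sectional analysis table.
#' @param traits trait columns (default [trait_names()]).
#' @param predictors character vector of predictor columns; defaults to
#'   the demographic (gender, age), clinical (disease duration, OCB
#'   status, IgG index, MSSS, treatment status) and genetic (total / HLA /
#'   non-HLA risk score) variables present in the table.
#' @param alpha family-wise error rate.
#' @param n_extra_tests tests outside this scan counted in the same family
#'   (default 6, the cross-tissue tests).
#' @return data.frame of association rows with `threshold` and
#'   `significant` columns; skipped predictors recorded in
#'   `attr(, "skipped")`.
#' @export
clinical_association_scan <- function(table, traits = trait_names(),
                                      predictors = NULL, alpha = 0.05,
                                      n_extra_tests = 6) {
  if (is.null(predictors))
    predictors <- intersect(c("gender", "age", "disease_duration",
                              "ocb_status", "igg_index", "msss", "treatment",
                              "prs_total", "prs_hla", "prs_nonhla"),
                            names(table))
  skipped <- character()
  rows <- list()
  for (pred in predictors) {
    x <- table[[pred]]
    if (all(is.na(x))) {
      message("clinical_association_scan: '", pred, "' is all-missing, skipped")
      skipped <- c(skipped, pred)
      next
    }
    if (length(unique(na.omit(x))) < 2) {
      message("clinical_association_scan: '", pred, "' is constant, skipped")
      skipped <- c(skipped, pred)
      next
    }
    for (tr in traits)
      rows[[paste(tr, pred)]] <- covariate_adjusted_association(table, tr, pred)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  thr <- bonferroni_threshold(alpha, nrow(out) + n_extra_tests)
  out$threshold <- thr
  out$significant <- out$p <= thr
  attr(out, "skipped") <- skipped
  attr(out, "n_tests_family") <- nrow(out) + n_extra_tests
  out
}
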
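# Longitudinal variance partitioning: generic (patient identifier + time)
# and clinical (age + gender + disease duration + time) linear models, and
# the deletion-based decomposition of explained variance.

#' Fit an ordinary least-squares trait model
#'
#' The workhorse behind every analysis model: Gaussian identity-link OLS
#' with reference-level dummy coding for categorical terms (a factor with
#' k levels contributes k - 1 predictors). Rows with missing values in the
#' used columns are dropped and counted; terms that are constant after row
#' dropping are removed with a log message. The model p-value is the
#' overall F-test against the intercept-only model.
#'
#' @param data data.frame holding response and term columns.
#' @param response name of the response column.
#' @param terms character vector of predictor column names; factor /
#'   character columns are treated as categorical.
#' @return object of class `model_fit`: `response`, `terms`,
#'   `coefficients` (estimate, se, t, p per coefficient), `r2`, `adj_r2`,
#'   `model_p`, `n`, `p_terms`, `n_dropped`, and the underlying `lm` fit.
#' @export
fit_trait_model <- function(data, response, terms) {
  missing_cols <- setdiff(c(response, terms), names(data))
  if (length(missing_cols))
    stop("columns not in table: ", paste(missing_cols, collapse = ", "))
  df <- data[, c(response, terms), drop = FALSE]
  for (cl in names(df))
    if (is.character(df[[cl]])) df[[cl]] <- factor(df[[cl]])
  cc <- complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  df <- droplevels(df)
  # constant terms carry no information for this fit; drop them with a note
  constant <- vapply(terms, function(tm) {
    x <- df[[tm]]
    (is.factor(x) && nlevels(x) < 2) || (!is.factor(x) && var(x) == 0)
  }, logical(1))
  if (any(constant)) {
    message("fit_trait_model: dropping constant term(s) ",
            paste(terms[constant], collapse = ", "))
    terms <- terms[!constant]
    if (!length(terms)) stop("all terms are constant; nothing to fit")
  }
  form <- as.formula(paste(sprintf("`%s`", response), "~",
                           paste(sprintf("`%s`", terms), collapse = " + ")))
  fit <- lm(form, data = df)
  p_terms <- fit$rank - 1L
  if (nrow(df) <= p_terms + 1L)
    stop(sprintf("not enough observations (n = %d) for %d predictors",
                 nrow(df), p_terms))
  if (anyNA(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("singular design: aliased terms ", paste(aliased, collapse = ", "))
  }
  # exact fits are legitimate here (noise-free phantoms); the perfect-fit
  # p-value is set explicitly below, so summary()'s caution is redundant
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  model_p <- if (p_terms == 0L) NA_real_
    else if (sm$r.squared >= 1 - 1e-12) 0
    else pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
            lower.tail = FALSE)
  structure(list(response = response, terms = terms,
                 coefficients = sm$coefficients,
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 model_p = unname(model_p), n = nrow(df), p_terms = p_terms,
                 n_dropped = n_dropped, fit = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit: %s ~ %s\n  n = %d (%d dropped), p_terms = %d\n",
              x$response, paste(x$terms, collapse = " + "), x$n, x$n_dropped,
              x$p_terms))
  cat(sprintf("  r2 = %.4f, adj r2 = %.4f, model p = %.3g\n",
              x$r2, x$adj_r2, x$model_p))
  invisible(x)
}

#' Assemble the longitudinal analysis table
#'
#' Joins the per-scan trait rows with the per-patient covariates into the
#' table consumed by the longitudinal models. `age` is the age at the first
#' scan; `days_since_first` is 0 at each patient's first scan.
#'
#' @param cohort a [simulate_cohort()] result, or a list with `patients`
#'   and `scans` data.frames read from TSV.
#' @return data.frame, one row per scan.
#' @export
longitudinal_table <- function(cohort) {
  pt <- cohort$patients
  pt$age <- pt$age_at_first_scan
  keep <- intersect(c("patient_id", "age", "gender", "disease_duration",
                      "ocb_status", "igg_index", "msss", "treatment",
                      "related_excluded", "genetic_available"), names(pt))
  merge(cohort$scans, pt[, keep, drop = FALSE], by = "patient_id", sort = FALSE)
}

#' Assemble the cross-sectional analysis table
#'
#' Takes the first available scan of each patient and joins the patient
#' covariates; `age` is the age at that scan.
#'
#' @inheritParams longitudinal_table
#' @return data.frame, one row per patient.
#' @export
cross_sectional_table <- function(cohort) {
  sc <- cohort$scans
  first <- sc[order(sc$patient_id, sc$days_since_first), ]
  first <- first[!duplicated(first$patient_id), , drop = FALSE]
  tab <- longitudinal_table(list(patients = cohort$patients, scans = first))
  tab$age <- tab$age + tab$days_since_first / 365.25
  tab
}

#' Decompose longitudinal trait variance by term deletion
#'
#' Fits the generic model `trait ~ patient identifier + days since first
#' scan` and attributes explained variance to the inter-patient (identifier)
#' and intra-patient (time) terms by deletion: each term's raw contribution
#' is the adjusted r-squared of the full model minus the adjusted r-squared
#' of the model without that term. Relative shares normalize the raw
#' contributions (negatives floored at 0, raw values still reported) to
#' sum to 100%.
#'
#' @param table longitudinal analysis table ([longitudinal_table()]); needs
#'   `patient_id`, `days_since_first` and the trait column. Patients with a
#'   single scan are retained (they inform the intercepts).
#' @param trait trait column name.
#' @return object of class `variance_decomposition`: `trait`,
#'   `full_adj_r2`, `model_p`, `contributions` (raw, named `patient`,
#'   `time`), `shares` (percent, same names), `adj_r2_without` (the two
#'   reduced-model adjusted r-squared), `n`.
#' @export
decompose_generic_model <- function(table, trait) {
  df <- table
  df$patient_id <- factor(df$patient_id)
  if (all(tapply(df$days_since_first, df$patient_id,
                 function(d) length(unique(d))) <= 1) ||
      var(df$days_since_first, na.rm = TRUE) == 0)
    stop("design error: time term undefined (every patient has a single scan)")
  if (nlevels(df$patient_id) < 2 || nrow(df) < nlevels(df$patient_id) + 2)
    stop("need >= 2 scans for >= 2 patients to decompose variance")
  full <- fit_trait_model(df, trait, c("patient_id", "days_since_first"))
  no_patient <- fit_trait_model(df, trait, "days_since_first")
  no_time <- fit_trait_model(df, trait, "patient_id")
  raw <- c(patient = full$adj_r2 - no_patient$adj_r2,
           time = full$adj_r2 - no_time$adj_r2)
  floored <- pmax(raw, 0)
  shares <- if (sum(floored) > 0) 100 * floored / sum(floored)
            else setNames(rep(NA_real_, 2), names(raw))
  structure(list(trait = trait, full_adj_r2 = full$adj_r2,
                 model_p = full$model_p, contributions = raw, shares = shares,
                 adj_r2_without = c(patient = no_patient$adj_r2,
                                    time = no_time$adj_r2),
                 n = full$n),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(paste0("variance decomposition of %s (n = %d scans)\n",
                     "  full adj r2 = %.3f (model p = %.3g)\n",
                     "  shares: patient %.1f%%, time %.1f%%\n"),
              x$trait, x$n, x$full_adj_r2, x$model_p,
              x$shares[["patient"]], x$shares[["time"]]))
  invisible(x)
}

#' Fit the clinical longitudinal model
#'
#' `trait ~ age + gender + disease duration + days since first scan`: can
#' known patient-specific covariates replace the patient identifier as
#' fixed effects? Reported side by side with the generic model.
#'
#' @inheritParams decompose_generic_model
#' @return a [fit_trait_model()] `model_fit`.
#' @export
fit_clinical_model <- function(table, trait) {
  fit_trait_model(table, trait,
                  c("age", "gender", "disease_duration", "days_since_first"))
}

#' Run the longitudinal analysis over all traits
#'
#' @param table longitudinal analysis table.
#' @param traits trait columns (default [trait_names()]).
#' @param alpha,n_tests family-wise error rate and test count for the
#'   Bonferroni threshold applied to model p-values (default 0.05 over 20:
#'   10 traits times 2 models).
#' @return data.frame, one row per trait: generic-model adjusted r2 and p,
#'   patient/time raw contributions and shares, clinical-model adjusted r2
#'   and p, significance flags at the Bonferroni threshold.
#' @export
longitudinal_analysis <- function(table, traits = trait_names(), alpha = 0.05,
                                  n_tests = 2 * length(traits)) {
  thr <- bonferroni_threshold(alpha, n_tests)
  rows <- lapply(traits, function(tr) {
    dec <- decompose_generic_model(table, tr)
    cli <- fit_clinical_model(table, tr)
    data.frame(trait = tr, generic_adj_r2 = dec$full_adj_r2,
               generic_p = dec$model_p,
               patient_contribution = dec$contributions[["patient"]],
               time_contribution = dec$contributions[["time"]],
               patient_share = dec$shares[["patient"]],
               time_share = dec$shares[["time"]],
               clinical_adj_r2 = cli$adj_r2, clinical_p = cli$model_p,
               n = dec$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_threshold <- thr
  out$generic_significant <- out$generic_p <= thr
  out$clinical_significant <- out$clinical_p <= thr
  rownames(out) <- NULL
  out
}
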
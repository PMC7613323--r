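#' Default adjustment covariate set
#'
#' Child sex and age at developmental assessment, preterm birth, maternal age
#' and education (3 levels, lowest as reference) and smoking in pregnancy.
#' Milestone (Cox) models drop the child-age covariate.
#' @export
default_covariates <- function() {
  c("sex", "age_assess_months", "preterm", "maternal_age",
    "maternal_education", "smoking")
}

# Build the model data.frame: outcome, exposure factor(s) with the largest
# class as reference, covariates (education coerced to factor).
.assoc_frame <- function(data, outcome, class_col, covariates, ref = NULL,
                         extra_class_col = NULL) {
  .assert(is.data.frame(data), "data must be a data.frame")
  need <- c(outcome, class_col, covariates, extra_class_col)
  miss <- setdiff(need, names(data))
  .assert(length(miss) == 0,
          paste("missing columns:", paste(miss, collapse = ", ")))
  df <- data[, need, drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  relevel_largest <- function(x, ref) {
    f <- factor(x)
    if (is.null(ref)) ref <- names(which.max(table(f)))
    stats::relevel(f, ref = as.character(ref))
  }
  df[[class_col]] <- relevel_largest(df[[class_col]], ref)
  if (!is.null(extra_class_col))
    df[[extra_class_col]] <- relevel_largest(df[[extra_class_col]], NULL)
  if ("maternal_education" %in% names(df))
    df$maternal_education <- factor(df$maternal_education)
  df
}

.check_full_rank <- function(mm) {
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# extract exposure-class rows from a fitted model into AssociationResult rows
.class_results <- function(fit, class_col, outcome, family, vc = NULL,
                           exponentiate = FALSE, n_used = NULL) {
  est <- coef(fit)
  if (is.null(vc)) vc <- vcov(fit)
  se <- sqrt(diag(vc))
  sel <- grep(paste0("^", class_col), names(est))
  z <- est[sel] / se[sel]
  p <- 2 * pnorm(-abs(z))
  lo <- est[sel] - qnorm(0.975) * se[sel]
  hi <- est[sel] + qnorm(0.975) * se[sel]
  out <- data.frame(
    outcome = outcome,
    class = sub(paste0("^", class_col), "", names(est)[sel]),
    family = family,
    estimate = if (exponentiate) exp(unname(est[sel])) else unname(est[sel]),
    ci_low = if (exponentiate) exp(unname(lo)) else unname(lo),
    ci_high = if (exponentiate) exp(unname(hi)) else unname(hi),
    p_value = unname(p),
    n_used = if (is.null(n_used)) stats::nobs(fit) else n_used,
    row.names = NULL)
  out
}

#' Linear association of trajectory class with a continuous outcome
#'
#' Ordinary least squares with exposure-class indicators (largest class =
#' reference) plus the standard covariate set; per-class coefficient, 95%
#' normal-theory CI and p-value.
#'
#' @param data subject-level data.frame.
#' @param outcome name of the continuous outcome column.
#' @param class_col name of the trajectory-class column.
#' @param covariates character vector of adjustment covariates.
#' @param ref reference class (default: largest class).
#' @return data.frame of association results, one row per non-reference
#'   class; the reference class never appears.
#' @export
fit_linear <- function(data, outcome, class_col = "hc_class",
                       covariates = default_covariates(), ref = NULL) {
  df <- .assoc_frame(data, outcome, class_col, covariates, ref)
  fml <- as.formula(paste(outcome, "~",
                          paste(c(class_col, covariates), collapse = " + ")))
  .check_full_rank(model.matrix(fml, df))
  fit <- lm(fml, data = df)
  .class_results(fit, class_col, outcome, "linear", n_used = nrow(df))
}

#' Modified Poisson regression: relative risks for binary or count outcomes
#'
#' Poisson generalized linear model with log link. The variance is corrected
#' for overdispersion: by default the covariance is scaled by the Pearson
#' dispersion statistic; `variance = "sandwich"` uses the robust (HC0)
#' sandwich estimator instead. Exponentiated coefficients are returned as
#' relative risks (rate ratios) with 95% CIs.
#'
#' @inheritParams fit_linear
#' @param variance "pearson" (dispersion-scaled) or "sandwich" (robust HC0).
#' @export
fit_modified_poisson <- function(data, outcome, class_col = "hc_class",
                                 covariates = default_covariates(),
                                 ref = NULL,
                                 variance = c("pearson", "sandwich")) {
  variance <- match.arg(variance)
  df <- .assoc_frame(data, outcome, class_col, covariates, ref)
  if (any(df[[outcome]] < 0))
    stop("outcome has negative values; modified Poisson requires counts or ",
         "0/1 indicators", call. = FALSE)
  fml <- as.formula(paste(outcome, "~",
                          paste(c(class_col, covariates), collapse = " + ")))
  .check_full_rank(model.matrix(fml, df))
  fit <- glm(fml, data = df, family = poisson())
  vc <- if (variance == "sandwich") {
    sandwich::vcovHC(fit, type = "HC0")
  } else {
    disp <- sum(residuals(fit, type = "pearson")^2) / df.residual(fit)
    vcov(fit) * disp
  }
  .class_results(fit, class_col, outcome, "modified_poisson", vc = vc,
                 exponentiate = TRUE, n_used = nrow(df))
}

#' Cox proportional hazards model for milestone attainment age
#'
#' Partial-likelihood estimation with Efron tie handling; hazard ratios per
#' trajectory class with 95% CIs. Child age at assessment is not a covariate
#' in milestone models. Milestones never observed are entered censored at the
#' age at last assessment (prepared upstream).
#'
#' @inheritParams fit_linear
#' @param age_col name of the attainment-age column (months).
#' @param event_col name of the 0/1 event-indicator column.
#' @param covariates adjustment covariates; the default drops
#'   `age_assess_months`.
#' @export
fit_cox <- function(data, age_col, event_col, class_col = "hc_class",
                    covariates = setdiff(default_covariates(),
                                         "age_assess_months"),
                    ref = NULL) {
  df <- .assoc_frame(data, age_col, class_col, c(covariates, event_col), ref)
  .assert(all(df[[age_col]] > 0), "milestone ages must be positive")
  .assert(all(df[[event_col]] %in% c(0, 1)), "events must be 0/1")
  if (sum(df[[event_col]]) == 0)
    stop("no events observed; cannot fit a Cox model", call. = FALSE)
  fml <- as.formula(paste0("survival::Surv(", age_col, ", ", event_col,
                           ") ~ ",
                           paste(c(class_col, covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  res <- .class_results(fit, class_col, age_col, "cox", exponentiate = TRUE,
                        n_used = nrow(df))
  res$outcome <- age_col
  res
}

#' Reverse-code a bounded integer scale
#'
#' Returns `scale_max - score`; applying it twice is the identity. Used for
#' the positive-behaviour scale before count modelling.
#'
#' @param score integer score(s) in `[0, scale_max]`.
#' @param scale_max maximum of the scale.
#' @export
reverse_code <- function(score, scale_max) {
  if (any(score < 0 | score > scale_max))
    stop("score outside [0, scale_max]", call. = FALSE)
  scale_max - score
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Standard step-up procedure at level `q`: with ordered p-values p_(1) <=
#' ... <= p_(m), reject all hypotheses with p <= p_(k) where k is the largest
#' i such that p_(i) <= i q / m. Adjusted p-values (monotone after
#' cumulative-minimum enforcement) come from [stats::p.adjust()].
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param q target false-discovery rate.
#' @return list: `reject` (logical, input order), `p_adjusted`, `q`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  below <- which(ps <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(below)) {
    k <- max(below)
    reject[ord[seq_len(k)]] <- TRUE
  }
  list(reject = reject, p_adjusted = p.adjust(p_values, method = "BH"),
       q = q)
}

#' Effect modification by a binary stratum
#'
#' Fits the association model separately within each stratum (e.g.
#' breastfeeding `<7` vs `>=7` months) and a pooled model with class-by-
#' stratum interaction terms; a Wald p-value is reported per class for its
#' interaction term.
#'
#' @inheritParams fit_linear
#' @param family "linear" or "modified_poisson".
#' @param stratum_col name of the binary stratum column (factor or 2 values).
#' @return list: `strata` (named list of per-stratum result data.frames) and
#'   `interaction` (data.frame: class, wald_p).
#' @export
effect_modification <- function(data, outcome, class_col = "hc_class",
                                covariates = default_covariates(),
                                stratum_col, family = c("linear",
                                                        "modified_poisson"),
                                ref = NULL) {
  family <- match.arg(family)
  svals <- sort(unique(as.character(data[[stratum_col]])))
  .assert(length(svals) == 2, "stratum must have exactly 2 levels")
  for (s in svals)
    if (sum(data[[stratum_col]] == s, na.rm = TRUE) == 0)
      stop("empty stratum: ", s, call. = FALSE)
  fitter <- if (family == "linear") fit_linear else fit_modified_poisson
  strata <- lapply(svals, function(s)
    fitter(data[data[[stratum_col]] == s, , drop = FALSE], outcome,
           class_col, covariates, ref))
  names(strata) <- svals
  # pooled interaction model
  df <- .assoc_frame(data, outcome, class_col, c(covariates, stratum_col),
                     ref)
  df[[stratum_col]] <- factor(df[[stratum_col]])
  fml <- as.formula(paste(outcome, "~", class_col, "*", stratum_col, "+",
                          paste(covariates, collapse = " + ")))
  pooled <- if (family == "linear") lm(fml, data = df)
            else glm(fml, data = df, family = poisson())
  vc <- vcov(pooled)
  if (family == "modified_poisson") {
    disp <- sum(residuals(pooled, type = "pearson")^2) / df.residual(pooled)
    vc <- vc * disp
  }
  est <- coef(pooled); se <- sqrt(diag(vc))
  sel <- grep(paste0("^", class_col, ".*:"), names(est))
  wald <- data.frame(
    term = names(est)[sel],
    class = sub(paste0("^", class_col, "([^:]*):.*$"), "\\1",
                names(est)[sel]),
    wald_p = 2 * pnorm(-abs(est[sel] / se[sel])), row.names = NULL)
  list(strata = strata, interaction = wald)
}

#' Breastfeeding-duration stratum
#'
#' Dichotomises breastfeeding duration at 7 months; a duration of exactly 7
#' months belongs to the `">=7"` stratum.
#'
#' @param duration_months numeric duration in months.
#' @return factor with levels `"<7"` and `">=7"`.
#' @export
breastfeeding_stratum <- function(duration_months) {
  factor(ifelse(duration_months >= 7, ">=7", "<7"),
         levels = c("<7", ">=7"))
}

#' Sensitivity-analysis exclusion filter
#'
#' Drops children carrying a named exclusion flag (each analysis excludes one
#' group at a time): preterm birth, NICU admission, serious morbidity, at
#' least three infections in one year, or any hospitalisation.
#'
#' @param data subject-level data.frame carrying 0/1 flag columns.
#' @param exclusion one of "preterm", "nicu", "serious_morbidity",
#'   "frequent_infections", "hospitalized".
#' @return the filtered data.frame; attribute `n_removed` records the count.
#' @export
sensitivity_filter <- function(data, exclusion) {
  flags <- c(preterm = "preterm", nicu = "nicu",
             serious_morbidity = "serious_morbidity",
             frequent_infections = "frequent_infections",
             hospitalized = "hospitalized")
  if (!exclusion %in% names(flags))
    stop("unknown exclusion '", exclusion, "'; expected one of ",
         paste(names(flags), collapse = ", "), call. = FALSE)
  col <- flags[[exclusion]]
  .assert(col %in% names(data), paste("flag column missing:", col))
  keep <- !(data[[col]] %in% 1)
  out <- data[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  if (nrow(out) == 0)
    warning("all subjects carry flag '", exclusion,
            "'; filtered dataset is empty", call. = FALSE)
  out
}

#' Joint head- and abdominal-circumference exposure model
#'
#' Enters both trajectory-class assignments simultaneously so that the
#' head-circumference class effects are adjusted for abdominal growth;
#' reports the HC-class rows only. Perfectly aliased assignments raise a
#' rank-deficiency error.
#'
#' @inheritParams fit_linear
#' @param hc_col,ac_col names of the two class-assignment columns.
#' @param family "linear" or "modified_poisson".
#' @export
multi_exposure_fit <- function(data, outcome, hc_col = "hc_class",
                               ac_col = "ac_class",
                               covariates = default_covariates(),
                               family = c("linear", "modified_poisson"),
                               ref = NULL) {
  family <- match.arg(family)
  df <- .assoc_frame(data, outcome, hc_col, covariates, ref,
                     extra_class_col = ac_col)
  fml <- as.formula(paste(outcome, "~",
                          paste(c(hc_col, ac_col, covariates),
                                collapse = " + ")))
  .check_full_rank(model.matrix(fml, df))
  if (family == "linear") {
    fit <- lm(fml, data = df)
    .class_results(fit, hc_col, outcome, "linear", n_used = nrow(df))
  } else {
    fit <- glm(fml, data = df, family = poisson())
    disp <- sum(residuals(fit, type = "pearson")^2) / df.residual(fit)
    .class_results(fit, hc_col, outcome, "modified_poisson",
                   vc = vcov(fit) * disp, exponentiate = TRUE,
                   n_used = nrow(df))
  }
}
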
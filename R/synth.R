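#' Synthetic-cohort configuration
#'
#' Defaults emulate the study design the package targets: ~3,200 singleton
#' pregnancies scanned on a 5 +/- 1 week schedule (windows 14-18, 19-23,
#' 24-28, 29-33, 34-38 weeks; the post-term window is never analysed), five
#' head-circumference trajectory classes with proportions taken from modal
#' counts 1902/436/268/349/251 of 3206, a shared random intercept and
#' residual noise on the z-scale, and class-linked 2-year outcomes whose
#' effect sizes are seeded from the reported adjusted estimates (they are
#' configuration values, not claims). Trajectory shapes are quadratic
#' B-spline control values anchored to the narrative descriptions: MGT tracks
#' the median; EF falters throughout to about -0.7 SD at term; LF runs about
#' +0.5 SD through mid-pregnancy then falters in the early third trimester;
#' AG tracks the median then accelerates to about +1 SD; LMGT accelerates
#' after 15 weeks then normalises its growth rate at a high level.
#'
#' @param N number of subjects.
#' @param class_proportions probabilities of the G classes (sum to 1).
#' @param class_labels labels, same length.
#' @param beta G x p matrix of class spline coefficients on `spec`'s basis.
#' @param spec generating [spline_spec()] (default: quadratic, knot at 25.5,
#'   boundary 14-37).
#' @param sigma_b,sigma_e random-intercept and residual SDs (z units).
#' @param visit_windows matrix with columns start/end (weeks), one row per
#'   scheduled visit.
#' @param attendance per-window attendance probability in (0, 1].
#' @param outcome_effects list of per-class effects; see
#'   [default_outcome_effects()].
#' @param bf_interaction if TRUE, breastfeeding >= 7 months removes part of
#'   the early-faltering deficit on neurodevelopmental scores.
#' @param seed integer seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(N = 3200,
                         class_proportions = c(0.593, 0.136, 0.084,
                                               0.109, 0.078),
                         class_labels = c("MGT", "EF", "LF", "AG", "LMGT"),
                         beta = default_class_beta(),
                         spec = spline_spec(25.5, c(14, 37), 2),
                         sigma_b = 0.4, sigma_e = 0.3,
                         visit_windows = cbind(c(14, 19, 24, 29, 34),
                                               c(18, 23, 28, 33, 38)),
                         attendance = 0.98,
                         outcome_effects = default_outcome_effects(),
                         bf_interaction = FALSE,
                         seed = 1L) {
  class_proportions <- as.numeric(class_proportions)
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1", call. = FALSE)
  .assert(all(class_proportions > 0), "class proportions must be positive")
  .assert(sigma_b > 0 && sigma_e > 0, "SDs must be positive")
  .assert(attendance > 0 && attendance <= 1, "attendance must be in (0,1]")
  beta <- as.matrix(beta)
  .assert(nrow(beta) == length(class_proportions),
          "beta needs one row per class")
  .assert(ncol(beta) == spec$p, "beta columns must match basis dimension")
  structure(list(N = as.integer(N), class_proportions = class_proportions,
                 class_labels = class_labels, beta = beta, spec = spec,
                 sigma_b = sigma_b, sigma_e = sigma_e,
                 visit_windows = visit_windows, attendance = attendance,
                 outcome_effects = outcome_effects,
                 bf_interaction = bf_interaction, seed = as.integer(seed)),
            class = "synth_config")
}

#' Default class trajectory coefficients
#'
#' Quadratic B-spline control values (basis: boundary 14/37 weeks, internal
#' knot 25.5) for the five classes, rows MGT/EF/LF/AG/LMGT. Because the basis
#' is a partition of unity, each row is approximately the trajectory's value
#' at the Greville sites ~14, 19.8, 31.2 and 37 weeks.
#' @export
default_class_beta <- function() {
  rbind(MGT  = c(0.00, 0.00, 0.00, 0.00),
        EF   = c(0.00, -0.55, -0.85, -0.70),
        LF   = c(0.50, 0.55, 0.00, -0.35),
        AG   = c(0.00, -0.05, 0.45, 1.10),
        LMGT = c(0.00, 0.95, 1.10, 0.95))
}

#' Default class-linked outcome effects
#'
#' Per-class effects relative to the reference MGT class, seeded from the
#' reported adjusted point estimates: additive shifts for continuous scores
#' and 2-year growth z-scores, relative risks for the binary vision deficits
#' and the behaviour count scales, and hazard ratios for the six gross-motor
#' milestones. Class order EF, LF, AG, LMGT (MGT = 0 / 1).
#' @export
default_outcome_effects <- function() {
  cls <- c("EF", "LF", "AG", "LMGT")
  eff <- function(...) setNames(c(...), cls)
  list(
    continuous = list(
      cognitive   = list(base = 50, sd = 10, eff = eff(-4.12, -1.65, 1.53, 1.46)),
      language    = list(base = 50, sd = 13, eff = eff(-7.16, -2.22, 3.45, 3.48)),
      fine_motor  = list(base = 50, sd = 9,  eff = eff(-3.75, -1.45, 0.90, 1.00)),
      gross_motor = list(base = 50, sd = 10, eff = eff(-1.15, 0.93, 0.59, -1.79)),
      attentional_problems = list(base = 3.9, sd = 2.3,
                                  eff = eff(-0.11, 0.24, -0.01, 0.19)),
      emotional_reactivity = list(base = 5.7, sd = 3.6,
                                  eff = eff(0.47, 0.82, -0.36, -0.12)),
      height_z = list(base = -0.34, sd = 1.3,
                      eff = eff(-0.48, -0.08, 0.27, 0.38)),
      weight_z = list(base = 0.0, sd = 1.2,
                      eff = eff(-0.49, 0.03, 0.37, 0.27)),
      hc_z     = list(base = 0.0, sd = 1.1,
                      eff = eff(-0.54, 0.23, 0.64, 0.55)),
      bmi_z    = list(base = 0.0, sd = 1.2,
                      eff = eff(-0.39, 0.14, 0.37, 0.04))),
    binary = list(
      acuity_low   = list(base_risk = 0.13, rr = eff(2.02, 1.62, 0.52, 0.57)),
      contrast_low = list(base_risk = 0.09, rr = eff(1.92, 1.49, 0.52, 0.48))),
    count = list(
      negative_behavior = list(mu = 6, size = 8,
                               rr = eff(1.13, 1.05, 0.84, 0.87)),
      positive_behavior_reversed = list(mu = 8, size = 8, scale_max = 30,
                                        rr = eff(0.93, 0.89, 1.16, 1.09))),
    milestones = list(
      sitting            = list(median = 6.0,  hr = eff(1.11, 1.06, 0.92, 0.94)),
      crawling           = list(median = 8.5,  hr = eff(1.24, 0.96, 0.89, 0.97)),
      standing_with_help = list(median = 9.2,  hr = eff(1.06, 1.03, 0.95, 1.02)),
      standing_alone     = list(median = 11.0, hr = eff(1.12, 0.98, 0.92, 0.92)),
      walking_with_help  = list(median = 10.2, hr = eff(1.02, 0.99, 0.95, 0.98)),
      walking_alone      = list(median = 12.8, hr = eff(1.08, 0.95, 0.91, 0.91))))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws each subject's class from the configured proportions, a visit time
#' uniformly within each attended scheduled window, and scan z-scores
#' `y = B(t) beta_class + b_i + e` with subject random intercept `b_i`.
#' Subject-level outcomes are drawn from family-appropriate models: Gaussian
#' shifts for continuous scores and growth z-scores, Bernoulli via class
#' relative risks for vision deficits, negative-binomial counts via class
#' rate ratios for behaviour scales (overdispersed by construction), and
#' exponential milestone-attainment times with class hazard ratios, censored
#' at the age at assessment. Covariates are drawn independently of class, so
#' adjusted and unadjusted effects coincide in expectation. Fully
#' reproducible from the seed.
#'
#' @param config a [synth_config()].
#' @param seed overrides `config$seed` when supplied.
#' @return list: `scans` (long scan table: subject_id, ga_weeks, sex,
#'   measure, z), `outcomes` (one row per child), `truth` (true class and
#'   random intercept per subject plus the generating parameters).
#' @export
generate_cohort <- function(config = synth_config(), seed = NULL) {
  .assert(inherits(config, "synth_config"), "config must be a synth_config")
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  N <- config$N
  G <- length(config$class_proportions)
  ids <- sprintf("S%05d", seq_len(N))
  cls <- sample.int(G, N, replace = TRUE, prob = config$class_proportions)
  b <- rnorm(N, 0, config$sigma_b)
  sex <- ifelse(runif(N) < 0.52, "male", "female")

  # scans: one uniform time per attended window
  W <- nrow(config$visit_windows)
  attend <- matrix(runif(N * W) < config$attendance, N, W)
  tmat <- matrix(runif(N * W), N, W)
  tmat <- sweep(sweep(tmat, 2, config$visit_windows[, 2] -
                        config$visit_windows[, 1], "*"),
                2, config$visit_windows[, 1], "+")
  sel <- which(attend, arr.ind = TRUE)
  sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
  ga <- tmat[sel]
  subj_row <- sel[, 1]
  # trajectory mean: evaluate basis on the generating spec (clamped to the
  # window for evaluation; scans past 37 wk keep their true ga and are left
  # for the QC filter to drop downstream)
  ga_eval <- pmin(ga, config$spec$boundary_knots[2])
  B <- design_matrix(ga_eval, config$spec)
  mu <- rowSums(B * config$beta[cls[subj_row], , drop = FALSE])
  z <- mu + b[subj_row] + rnorm(length(ga), 0, config$sigma_e)
  scans <- data.frame(subject_id = ids[subj_row], ga_weeks = ga,
                      sex = sex[subj_row], measure = "HC", z = z,
                      row.names = NULL)

  # subject-level covariates, independent of class
  out <- data.frame(
    subject_id = ids,
    sex = sex,
    age_assess_months = pmin(pmax(round(rnorm(N, 25, 1.8), 1), 22), 30),
    preterm = rbinom(N, 1, 0.09),
    maternal_age = round(rnorm(N, 29.4, 5.2), 1),
    maternal_education = sample(c("primary", "secondary", "university"), N,
                                replace = TRUE, prob = c(0.20, 0.37, 0.43)),
    smoking = rbinom(N, 1, 0.041),
    breastfeeding_ge7m = rbinom(N, 1, 0.5),
    nicu = rbinom(N, 1, 0.08),
    serious_morbidity = rbinom(N, 1, 0.05),
    frequent_infections = rbinom(N, 1, 0.07),
    hospitalized = rbinom(N, 1, 0.06))

  lab <- config$class_labels[cls]
  eff_of <- function(effects) {
    e <- rep(0, N)
    hit <- lab %in% names(effects)
    e[hit] <- effects[lab[hit]]
    e
  }
  cov_shift <- with(out, 1.0 * (sex == "female") - 2.0 * preterm +
                      0.3 * (age_assess_months - 25) +
                      1.5 * (maternal_education == "university") -
                      1.0 * smoking)
  oe <- config$outcome_effects
  for (nm in names(oe$continuous)) {
    spec_o <- oe$continuous[[nm]]
    shift <- if (spec_o$base >= 40) cov_shift else 0   # scores only
    bf <- 0
    if (config$bf_interaction && nm %in% c("cognitive", "language",
                                           "fine_motor"))
      bf <- 3.0 * (lab == "EF") * out$breastfeeding_ge7m
    out[[nm]] <- spec_o$base + eff_of(spec_o$eff) + shift + bf +
      rnorm(N, 0, spec_o$sd)
  }
  for (nm in names(oe$binary)) {
    spec_o <- oe$binary[[nm]]
    rrs <- c(1, spec_o$rr)[match(lab, c("MGT", names(spec_o$rr)))]
    rrs[is.na(rrs)] <- 1
    out[[nm]] <- rbinom(N, 1, pmin(spec_o$base_risk * rrs, 0.95))
  }
  for (nm in names(oe$count)) {
    spec_o <- oe$count[[nm]]
    rrs <- c(1, spec_o$rr)[match(lab, c("MGT", names(spec_o$rr)))]
    rrs[is.na(rrs)] <- 1
    cnt <- rnbinom(N, mu = spec_o$mu * rrs, size = spec_o$size)
    if (!is.null(spec_o$scale_max)) cnt <- pmin(cnt, spec_o$scale_max)
    out[[nm]] <- cnt
  }
  if (!is.null(oe$count$positive_behavior_reversed)) {
    sm <- oe$count$positive_behavior_reversed$scale_max
    out$positive_behavior <- sm - out$positive_behavior_reversed
    out$positive_behavior_reversed <- NULL
    attr(out, "positive_behavior_scale_max") <- sm
  }
  for (nm in names(oe$milestones)) {
    spec_o <- oe$milestones[[nm]]
    hrs <- c(1, spec_o$hr)[match(lab, c("MGT", names(spec_o$hr)))]
    hrs[is.na(hrs)] <- 1
    rate <- log(2) / spec_o$median * hrs
    age <- pmax(rexp(N, rate), 0.25)   # attainment no earlier than 1 week
    event <- as.integer(age <= out$age_assess_months)
    out[[paste0(nm, "_age")]] <- round(pmin(age, out$age_assess_months), 2)
    out[[paste0(nm, "_event")]] <- event
  }

  truth <- list(
    class_index = setNames(cls, ids),
    class_label = setNames(lab, ids),
    b = setNames(b, ids),
    params = lcmm_params(config$class_proportions, t(config$beta),
                         config$sigma_b, config$sigma_e),
    spec = config$spec,
    outcome_effects = oe)
  list(scans = scans, outcomes = out, truth = truth)
}

# all permutations of 1..n (n small)
.perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Recovery of simulated ground truth by a fit
#'
#' Aligns fitted class labels to true labels by exhaustive maximum-agreement
#' permutation matching (G <= 7) and reports: modal assignment accuracy,
#' per-class mixture-weight error, root-mean-square error between fitted and
#' true mean trajectories on a gestational-age grid, and variance-component
#' errors.
#'
#' @param fit an `lcmm_fit`.
#' @param truth the `truth` element of [generate_cohort()].
#' @param grid gestational-age grid for the trajectory RMSE.
#' @return list with `accuracy`, `mapping` (fitted -> true class index),
#'   `pi_error`, `traj_rmse` (per matched class), `sigma_b_error`,
#'   `sigma_e_error`.
#' @export
truth_recovery_report <- function(fit, truth,
                                  grid = seq(14, 37, by = 0.5)) {
  ids <- fit$subject_id
  if (!all(ids %in% names(truth$class_index)))
    stop("fit and truth cover different subjects", call. = FALSE)
  true_cls <- truth$class_index[ids]
  G_true <- length(truth$params$pi)
  G_fit <- fit$G
  G <- max(G_true, G_fit)
  .assert(G <= 7, "exhaustive matching supports at most 7 classes")
  pm <- .perms(G)
  acc <- apply(pm, 1, function(p) mean(p[fit$assignments] == true_cls))
  best <- pm[which.max(acc), ]
  mapping <- best[seq_len(G_fit)]
  # trajectory RMSE per matched class that exists in both
  Bf <- design_matrix(grid, fit$spec)
  Bt <- design_matrix(grid, truth$spec)
  rmse <- rep(NA_real_, G_fit)
  pi_err <- rep(NA_real_, G_fit)
  for (g in seq_len(G_fit)) {
    tg <- mapping[g]
    if (tg > G_true) next
    f_traj <- Bf %*% fit$params$beta[, g]
    t_traj <- Bt %*% truth$params$beta[, tg]
    rmse[g] <- sqrt(mean((f_traj - t_traj)^2))
    pi_err[g] <- fit$params$pi[g] - truth$params$pi[tg]
  }
  list(accuracy = max(acc), mapping = mapping, pi_error = pi_err,
       traj_rmse = rmse,
       sigma_b_error = fit$params$sigma_b - truth$params$sigma_b,
       sigma_e_error = fit$params$sigma_e - truth$params$sigma_e)
}
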
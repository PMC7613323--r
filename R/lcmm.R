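#' Latent-class linear mixed model parameters
#'
#' A G-component mixture of linear mixed models on the z-score scale: class g
#' has mean trajectory `X beta_g` (B-spline design `X`), all subjects share a
#' Gaussian random intercept (SD `sigma_b`) and residual SD `sigma_e`, so a
#' subject's within-class covariance is compound-symmetric,
#' `V = sigma_b^2 J + sigma_e^2 I`.
#'
#' @param pi class probabilities (simplex, length G).
#' @param beta p x G matrix of class spline coefficients (z-score units).
#' @param sigma_b random-intercept SD, >= 0.
#' @param sigma_e residual SD, > 0.
#' @return An object of class `lcmm_params`.
#' @export
lcmm_params <- function(pi, beta, sigma_b, sigma_e) {
  beta <- as.matrix(beta)
  .assert(length(pi) == ncol(beta), "length(pi) must equal ncol(beta)")
  .assert(all(pi >= 0) && abs(sum(pi) - 1) < 1e-8,
          "pi must be a probability simplex")
  .assert(sigma_b >= 0, "sigma_b must be >= 0")
  .assert(sigma_e > 0, "sigma_e must be > 0")
  structure(list(G = length(pi), pi = as.numeric(pi), beta = beta,
                 sigma_b = sigma_b, sigma_e = sigma_e),
            class = "lcmm_params")
}

#' EM fitting configuration
#'
#' @param tol relative log-likelihood convergence tolerance, checked over the
#'   last two iterations.
#' @param max_iter maximum EM iterations per restart.
#' @param n_restarts number of initialisations (restart 1 is k-means based,
#'   the rest are seeded perturbations); the best final likelihood wins.
#' @param seed integer seed controlling initialisation.
#' @param variance_floor lower bound on the residual variance, preventing
#'   degenerate likelihood spikes.
#' @export
fit_config <- function(tol = 1e-8, max_iter = 500, n_restarts = 10,
                       seed = 1, variance_floor = 1e-6) {
  .assert(tol > 0 && max_iter > 0 && n_restarts > 0 && variance_floor > 0,
          "all fit_config values must be positive")
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 variance_floor = variance_floor),
            class = "fit_config")
}

# ---- internal data preparation -------------------------------------------

# Long cohort -> per-subject indexed structure used by all likelihood code.
.lcmm_prep <- function(cohort, spec) {
  .assert(is.data.frame(cohort), "cohort must be a data.frame")
  .assert(all(c("subject_id", "ga_weeks", "z") %in% names(cohort)),
          "cohort needs columns subject_id, ga_weeks, z")
  .assert(nrow(cohort) > 0, "empty cohort")
  subj <- factor(cohort$subject_id, levels = unique(cohort$subject_id))
  X <- design_matrix(cohort$ga_weeks, spec)
  list(y = as.numeric(cohort$z), t = as.numeric(cohort$ga_weeks),
       X = X, subj = subj, idx = as.integer(subj),
       n_i = as.integer(table(subj)), N = nlevels(subj),
       subject_id = levels(subj), p = ncol(X))
}

# N x G matrix of per-subject, per-class Gaussian log-densities using the
# structured compound-symmetry forms:
#   log|V_i|  = (n_i - 1) log s2 + log(s2 + n_i sb2)
#   V_i^{-1}  = s2^{-1} [I - (sb2 / (s2 + n_i sb2)) J]
.class_logdens <- function(prep, beta, sigma_b, sigma_e) {
  s2 <- sigma_e^2; sb2 <- sigma_b^2
  R <- prep$y - prep$X %*% beta            # n_obs x G residuals
  S1 <- rowsum(R, prep$subj)               # N x G per-subject residual sums
  S2 <- rowsum(R * R, prep$subj)
  denom <- s2 + prep$n_i * sb2
  ci <- sb2 / denom
  logdet <- (prep$n_i - 1) * log(s2) + log(denom)
  quad <- (S2 - ci * S1^2) / s2
  -0.5 * (prep$n_i * log(2 * pi) + logdet + quad)
}

.check_params <- function(params) {
  .assert(inherits(params, "lcmm_params"), "params must be lcmm_params")
  if (any(params$pi < 0) || abs(sum(params$pi) - 1) > 1e-8)
    stop("pi is not a probability simplex", call. = FALSE)
  if (params$sigma_e <= 0) stop("sigma_e must be > 0", call. = FALSE)
  if (params$sigma_b < 0) stop("sigma_b must be >= 0", call. = FALSE)
}

#' Marginal mixture log-likelihood
#'
#' `sum_i log sum_g pi_g phi(y_i; X_i beta_g, V_i)` with
#' `V_i = sigma_b^2 J + sigma_e^2 I`, evaluated through the structured
#' compound-symmetry determinant/inverse and combined across classes by
#' log-sum-exp.
#'
#' @param cohort long data.frame (`subject_id`, `ga_weeks`, `z`).
#' @param spec a [spline_spec()].
#' @param params an [lcmm_params()].
#' @return scalar log-likelihood.
#' @export
marginal_loglik <- function(cohort, spec, params) {
  .check_params(params)
  prep <- .lcmm_prep(cohort, spec)
  .assert(ncol(params$beta) == params$G && nrow(params$beta) == prep$p,
          "beta must be p x G")
  ld <- .class_logdens(prep, params$beta, params$sigma_b, params$sigma_e)
  A <- sweep(ld, 2, log(pmax(params$pi, 1e-300)), "+")
  sum(.logsumexp_rows(A))
}

#' E-step: posterior class-membership probabilities
#'
#' Bayes' rule `p_ig = pi_g phi_ig / sum_h pi_h phi_ih`, computed in log
#' space so that no row can underflow to NaN. Rows sum to 1.
#'
#' @inheritParams marginal_loglik
#' @return N x G matrix of posterior probabilities (rownames = subject ids).
#' @export
e_step <- function(cohort, spec, params) {
  .check_params(params)
  prep <- .lcmm_prep(cohort, spec)
  ld <- .class_logdens(prep, params$beta, params$sigma_b, params$sigma_e)
  A <- sweep(ld, 2, log(pmax(params$pi, 1e-300)), "+")
  P <- exp(A - .logsumexp_rows(A))
  rownames(P) <- prep$subject_id
  P
}

# ---- EM internals ---------------------------------------------------------

# joint E-step quantities from a log pi + logdens matrix
.posterior_and_ll <- function(ld, logpi) {
  A <- sweep(ld, 2, logpi, "+")
  lse <- .logsumexp_rows(A)
  list(P = exp(A - lse), ll = sum(lse))
}

# M-step for beta: posterior-weighted GLS per class, using
# X' V^{-1} X = s^{-2} [ sum_obs w x x' - sum_i p_ig c_i (sum_i x)(sum_i x)' ]
.update_beta <- function(prep, P, sigma_b, sigma_e) {
  s2 <- sigma_e^2; sb2 <- sigma_b^2
  ci <- sb2 / (s2 + prep$n_i * sb2)
  SX <- rowsum(prep$X, prep$subj)          # N x p
  Sy <- rowsum(prep$y, prep$subj)          # N x 1
  G <- ncol(P); p <- prep$p
  beta <- matrix(0, p, G)
  for (g in seq_len(G)) {
    w <- P[prep$idx, g]
    pc <- P[, g] * ci
    A <- crossprod(prep$X * w, prep$X) - crossprod(SX * pc, SX)
    b <- crossprod(prep$X, w * prep$y) - crossprod(SX * pc, Sy)
    beta[, g] <- tryCatch(solve(A, b),
                          error = function(e)
                            solve(A + diag(1e-8, p), b))
  }
  beta
}

# M-step for (sigma_b, sigma_e): numerical maximisation of the posterior-
# weighted expected complete-data log-likelihood (generalized EM step).
# Uses per-subject residual aggregates so each evaluation is O(N G).
.update_variances <- function(prep, P, beta, sigma_b, sigma_e, floor_se2) {
  R <- prep$y - prep$X %*% beta
  S1 <- rowsum(R, prep$subj)
  S2 <- rowsum(R * R, prep$subj)
  n_i <- prep$n_i
  negQ <- function(par) {
    sb2 <- exp(par[1]); s2 <- exp(par[2])
    denom <- s2 + n_i * sb2
    ld <- -0.5 * ((n_i - 1) * log(s2) + log(denom) +
                    (S2 - (sb2 / denom) * S1^2) / s2)
    -sum(P * ld)
  }
  par0 <- c(log(max(sigma_b^2, 1e-10)), log(max(sigma_e^2, floor_se2)))
  opt <- tryCatch(
    optim(par0, negQ, method = "L-BFGS-B",
          lower = c(log(1e-12), log(floor_se2)), upper = c(10, 10)),
    error = function(e) NULL)
  if (is.null(opt) || opt$value > negQ(par0) + 1e-12)
    return(c(sigma_b, sigma_e))              # keep old values: GEM safeguard
  c(sqrt(exp(opt$par[1])), sqrt(exp(opt$par[2])))
}

# Per-subject pseudo-profiles for initialisation: each subject's observed
# series interpolated (linearly, with nearest-value extrapolation) onto the
# Greville abscissae. Unlike raw per-subject OLS spline coefficients these
# features are bounded by the observed z-range, so k-means on them is stable
# even for subjects with few or clustered scans.
.subject_features <- function(prep, spec) {
  gr <- .greville(spec)
  out <- matrix(0, prep$N, prep$p)
  for (i in seq_len(prep$N)) {
    sel <- prep$idx == i
    ti <- prep$t[sel]; yi <- prep$y[sel]
    out[i, ] <- if (length(unique(ti)) == 1) rep(mean(yi), length(gr))
                else approx(ti, yi, xout = gr, rule = 2, ties = mean)$y
  }
  out
}

.init_params <- function(prep, spec, G, restart, seed, base = NULL) {
  set.seed((seed %% 100000L) * 17L + restart * 1009L + G * 101L)
  if (restart == 1 || is.null(base)) {
    cf <- .subject_features(prep, spec)
    if (G == 1) {
      centers <- matrix(colMeans(cf), 1)
      cl <- rep(1L, prep$N)
    } else {
      km <- kmeans(cf, centers = G, nstart = 20, iter.max = 50)
      centers <- km$centers
      cl <- km$cluster
    }
    pi0 <- as.numeric(table(factor(cl, levels = seq_len(G)))) / prep$N
    pi0 <- pmax(pi0, 1 / (10 * G)); pi0 <- pi0 / sum(pi0)
    # centers live on the Greville-site value scale; map to coefficients
    Xg <- design_matrix(.greville(spec), spec)
    beta0 <- apply(centers, 1, function(v) qr.solve(Xg, v))
    beta0 <- matrix(beta0, nrow = prep$p)
    fitted <- rowSums(prep$X * t(beta0)[cl[prep$idx], , drop = FALSE])
    resid <- prep$y - fitted
    m_i <- rowsum(resid, prep$subj) / prep$n_i
    sb0 <- sqrt(max(var(as.numeric(m_i)) * 0.5, 1e-4))
    se0 <- sqrt(max(var(resid - m_i[prep$idx]) , 1e-4))
    list(pi = pi0, beta = beta0, sigma_b = sb0, sigma_e = max(se0, 0.05))
  } else {
    pi0 <- runif(G, 0.5, 1.5); pi0 <- pi0 / sum(pi0)
    beta0 <- base$beta + matrix(rnorm(length(base$beta), 0, 0.3),
                                nrow(base$beta))
    list(pi = pi0, beta = beta0,
         sigma_b = base$sigma_b * exp(rnorm(1, 0, 0.2)),
         sigma_e = base$sigma_e * exp(rnorm(1, 0, 0.2)))
  }
}

# one EM run from a given initialisation
.em_run <- function(prep, init, config) {
  pi_g <- init$pi; beta <- init$beta
  sigma_b <- init$sigma_b; sigma_e <- max(init$sigma_e,
                                          sqrt(config$variance_floor))
  trace <- numeric(0)
  ll_prev <- -Inf; converged <- FALSE; iter <- 0
  repeat {
    iter <- iter + 1
    ld <- .class_logdens(prep, beta, sigma_b, sigma_e)
    es <- .posterior_and_ll(ld, log(pmax(pi_g, 1e-300)))
    trace[iter] <- es$ll
    if (iter >= 3) {
      rel <- abs(es$ll - ll_prev) / (abs(es$ll) + 1e-10)
      rel2 <- abs(es$ll - trace[iter - 2]) / (abs(es$ll) + 1e-10)
      if (rel < config$tol && rel2 < 2 * config$tol) { converged <- TRUE; break }
    }
    if (iter >= config$max_iter) break
    ll_prev <- es$ll
    pi_g <- colMeans(es$P)
    beta <- .update_beta(prep, es$P, sigma_b, sigma_e)
    vs <- .update_variances(prep, es$P, beta, sigma_b, sigma_e,
                            config$variance_floor)
    sigma_b <- vs[1]; sigma_e <- vs[2]
  }
  list(pi = pi_g, beta = beta, sigma_b = sigma_b, sigma_e = sigma_e,
       loglik = trace[iter], trace = trace, iterations = iter,
       converged = converged)
}

#' Fit the latent-class linear mixed model by EM
#'
#' Maximises the marginal mixture likelihood with latent class labels:
#' E-step by Bayes' rule on the structured compound-symmetry densities;
#' M-step updates the class probabilities in closed form, the class spline
#' coefficients by posterior-weighted generalized least squares, and the two
#' variance components by numerical maximisation of the expected
#' complete-data log-likelihood (a generalized-EM step, so the marginal
#' log-likelihood never decreases). Runs `n_restarts` seeded initialisations
#' (the first seeds classes by k-means on per-subject spline coefficients)
#' and keeps the best. Classes are relabelled in descending estimated
#' probability before return, so class 1 is always the largest class.
#'
#' @param cohort long data.frame (`subject_id`, `ga_weeks`, `z`), already
#'   QC- and eligibility-filtered.
#' @param spec a [spline_spec()].
#' @param G number of latent classes.
#' @param config a [fit_config()].
#' @return An object of class `lcmm_fit`: `params`, `loglik`, `bic`,
#'   `posteriors` (N x G), `assignments` (modal class, named by subject),
#'   `app`, `occ`, `n_per_class`, `convergence` (iterations, restarts_used,
#'   converged, loglik trace of the winning run), `spec`, `N`, `G`.
#' @export
fit_lcmm <- function(cohort, spec, G, config = fit_config()) {
  .assert(inherits(config, "fit_config"), "config must be a fit_config")
  prep <- .lcmm_prep(cohort, spec)
  .assert(prep$N >= G, "need at least G subjects")
  best <- NULL; base <- NULL
  for (r in seq_len(config$n_restarts)) {
    init <- .init_params(prep, spec, G, r, config$seed, base)
    if (r == 1) base <- init
    run <- .em_run(prep, init, config)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (!best$converged)
    warning("EM did not converge within max_iter; returning best run",
            call. = FALSE)
  ord <- order(best$pi, decreasing = TRUE)
  params <- lcmm_params(best$pi[ord] / sum(best$pi),
                        best$beta[, ord, drop = FALSE],
                        best$sigma_b, best$sigma_e)
  ld <- .class_logdens(prep, params$beta, params$sigma_b, params$sigma_e)
  es <- .posterior_and_ll(ld, log(pmax(params$pi, 1e-300)))
  P <- es$P
  rownames(P) <- prep$subject_id
  assign <- classify(P)
  names(assign) <- prep$subject_id
  diag <- lcmm_diagnostics(P, assign, params$pi)
  k <- (G - 1) + G * prep$p + 2
  fit <- structure(list(
    params = params, loglik = es$ll,
    bic = -2 * es$ll + k * log(prep$N), k = k,
    posteriors = P, assignments = assign,
    app = diag$app, occ = diag$occ,
    n_per_class = tabulate(assign, nbins = G),
    convergence = list(iterations = best$iterations,
                       restarts_used = config$n_restarts,
                       converged = best$converged,
                       loglik_trace = best$trace),
    spec = spec, N = prep$N, G = G, subject_id = prep$subject_id),
    class = "lcmm_fit")
  fit
}

#' Bayesian information criterion of a fit
#'
#' `BIC = -2 loglik + k log(N)` with `k = (G - 1) + G p + 2` free parameters
#' (mixture weights, class spline coefficients, two variance components) and
#' `N` the number of subjects, consistent with the subject-level mixture
#' likelihood. Lower is better.
#'
#' @param fit an `lcmm_fit`.
#' @param N number of subjects (defaults to the fit's).
#' @export
bic_lcmm <- function(fit, N = fit$N) {
  -2 * fit$loglik + fit$k * log(N)
}

#' Modal class assignment
#'
#' Highest-posterior class per subject; ties break toward the lower class
#' index, deterministically.
#'
#' @param posteriors N x G posterior matrix.
#' @return integer vector of class indices.
#' @export
classify <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  max.col(posteriors, ties.method = "first")
}

#' Classification-quality diagnostics: APP and OCC
#'
#' APP_g is the average posterior probability of class g among subjects
#' modally assigned to g; OCC_g = (APP_g / (1 - APP_g)) / (pi_g / (1 - pi_g))
#' compares posterior to prior odds of correct assignment — OCC_g > 1 means
#' classification beats chance. An empty class yields APP = NA with a
#' warning; APP = 1 yields OCC = +Inf.
#'
#' @param posteriors N x G posterior matrix.
#' @param assignments integer modal assignments (from [classify()]).
#' @param pi_hat estimated class probabilities.
#' @return list with numeric vectors `app` and `occ` (length G).
#' @export
lcmm_diagnostics <- function(posteriors, assignments, pi_hat) {
  posteriors <- as.matrix(posteriors)
  G <- ncol(posteriors)
  app <- rep(NA_real_, G); occ <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    sel <- assignments == g
    if (!any(sel)) next
    app[g] <- mean(posteriors[sel, g])
    prior_odds <- pi_hat[g] / (1 - pi_hat[g])
    occ[g] <- if (app[g] >= 1) Inf
              else (app[g] / (1 - app[g])) / prior_odds
  }
  if (anyNA(app))
    warning("empty class: APP undefined for class(es) ",
            paste(which(is.na(app)), collapse = ", "), call. = FALSE)
  list(app = app, occ = occ)
}

#' @export
print.lcmm_fit <- function(x, ...) {
  cat("Latent-class linear mixed model fit\n")
  cat(sprintf("  subjects: %d   classes: %d   basis dim: %d\n",
              x$N, x$G, nrow(x$params$beta)))
  cat(sprintf("  loglik: %.3f   BIC: %.3f   converged: %s (%d iter)\n",
              x$loglik, x$bic, x$convergence$converged,
              x$convergence$iterations))
  cat(sprintf("  pi: %s\n", paste(sprintf("%.3f", x$params$pi),
                                  collapse = " ")))
  cat(sprintf("  sigma_b: %.4f   sigma_e: %.4f\n",
              x$params$sigma_b, x$params$sigma_e))
  cat(sprintf("  APP: %s\n", paste(sprintf("%.3f", x$app), collapse = " ")))
  cat(sprintf("  OCC: %s\n", paste(sprintf("%.2f", x$occ), collapse = " ")))
  invisible(x)
}

#' Plot fitted class mean trajectories
#'
#' One curve per latent class on a gestational-age grid, labelled with the
#' estimated class probabilities.
#'
#' @param x an `lcmm_fit`.
#' @param grid gestational-age grid (weeks).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lcmm_fit <- function(x, grid = seq(x$spec$boundary_knots[1],
                                        x$spec$boundary_knots[2],
                                        by = 0.25), ...) {
  traj <- design_matrix(grid, x$spec) %*% x$params$beta
  graphics::matplot(grid, traj, type = "l", lty = 1, lwd = 2,
                    xlab = "Gestational age (weeks)",
                    ylab = "Head circumference z-score", ...)
  graphics::legend("topleft", bty = "n", lty = 1, lwd = 2,
                   col = seq_len(x$G),
                   legend = sprintf("class %d (%.1f%%)", seq_len(x$G),
                                    100 * x$params$pi))
  invisible(x)
}

#' Posterior/assignment table for a fit
#'
#' One row per subject: posterior probability of each class and the modal
#' class; suitable for CSV export.
#' @param fit an `lcmm_fit`.
#' @export
posterior_table <- function(fit) {
  P <- fit$posteriors
  out <- data.frame(subject_id = fit$subject_id, P,
                    modal_class = fit$assignments,
                    row.names = NULL, check.names = FALSE)
  names(out)[2:(1 + fit$G)] <- paste0("p_", seq_len(fit$G))
  out
}

#' Serialise a fit to a structured text file (JSON)
#'
#' Writes parameters, diagnostics and the convergence trace; posteriors are
#' written separately via [posterior_table()].
#' @param fit an `lcmm_fit`.
#' @param path output file path.
#' @export
write_lcmm_fit <- function(fit, path) {
  obj <- list(G = fit$G, N = fit$N,
              pi = fit$params$pi, beta = fit$params$beta,
              sigma_b = fit$params$sigma_b, sigma_e = fit$params$sigma_e,
              loglik = fit$loglik, bic = fit$bic, k = fit$k,
              app = fit$app, occ = fit$occ,
              n_per_class = fit$n_per_class,
              convergence = fit$convergence,
              spline = list(degree = fit$spec$degree,
                            internal_knots = fit$spec$internal_knots,
                            boundary_knots = fit$spec$boundary_knots))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
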
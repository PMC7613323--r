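spec4 <- spline_spec(25.5, c(14, 37))

test_that("marginal log-likelihood reduces to univariate normals when sigma_b = 0", {
  # single subject, single scan at its class mean, unit residual SD
  cohort <- data.frame(subject_id = "s1", ga_weeks = 20, z = 0.7)
  beta <- matrix(0.7, 4, 1)   # partition of unity => X beta = 0.7 everywhere
  params <- lcmm_params(1, beta, sigma_b = 0, sigma_e = 1)
  expect_equal(marginal_loglik(cohort, spec4, params), -0.5 * log(2 * pi),
               tolerance = 1e-12)

  # several subjects: must equal the sum of independent normal log-densities
  set.seed(5)
  cohort <- data.frame(subject_id = rep(c("a", "b"), each = 3),
                       ga_weeks = runif(6, 14, 37), z = rnorm(6))
  beta <- matrix(rnorm(4), 4, 1)
  params <- lcmm_params(1, beta, sigma_b = 0, sigma_e = 0.8)
  mu <- drop(design_matrix(cohort$ga_weeks, spec4) %*% beta)
  expect_equal(marginal_loglik(cohort, spec4, params),
               sum(dnorm(cohort$z, mu, 0.8, log = TRUE)), tolerance = 1e-10)
})

test_that("invalid parameters are rejected", {
  cohort <- data.frame(subject_id = "s", ga_weeks = 20, z = 0)
  expect_error(lcmm_params(c(0.6, 0.6), matrix(0, 4, 2), 0.1, 0.1),
               "simplex")
  expect_error(lcmm_params(1, matrix(0, 4, 1), 0.1, -1), "sigma_e")
})

test_that("likelihood is invariant under class relabelling", {
  inst <- random_instance(11)
  p <- inst$params
  perm <- sample(p$G)
  p2 <- lcmm_params(p$pi[perm], p$beta[, perm, drop = FALSE],
                    p$sigma_b, p$sigma_e)
  expect_equal(marginal_loglik(inst$cohort, inst$spec, p),
               marginal_loglik(inst$cohort, inst$spec, p2),
               tolerance = 1e-12)
})

test_that("posteriors obey symmetry and degenerate-prior limits", {
  cohort <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                       ga_weeks = c(15, 20, 25, 30), z = rnorm(4))
  beta <- matrix(0.3, 4, 2)   # identical classes
  params <- lcmm_params(c(0.5, 0.5), beta, 0.2, 0.5)
  P <- e_step(cohort, spec4, params)
  expect_equal(unname(P), matrix(0.5, 2, 2), tolerance = 1e-12)

  params2 <- lcmm_params(c(1, 0), matrix(rnorm(8), 4, 2), 0.2, 0.5)
  P2 <- e_step(cohort, spec4, params2)
  expect_equal(unname(P2[, 1]), c(1, 1), tolerance = 1e-12)
})

test_that("posteriors match the dense-covariance Bayes oracle", {
  for (s in 1:20) {
    inst <- random_instance(s + 400)
    P <- e_step(inst$cohort, inst$spec, inst$params)
    O <- oracle_dense_posteriors(inst$cohort, inst$spec, inst$params)
    expect_lt(max(abs(unname(P) - O)), 1e-10)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  }
})

test_that("posterior rows never underflow to NaN", {
  # extreme separation: densities underflow, log-sum-exp must not
  cohort <- data.frame(subject_id = "s", ga_weeks = c(15, 25, 35),
                       z = c(0, 0, 0))
  params <- lcmm_params(c(0.5, 0.5),
                        cbind(rep(0, 4), rep(500, 4)), 0.1, 0.1)
  P <- e_step(cohort, spec4, params)
  expect_false(anyNA(P))
  expect_equal(sum(P), 1, tolerance = 1e-12)
})

test_that("modal classification is an argmax with low-index tie-break", {
  expect_equal(classify(matrix(c(0.9, 0.1), 1)), 1L)
  expect_equal(classify(matrix(c(0.5, 0.5), 1)), 1L)
  set.seed(9)
  P <- matrix(runif(300), 100, 3)
  expect_equal(classify(P), apply(P, 1, which.max))
})

test_that("APP/OCC formulas match hand arithmetic", {
  # APP 0.75 against prior 0.5: OCC = (0.75/0.25)/(0.5/0.5) = 3
  P <- matrix(c(0.75, 0.25,
                0.75, 0.25,
                0.25, 0.75), 3, 2, byrow = TRUE)
  d <- lcmm_diagnostics(P, c(1, 1, 2), pi_hat = c(0.5, 0.5))
  expect_equal(d$app, c(0.75, 0.75))
  expect_equal(d$occ[1], 3.0)
  # APP equal to the prior: no better than chance
  P2 <- matrix(c(0.3, 0.7), 1)
  d2 <- suppressWarnings(lcmm_diagnostics(P2, 2L, pi_hat = c(0.3, 0.7)))
  expect_equal(d2$occ[2], 1.0)
  # empty class: APP missing with warning; APP = 1: OCC infinite
  expect_warning(d3 <- lcmm_diagnostics(matrix(c(1, 0), 1), 1L,
                                        c(0.6, 0.4)), "empty class")
  expect_true(is.na(d3$app[2]))
  expect_equal(d3$occ[1], Inf)
})

test_that("BIC follows -2 loglik + k log N with subject-level N", {
  fake <- structure(list(loglik = 0, k = 6, N = exp(2)),
                    class = "lcmm_fit")
  expect_equal(bic_lcmm(fake), 12)             # G=1, p=4 -> k = 6
  fake2 <- structure(list(loglik = -100, k = 11, N = 50),
                     class = "lcmm_fit")       # G=2, p=4 -> k = 11
  expect_equal(bic_lcmm(fake2), 200 + 11 * log(50), tolerance = 1e-10)
  expect_equal(bic_lcmm(fake2), 243.0320, tolerance = 1e-4)
})

test_that("fit recovers a 2-class structure and its EM trace ascends", {
  cfg <- synth_config(N = 200, class_proportions = c(0.6, 0.4),
                      class_labels = c("hi", "lo"),
                      beta = rbind(c(0.8, 0.9, 0.8, 0.7),
                                   c(-0.8, -0.9, -0.8, -0.7)),
                      sigma_b = 0.4, sigma_e = 0.3, seed = 21)
  cc <- make_cohort(cfg)
  fit <- fit_lcmm(cc$cohort, spec4, 2, fit_config(n_restarts = 3, seed = 4))
  expect_true(all(diff(fit$convergence$loglik_trace) > -1e-9))
  rep <- truth_recovery_report(fit, cc$truth)
  expect_gte(rep$accuracy, 0.98)
  # compare to the realised class shares (at N = 200 the nominal proportions
  # carry ~0.035 binomial sampling error of their own)
  realised <- tabulate(cc$truth$class_index[fit$subject_id], 2) / fit$N
  expect_lt(max(abs(fit$params$pi - realised[rep$mapping])), 0.05)
  # classes come back ordered by descending weight and posteriors are proper
  expect_true(!is.unsorted(rev(fit$params$pi)))
  expect_lt(max(abs(rowSums(fit$posteriors) - 1)), 1e-10)
  expect_equal(sum(fit$n_per_class), fit$N)
})

test_that("fit refuses more classes than subjects", {
  cohort <- data.frame(subject_id = rep(c("a", "b"), each = 3),
                       ga_weeks = rep(c(15, 25, 35), 2), z = rnorm(6))
  expect_error(fit_lcmm(cohort, spec4, 3, fit_config(n_restarts = 1)),
               "at least G subjects")
})

test_that("with one scan per subject the fit matches a mixture-of-regressions EM", {
  set.seed(31)
  n <- 150
  t <- runif(n, 14, 37)
  X <- design_matrix(t, spec4)
  grp <- sample(1:2, n, replace = TRUE, prob = c(0.6, 0.4))
  betas <- cbind(c(1, 1.2, 1, 0.8), c(-1, -1.2, -1, -0.8))
  y <- rowSums(X * t(betas)[grp, ]) + rnorm(n, 0, 0.5)
  cohort <- data.frame(subject_id = sprintf("u%03d", seq_len(n)),
                       ga_weeks = t, z = y)
  fit <- fit_lcmm(cohort, spec4, 2, fit_config(n_restarts = 4, seed = 5))
  ll_oracle <- oracle_mixreg_em(y, X, 2, n_restarts = 6, seed = 2)
  # with n_i = 1 only sigma_b^2 + sigma_e^2 is identified, so the marginal
  # likelihoods are directly comparable
  expect_equal(fit$loglik, ll_oracle, tolerance = 1e-4)
})

test_that("adding a class to single-class noise increases BIC", {
  cfg <- synth_config(N = 150, class_proportions = 1, class_labels = "only",
                      beta = rbind(c(0, 0, 0, 0)), sigma_b = 0.4,
                      sigma_e = 0.3, seed = 77)
  cc <- make_cohort(cfg)
  f1 <- fit_lcmm(cc$cohort, spec4, 1, fit_config(n_restarts = 1, seed = 1))
  f2 <- fit_lcmm(cc$cohort, spec4, 2, fit_config(n_restarts = 2, seed = 1))
  expect_gt(f2$bic, f1$bic)
})
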
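# subject table with a 3-level trajectory class (class "1" largest) and the
# standard covariate set; outcome built per test
make_outcome_data <- function(n = 2000, seed = 1) {
  df <- make_covariates(n, seed)
  set.seed(seed + 500)
  df$hc_class <- sample(c("1", "2", "3"), n, replace = TRUE,
                        prob = c(0.6, 0.25, 0.15))
  df
}

test_that("linear class effects are estimated against the largest class", {
  df <- make_outcome_data(2000, seed = 2)
  set.seed(99)
  df$score <- 50 + 5.0 * (df$hc_class == "2") +
    1.2 * (df$sex == "female") - 2 * df$preterm + rnorm(nrow(df), 0, 8)
  res <- fit_linear(df, "score")
  expect_setequal(res$class, c("2", "3"))      # reference never appears
  r2 <- res[res$class == "2", ]
  expect_true(r2$ci_low <= 5.0 && 5.0 <= r2$ci_high)
  r3 <- res[res$class == "3", ]
  expect_true(r3$ci_low <= 0 && 0 <= r3$ci_high)   # null class covers 0
  expect_true(all(res$ci_low <= res$estimate & res$estimate <= res$ci_high))
})

test_that("unadjusted linear fit reproduces raw class mean differences", {
  df <- make_outcome_data(600, seed = 3)
  set.seed(11)
  df$y <- rnorm(600, 10, 2) + 2 * (df$hc_class == "3")
  res <- fit_linear(df, "y", covariates = character(0))
  means <- tapply(df$y, df$hc_class, mean)
  expect_equal(res$estimate[res$class == "2"],
               unname(means["2"] - means["1"]), tolerance = 1e-8)
  expect_equal(res$estimate[res$class == "3"],
               unname(means["3"] - means["1"]), tolerance = 1e-8)
})

test_that("rank-deficient designs fail loudly naming the collinear column", {
  df <- make_outcome_data(300, seed = 4)
  df$dup <- as.numeric(df$preterm)
  df$y <- rnorm(300)
  expect_error(fit_linear(df, "y", covariates = c("preterm", "dup")),
               "rank deficient.*dup")
})

test_that("modified Poisson on a covariate-free 2x2 returns the exact risk ratio", {
  df <- data.frame(hc_class = rep(c("1", "2"), each = 100),
                   y = c(rep(1, 10), rep(0, 90), rep(1, 20), rep(0, 80)))
  res <- fit_modified_poisson(df, "y", covariates = character(0))
  expect_equal(res$estimate, 2.0, tolerance = 1e-8)   # 0.20 / 0.10
  expect_true(res$ci_low <= res$estimate & res$estimate <= res$ci_high)
})

test_that("modified Poisson is null-calibrated and rejects negative outcomes", {
  df <- make_outcome_data(3000, seed = 6)
  set.seed(12)
  df$y <- rbinom(nrow(df), 1, 0.2)
  res <- fit_modified_poisson(df, "y")
  expect_true(all(res$ci_low <= 1 & 1 <= res$ci_high))
  expect_lt(max(abs(res$estimate - 1)), 0.25)
  df$bad <- df$y - 1
  expect_error(fit_modified_poisson(df, "bad"), "negative")
})

test_that("overdispersion correction widens the naive Poisson intervals", {
  df <- make_outcome_data(1500, seed = 7)
  set.seed(13)
  df$cnt <- rnbinom(nrow(df), mu = 6 * ifelse(df$hc_class == "2", 1.3, 1),
                    size = 2)   # strongly overdispersed
  res <- fit_modified_poisson(df, "cnt", covariates = character(0))
  naive <- glm(cnt ~ factor(hc_class), data = df, family = poisson())
  se_naive <- sqrt(diag(vcov(naive)))[-1]
  width_naive <- exp(coef(naive)[-1] + 1.96 * se_naive) -
    exp(coef(naive)[-1] - 1.96 * se_naive)
  width_corr <- res$ci_high - res$ci_low
  expect_true(all(width_corr > unname(width_naive)))
  # sandwich variant runs and also widens
  res_sw <- fit_modified_poisson(df, "cnt", covariates = character(0),
                                 variance = "sandwich")
  expect_true(all(res_sw$ci_high - res_sw$ci_low > unname(width_naive)))
})

test_that("Cox milestone models recover hazard ratios and handle the null", {
  set.seed(21)
  n <- 1000
  df <- make_covariates(n, seed = 21)
  df$hc_class <- rep(c("1", "2"), each = n / 2)
  rate <- ifelse(df$hc_class == "2", 2, 1) * log(2) / 10
  df$age <- rexp(n, rate)
  df$event <- 1L
  res <- fit_cox(df, "age", "event", covariates = character(0))
  expect_gt(res$estimate, 1.8)
  expect_lt(res$estimate, 2.2)
  # identical groups: HR near 1
  set.seed(22)
  df$age0 <- rexp(n, log(2) / 10)
  res0 <- fit_cox(df, "age0", "event", covariates = character(0))
  expect_lt(abs(res0$estimate - 1), 0.2)
  df$noev <- 0L
  expect_error(fit_cox(df, "age", "noev", covariates = character(0)),
               "no events")
})

test_that("reverse coding is an involution on the declared scale", {
  expect_equal(reverse_code(35, 35), 0)
  expect_equal(reverse_code(0, 35), 35)
  x <- c(0, 3, 17, 35)
  expect_equal(reverse_code(reverse_code(x, 35), 35), x)
  expect_error(reverse_code(36, 35), "outside")
})

test_that("BH step-up rejects by the declared worked example", {
  out <- bh_fdr(c(0.01, 0.02, 0.04), q = 0.05)
  expect_true(all(out$reject))
  expect_false(any(bh_fdr(rep(1, 5))$reject))
  expect_true(bh_fdr(0.04, q = 0.05)$reject)   # m = 1: raw threshold
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # adjusted p are monotone in the raw ordering
  p <- c(0.003, 0.04, 0.2, 0.04, 0.8)
  expect_false(is.unsorted(sort(bh_fdr(p)$p_adjusted)))
})

test_that("breastfeeding stratification puts exactly 7 months in >=7", {
  s <- breastfeeding_stratum(c(3, 6.9, 7, 12))
  expect_equal(as.character(s), c("<7", "<7", ">=7", ">=7"))
})

test_that("effect modification recovers an injected interaction", {
  df <- make_outcome_data(2000, seed = 8)
  set.seed(14)
  df$stratum <- sample(c("<7", ">=7"), nrow(df), replace = TRUE)
  eff <- ifelse(df$stratum == "<7", -5, 0)
  df$y <- 40 + eff * (df$hc_class == "2") + rnorm(nrow(df), 0, 6)
  em <- effect_modification(df, "y", stratum_col = "stratum",
                            family = "linear")
  a <- em$strata[["<7"]]
  b <- em$strata[[">=7"]]
  expect_true(a$ci_low[a$class == "2"] <= -5 &
                -5 <= a$ci_high[a$class == "2"])
  expect_true(b$ci_low[b$class == "2"] <= 0 & 0 <= b$ci_high[b$class == "2"])
  expect_lt(em$interaction$wald_p[em$interaction$class == "2"], 0.01)

  # no interaction: strata agree
  set.seed(15)
  df$y0 <- 40 - 3 * (df$hc_class == "2") + rnorm(nrow(df), 0, 6)
  em0 <- effect_modification(df, "y0", stratum_col = "stratum",
                             family = "linear")
  est <- sapply(em0$strata, function(s) s$estimate[s$class == "2"])
  expect_lt(abs(diff(est)), 2)
  expect_gt(em0$interaction$wald_p[em0$interaction$class == "2"], 0.01)
  # empty stratum is named
  df$stratum2 <- "<7"
  expect_error(effect_modification(df, "y", stratum_col = "stratum2",
                                   family = "linear"), "2 levels")
})

test_that("sensitivity exclusions are exact bookkeeping", {
  df <- make_outcome_data(200, seed = 9)
  df$nicu <- rbinom(200, 1, 0.1)
  out <- sensitivity_filter(df, "nicu")
  expect_equal(nrow(out), 200 - sum(df$nicu))
  expect_equal(attr(out, "n_removed"), sum(df$nicu))
  df$nicu <- 0
  expect_equal(nrow(sensitivity_filter(df, "nicu")), 200)   # identity
  df$nicu <- 1
  expect_warning(out2 <- sensitivity_filter(df, "nicu"), "empty")
  expect_equal(nrow(out2), 0)
  expect_error(sensitivity_filter(df, "bogus"), "unknown exclusion")
})

test_that("joint HC+AC models adjust for the abdominal trajectory", {
  df <- make_outcome_data(2500, seed = 10)
  set.seed(16)
  df$ac_class <- sample(c("1", "2", "3"), nrow(df), replace = TRUE,
                        prob = c(0.6, 0.25, 0.15))
  df$y <- 30 + 4 * (df$hc_class == "2") + rnorm(nrow(df), 0, 5)
  single <- fit_linear(df, "y", covariates = character(0))
  joint <- multi_exposure_fit(df, "y", covariates = character(0))
  expect_lt(abs(joint$estimate[joint$class == "2"] -
                  single$estimate[single$class == "2"]), 0.5)

  # outcome fully driven by AC: HC effects shrink to null
  set.seed(17)
  df$y2 <- 30 + 6 * (df$ac_class == "2") + rnorm(nrow(df), 0, 1)
  joint2 <- multi_exposure_fit(df, "y2", covariates = character(0))
  expect_lt(max(abs(joint2$estimate)), 0.3)

  # perfectly aliased assignments cannot be separated
  df$ac_class <- df$hc_class
  expect_error(multi_exposure_fit(df, "y", covariates = character(0)),
               "rank deficient")
})
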
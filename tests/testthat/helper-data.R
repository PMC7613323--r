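# Shared synthetic configurations used across test files.

# three well-separated classes (separation 2 z-units across the window),
# study-scale variances; used for recovery and selection checks
config_3class <- function(N = 500, seed = 1) {
  synth_config(
    N = N,
    class_proportions = c(0.5, 0.3, 0.2),
    class_labels = c("A", "B", "C"),
    beta = rbind(c(0, 0, 0, 0),
                 c(2, 2.2, 2, 1.8),
                 c(-2, -1.8, -2, -2.2)),
    sigma_b = 0.4, sigma_e = 0.3, seed = seed)
}

# generate, QC and eligibility-filter in one step
make_cohort <- function(config, seed = NULL) {
  d <- generate_cohort(config, seed)
  el <- eligibility_filter(qc_filter(d$scans)$kept)
  list(cohort = el, truth = d$truth, outcomes = d$outcomes,
       scans = d$scans)
}

# subject-level covariate frame for outcome-model tests
make_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("C%05d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_assess_months = round(rnorm(n, 25, 1.8), 1),
    preterm = rbinom(n, 1, 0.09),
    maternal_age = round(rnorm(n, 29, 5), 1),
    maternal_education = sample(c("primary", "secondary", "university"), n,
                                replace = TRUE),
    smoking = rbinom(n, 1, 0.05))
}
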
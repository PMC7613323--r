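# hctraj

Latent-class trajectory modelling of fetal cranial growth, and its
consequences at age 2.

## What it does, and for whom

`hctraj` is for perinatal epidemiologists and biostatisticians analysing
serial ultrasound biometry. Given longitudinal fetal head-circumference
(HC) measurements expressed as sex- and gestational-age-specific z-scores,
it:

1. applies the standard QC and eligibility rules (|z| > 5 excluded,
   analysis window 14–37 weeks, at least 3 scans per fetus);
2. fits a **latent-class linear mixed model**: a G-component mixture in
   which class g has mean trajectory $B(t)^\top\beta_g$ on a quadratic
   B-spline basis (one internal knot at the pooled median scan age) and
   every subject carries a shared random intercept, giving the
   compound-symmetry covariance $V_i = \sigma_b^2 J + \sigma^2 I$. The
   marginal mixture likelihood
   $\sum_i \log \sum_g \pi_g\, \varphi(y_i; X_i\beta_g, V_i)$
   is maximised by a restarted EM algorithm on the structured
   (O(n) per subject) covariance forms;
3. selects the number of classes by BIC
   ($-2\ell + k\log N$, $k = (G-1)+Gp+2$, N = subjects) subject to a
   smallest-class rule (every modal class ≥ 2.5% of the sample), and
   reports the APP and OCC classification diagnostics;
4. estimates class-specific associations with 2-year outcomes — linear
   regression for continuous scores and growth z-scores, modified Poisson
   (log-link, overdispersion-corrected) relative risks for binary and
   count outcomes, Cox proportional hazards for motor-milestone ages —
   with Benjamini–Hochberg FDR control, breastfeeding effect-modification,
   sensitivity exclusions and joint HC+AC exposure models;
5. generates seeded **synthetic cohorts** with the study's longitudinal
   structure and known ground truth, so the whole pipeline is testable
   without access to individual-level cohort data.

## Worked example

```r
library(hctraj)

d <- generate_cohort(synth_config(seed = 1))   # N = 3200, five classes
scans <- eligibility_filter(qc_filter(d$scans)$kept)

spec <- place_knots(scans$ga_weeks)
report <- select_model(scans, spec, G_grid = c(3, 4, 5),
                       config = fit_config(n_restarts = 3, seed = 2))
fit <- report$fits[[as.character(report$selected_G)]]
print(fit)
```

```
Latent-class linear mixed model fit
  subjects: 3197   classes: 5   basis dim: 4
  loglik: -8989.547   BIC: 18188.914   converged: TRUE (116 iter)
  pi: 0.634 0.127 0.105 0.075 0.059
  sigma_b: 0.4209   sigma_e: 0.3024
  APP: 0.820 0.753 0.744 0.774 0.714
  OCC: 2.63 21.07 24.70 42.43 39.50
```

Class 1 — the largest, median-tracking class — is the reference. `pi` are
the estimated class probabilities, `sigma_b`/`sigma_e` the random-intercept
and residual SDs in z-units. APP is each class's average posterior
probability among its assigned members and OCC the odds of correct
classification (>1 beats chance). `plot(fit)` draws the five mean
trajectories; `truth_recovery_report(fit, d$truth)` scores the fit against
the generating truth (here: 78% modal-assignment accuracy after label
matching, trajectory RMSE ≤ 0.06 z).

Association models then quantify what trajectory membership means at age
2, for example:

```r
out <- d$outcomes
out$hc_class <- fit$assignments[match(out$subject_id, names(fit$assignments))]
fit_linear(out, "language")[, c("class", "estimate", "ci_low", "ci_high")]
```

```
  class  estimate    ci_low    ci_high
1     2  3.219221  1.677859  4.7605821
2     3 -6.643831 -8.348206 -4.9394564
3     4  4.166751  2.300487  6.0330150
4     5 -3.311825 -5.758238 -0.8654126
```

the adjusted language-score difference of each class against the
reference: fitted class 3 matches the generating early-faltering class
(injected effect −7.16, estimated −6.6 — attenuated by classification
error), classes 2 and 4 the two accelerated classes with their positive
effects.

The one-call driver `run_pipeline(pipeline_config(...))` chains QC, knot
placement, selection, classification, all outcome families and FDR,
writing CSV/JSON artifacts plus a run manifest.

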
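#' Pipeline configuration
#'
#' Bundles every stage's settings. Scan and outcome tables may be supplied
#' as data.frames or CSV paths (comma-separated, UTF-8, header row, empty
#' fields for missing values).
#'
#' @param scans long scan table (data.frame or CSV path): subject_id,
#'   ga_weeks, sex, measure, and z (or value_mm plus a `standard`).
#' @param outcomes subject-level outcome table (data.frame or CSV path).
#' @param out_dir output directory (created if absent); NULL disables file
#'   output.
#' @param window a [cohort_window()].
#' @param spec optional [spline_spec()]; default places the internal knot at
#'   the pooled median scan age after filtering.
#' @param standard optional [reference_standard()] used when `z` is absent.
#' @param G_grid class-count grid for selection.
#' @param min_share smallest-class eligibility share.
#' @param fit a [fit_config()].
#' @param linear_outcomes,count_outcomes,binary_outcomes,milestones outcome
#'   names per regression family (milestones expect `<name>_age` /
#'   `<name>_event` columns).
#' @param covariates adjustment covariates.
#' @param fdr_q false-discovery-rate level applied across the non-milestone
#'   outcome-by-class p-value grid.
#' @param positive_behavior_scale_max scale maximum used to reverse-code the
#'   positive-behaviour score before count modelling.
#' @param seed integer seed.
#' @export
pipeline_config <- function(scans, outcomes = NULL, out_dir = NULL,
                            window = cohort_window(), spec = NULL,
                            standard = NULL,
                            G_grid = c(3, 4, 5), min_share = 0.025,
                            fit = fit_config(),
                            linear_outcomes = c("cognitive", "language",
                                                "fine_motor", "gross_motor",
                                                "attentional_problems",
                                                "emotional_reactivity",
                                                "height_z", "weight_z",
                                                "hc_z", "bmi_z"),
                            count_outcomes = c("negative_behavior",
                                               "positive_behavior_reversed"),
                            binary_outcomes = c("acuity_low",
                                                "contrast_low"),
                            milestones = c("sitting", "crawling",
                                           "standing_with_help",
                                           "standing_alone",
                                           "walking_with_help",
                                           "walking_alone"),
                            covariates = default_covariates(),
                            fdr_q = 0.05,
                            positive_behavior_scale_max = 30,
                            seed = 1L) {
  for (x in list(scans, outcomes))
    if (is.character(x) && !file.exists(x))
      stop("input file does not exist: ", x, call. = FALSE)
  structure(list(scans = scans, outcomes = outcomes, out_dir = out_dir,
                 window = window, spec = spec, standard = standard,
                 G_grid = G_grid, min_share = min_share, fit = fit,
                 linear_outcomes = linear_outcomes,
                 count_outcomes = count_outcomes,
                 binary_outcomes = binary_outcomes,
                 milestones = milestones, covariates = covariates,
                 fdr_q = fdr_q,
                 positive_behavior_scale_max = positive_behavior_scale_max,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.read_table <- function(x) {
  if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
}

#' Run the full trajectory-and-outcomes pipeline
#'
#' Sequence: z-scoring (if needed) -> QC filter -> eligibility filter ->
#' knot placement -> class-count selection -> classification and
#' diagnostics -> outcome association models -> FDR correction. Every
#' stage's output is written under `out_dir` (when set) together with a run
#' manifest (configuration echo, seed, package version, stage timings).
#'
#' @param config a [pipeline_config()].
#' @return invisible list: `qc`, `eligible`, `spec`, `selection`, `fit`,
#'   `associations`, `manifest`.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "pipeline_config"),
          "config must be a pipeline_config")
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  scans <- .read_table(config$scans)
  if (!"z" %in% names(scans) || any(!is.finite(scans$z))) {
    .assert(!is.null(config$standard),
            "scans lack z-scores and no reference standard was supplied")
    scans$z <- compute_zscore(scans$value_mm, scans$ga_weeks, scans$sex,
                              config$standard)
  }
  qc <- qc_filter(scans, config$window)
  eligible <- eligibility_filter(qc$kept, config$window)
  .assert(nrow(eligible) > 0, "no eligible subjects after QC")
  tick("qc")

  spec <- if (is.null(config$spec))
    place_knots(eligible$ga_weeks, c(config$window$ga_min,
                                     config$window$ga_max))
  else config$spec
  selection <- select_model(eligible, spec, config$G_grid,
                            config$min_share, config$fit)
  .assert(!selection$failed, "model selection failed: no eligible fit")
  fit <- selection$fits[[as.character(selection$selected_G)]]
  tick("model")

  associations <- NULL
  if (!is.null(config$outcomes)) {
    out <- .read_table(config$outcomes)
    out$hc_class <- fit$assignments[match(out$subject_id,
                                          names(fit$assignments))]
    out <- out[!is.na(out$hc_class), , drop = FALSE]
    if ("positive_behavior" %in% names(out) &&
        "positive_behavior_reversed" %in% config$count_outcomes)
      out$positive_behavior_reversed <-
        reverse_code(out$positive_behavior,
                     config$positive_behavior_scale_max)
    res <- list()
    for (nm in intersect(config$linear_outcomes, names(out)))
      res[[length(res) + 1]] <- fit_linear(out, nm, "hc_class",
                                           config$covariates)
    for (nm in intersect(c(config$count_outcomes, config$binary_outcomes),
                         names(out)))
      res[[length(res) + 1]] <- fit_modified_poisson(out, nm, "hc_class",
                                                     config$covariates)
    for (nm in config$milestones) {
      ac <- paste0(nm, "_age"); ev <- paste0(nm, "_event")
      if (all(c(ac, ev) %in% names(out)))
        res[[length(res) + 1]] <- fit_cox(out, ac, ev, "hc_class",
                                          setdiff(config$covariates,
                                                  "age_assess_months"))
    }
    associations <- do.call(rbind, res)
    # FDR across the primary (non-milestone) outcome x class grid
    primary <- associations$family != "cox"
    associations$p_adjusted <- NA_real_
    if (any(primary)) {
      fdr <- bh_fdr(associations$p_value[primary], config$fdr_q)
      associations$p_adjusted[primary] <- fdr$p_adjusted
      associations$fdr_reject <- FALSE
      associations$fdr_reject[primary] <- fdr$reject
    }
    tick("associations")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hctraj")),
    seed = config$seed,
    n_scans_input = nrow(scans), qc_counts = as.list(qc$counts),
    n_eligible_subjects = length(unique(eligible$subject_id)),
    internal_knots = spec$internal_knots,
    boundary_knots = spec$boundary_knots,
    G_grid = config$G_grid, min_share = config$min_share,
    selected_G = selection$selected_G,
    timings_sec = as.list(timings))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(f) file.path(config$out_dir, f)
    write.csv(rbind(qc$kept, qc$removed), wp("scans_qc.csv"),
              row.names = FALSE)
    write.csv(qc$removed, wp("exclusions.csv"), row.names = FALSE)
    write_selection_report(selection, wp("selection.csv"))
    write_lcmm_fit(fit, wp("fit.json"))
    write.csv(posterior_table(fit), wp("posteriors.csv"),
              row.names = FALSE)
    if (!is.null(associations))
      write.csv(associations, wp("associations.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, wp("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  invisible(list(qc = qc, eligible = eligible, spec = spec,
                 selection = selection, fit = fit,
                 associations = associations, manifest = manifest))
}
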
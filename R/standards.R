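#' Reference growth standard
#'
#' A pluggable sex- and gestational-age-specific reference standard, given as a
#' pair of functions returning the expected measurement (mm) and its standard
#' deviation (mm) at a gestational age. The published international fetal
#' growth standard equations are external to this package; any standard with
#' this interface can be supplied.
#'
#' @param mean_fn function(ga_weeks, sex) returning the reference mean in mm.
#' @param sd_fn function(ga_weeks, sex) returning the reference SD in mm;
#'   must be strictly positive over `ga_range`.
#' @param ga_range length-2 numeric, the gestational-age domain (weeks) over
#'   which the standard is defined.
#' @return An object of class `reference_standard`.
#' @examples
#' std <- reference_standard(function(ga, sex) 10 * ga,
#'                           function(ga, sex) ga, c(14, 40))
#' compute_zscore(300, 25, "female", std)
#' @export
reference_standard <- function(mean_fn, sd_fn, ga_range) {
  .assert(is.function(mean_fn) && is.function(sd_fn),
          "mean_fn and sd_fn must be functions")
  .assert(length(ga_range) == 2 && ga_range[1] < ga_range[2],
          "ga_range must be an increasing length-2 numeric")
  structure(list(mean_fn = mean_fn, sd_fn = sd_fn,
                 ga_range = as.numeric(ga_range)),
            class = "reference_standard")
}

#' Identity standard for data already on the z-scale
#'
#' Mean 0, SD 1 at every gestational age: z-scoring against it returns the
#' input unchanged. Used for synthetic cohorts generated directly as z-scores.
#' @export
identity_standard <- function() {
  reference_standard(function(ga, sex) rep(0, length(ga)),
                     function(ga, sex) rep(1, length(ga)),
                     c(0, 60))
}

#' Sex- and gestational-age-specific z-score
#'
#' `z = (value - mean_fn(ga, sex)) / sd_fn(ga, sex)`. Vectorised over
#' `value`/`ga_weeks`/`sex`.
#'
#' @param value measurement in mm.
#' @param ga_weeks gestational age in decimal weeks.
#' @param sex "male" or "female" (passed through to the standard's functions).
#' @param standard a [reference_standard()].
#' @return numeric vector of z-scores.
#' @export
compute_zscore <- function(value, ga_weeks, sex, standard) {
  .assert(inherits(standard, "reference_standard"),
          "standard must be a reference_standard")
  .assert(all(is.finite(ga_weeks)) && all(ga_weeks > 0),
          "ga_weeks must be positive and finite")
  if (any(ga_weeks < standard$ga_range[1] | ga_weeks > standard$ga_range[2]))
    stop("gestational age outside the reference standard's domain [",
         standard$ga_range[1], ", ", standard$ga_range[2], "]", call. = FALSE)
  mu <- standard$mean_fn(ga_weeks, sex)
  sdv <- standard$sd_fn(ga_weeks, sex)
  if (any(!is.finite(sdv)) || any(sdv <= 0))
    stop("reference standard returned a non-positive SD", call. = FALSE)
  (value - mu) / sdv
}

#' Inverse of [compute_zscore()]
#'
#' Maps a z-score back to the measurement scale of the standard.
#' @inheritParams compute_zscore
#' @param z z-score.
#' @export
invert_zscore <- function(z, ga_weeks, sex, standard) {
  .assert(inherits(standard, "reference_standard"),
          "standard must be a reference_standard")
  standard$mean_fn(ga_weeks, sex) + z * standard$sd_fn(ga_weeks, sex)
}

#' Analysis window and eligibility rules
#'
#' @param ga_min,ga_max inclusive gestational-age window in weeks; scans
#'   outside it are excluded.
#' @param min_scans minimum number of in-window, QC-passing scans a subject
#'   must have to enter the trajectory analysis.
#' @param z_abs_max absolute z-score bound; |z| strictly greater is excluded
#'   (|z| equal to the bound is kept).
#' @return An object of class `cohort_window`.
#' @export
cohort_window <- function(ga_min = 14, ga_max = 37, min_scans = 3,
                          z_abs_max = 5) {
  .assert(ga_min < ga_max, "ga_min must be < ga_max")
  .assert(min_scans >= 1, "min_scans must be >= 1")
  .assert(z_abs_max > 0, "z_abs_max must be > 0")
  structure(list(ga_min = ga_min, ga_max = ga_max,
                 min_scans = as.integer(min_scans), z_abs_max = z_abs_max),
            class = "cohort_window")
}

#' Quality-control filter on scan records
#'
#' Removes scans with |z| strictly above the bound or gestational age outside
#' the inclusive analysis window. The two output sets partition the input
#' exactly; a `qc_flag` column records the reason for removal.
#'
#' @param records data.frame with at least `subject_id`, `ga_weeks`, `z`.
#' @param window a [cohort_window()].
#' @return list with elements `kept` and `removed` (both data.frames carrying
#'   a `qc_flag` column: "pass", "extreme_z" or "out_of_window") and `counts`.
#' @export
qc_filter <- function(records, window = cohort_window()) {
  .assert(is.data.frame(records), "records must be a data.frame")
  .assert(all(c("subject_id", "ga_weeks", "z") %in% names(records)),
          "records needs columns subject_id, ga_weeks, z")
  if (any(!is.finite(records$z)))
    stop("all records must have a finite z-score before QC", call. = FALSE)
  extreme <- abs(records$z) > window$z_abs_max
  outside <- records$ga_weeks < window$ga_min | records$ga_weeks > window$ga_max
  flag <- ifelse(extreme, "extreme_z",
                 ifelse(outside, "out_of_window", "pass"))
  records$qc_flag <- flag
  keep <- flag == "pass"
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE],
       counts = c(input = nrow(records), kept = sum(keep),
                  extreme_z = sum(extreme),
                  out_of_window = sum(outside & !extreme)))
}

#' Eligibility filter: minimum number of scans per subject
#'
#' Subjects with fewer than `window$min_scans` retained scans are dropped
#' entirely; applied after [qc_filter()].
#'
#' @inheritParams qc_filter
#' @return data.frame of records for eligible subjects, with an attribute
#'   `scan_counts` (named integer vector, all input subjects).
#' @export
eligibility_filter <- function(records, window = cohort_window()) {
  .assert(is.data.frame(records), "records must be a data.frame")
  if (nrow(records) == 0) {
    attr(records, "scan_counts") <- integer(0)
    return(records)
  }
  counts <- table(records$subject_id)
  keep_ids <- names(counts)[counts >= window$min_scans]
  out <- records[records$subject_id %in% keep_ids, , drop = FALSE]
  attr(out, "scan_counts") <- setNames(as.integer(counts), names(counts))
  out
}
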
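#' Select the number of latent classes
#'
#' Fits the latent-class model over a grid of class counts and applies the
#' two selection criteria: lowest BIC among fits whose smallest modal class
#' contains at least `min_share` of the sample. The share is computed on
#' modal assignments (participants counted per assigned group), not on the
#' estimated mixture weights. BIC ties within 1e-6 break toward smaller G.
#'
#' @param cohort long data.frame (`subject_id`, `ga_weeks`, `z`).
#' @param spec a [spline_spec()].
#' @param G_grid integer vector of class counts to fit.
#' @param min_share minimum fraction of subjects in the smallest modal class
#'   for a fit to be eligible.
#' @param config a [fit_config()].
#' @return An object of class `model_selection_report`: `fits` (named list by
#'   G), `log` (per-G data.frame: G, loglik, k, bic, min_class_share,
#'   eligible), `selected_G` (NA if no fit is eligible), `failed` flag.
#' @export
select_model <- function(cohort, spec, G_grid = c(3, 4, 5),
                         min_share = 0.025, config = fit_config()) {
  .assert(length(G_grid) > 0, "G_grid must be non-empty")
  G_grid <- sort(unique(as.integer(G_grid)))
  fits <- list()
  rows <- vector("list", length(G_grid))
  for (j in seq_along(G_grid)) {
    G <- G_grid[j]
    fit <- fit_lcmm(cohort, spec, G, config)
    fits[[as.character(G)]] <- fit
    share <- min(fit$n_per_class) / fit$N
    rows[[j]] <- data.frame(G = G, loglik = fit$loglik, k = fit$k,
                            bic = fit$bic, min_class_share = share,
                            eligible = share >= min_share)
  }
  log <- do.call(rbind, rows)
  selected_G <- NA_integer_
  failed <- TRUE
  if (any(log$eligible)) {
    el <- log[log$eligible, , drop = FALSE]
    bmin <- min(el$bic)
    cand <- el$G[el$bic <= bmin + 1e-6]
    selected_G <- min(cand)
    failed <- FALSE
  }
  structure(list(fits = fits, log = log, selected_G = selected_G,
                 failed = failed, min_share = min_share),
            class = "model_selection_report")
}

#' @export
print.model_selection_report <- function(x, ...) {
  cat("Latent-class model selection\n")
  print(x$log, row.names = FALSE)
  if (x$failed)
    cat(sprintf("No fit satisfies the %.1f%% smallest-class rule.\n",
                100 * x$min_share))
  else
    cat(sprintf("Selected: G = %d (lowest BIC among eligible fits)\n",
                x$selected_G))
  invisible(x)
}

#' Write the selection log to CSV
#' @param report a `model_selection_report`.
#' @param path output CSV path.
#' @export
write_selection_report <- function(report, path) {
  write.csv(report$log, path, row.names = FALSE)
  invisible(path)
}
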
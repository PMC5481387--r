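#' Analyse one ROI end to end
#'
#' Convenience wrapper around [bayes_cluster()] that optionally writes the
#' per-point, per-cluster and summary outputs (see [write_results()]) plus
#' the axial profile, and logs the winning proposal.
#'
#' @inheritParams bayes_cluster
#' @param out_dir Output directory; `NULL` (default) writes nothing.
#' @param verbose Log progress and the winning (r, T, K, score) via
#'   `message()`.
#' @return The [bayes_cluster()] fit, invisibly when `out_dir` is given.
#' @export
analyze_roi <- function(locs, roi, config = model_config(),
                        grid = sweep_grid(), out_dir = NULL,
                        verbose = FALSE) {
  fit <- bayes_cluster(locs, roi, config = config, grid = grid)
  if (verbose) {
    message(sprintf(
      "MAP proposal: r = %s, T = %s, K = %d, log score = %.2f (%d proposals scored)",
      format(fit$best$r), format(fit$best$t), fit$best$k,
      fit$best$log_score, nrow(fit$scored)))
  }
  if (!is.null(out_dir)) {
    write_results(fit, out_dir)
    readr::write_csv(z_profile(fit), file.path(out_dir, "z_profile.csv"))
    return(invisible(fit))
  }
  fit
}

#' Evaluate recovery over a batch of simulated ROIs
#'
#' Runs [recovery_metrics()] for each matched (simulation, fit) pair and
#' appends condition-level means and standard errors.
#'
#' @param sims List of [simulate_roi()] results.
#' @param fits List of [bayes_cluster()] fits, same length and order.
#' @return A list with `per_roi` (one recovery row per ROI) and `summary`
#'   (mean and SEM of each recovery column).
#' @export
evaluate_recovery <- function(sims, fits) {
  if (length(sims) != length(fits)) {
    stop("sims and fits must be matched lists of equal length", call. = FALSE)
  }
  per_roi <- dplyr::bind_rows(purrr::map2(sims, fits, recovery_metrics))
  vars <- names(per_roi)
  summary <- purrr::map_dfr(vars, function(v) {
    vals <- per_roi[[v]][is.finite(per_roi[[v]])]
    tibble::tibble(
      metric = v,
      mean = if (length(vals) > 0) mean(vals) else NA_real_,
      sem = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0)
  })
  list(per_roi = per_roi, summary = summary)
}
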
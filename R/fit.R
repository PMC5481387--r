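#' Bayesian cluster analysis of a 3D localization table
#'
#' Runs the full method on one ROI: fit the axial background model (unless
#' configured uniform), generate cluster proposals over the (r, T) sweep
#' grid, score every distinct proposal under the generative model, and retain
#' the maximum a posteriori proposal. The returned fit supports
#' [generics::tidy()] (per-cluster descriptors), [generics::glance()]
#' (per-ROI descriptors), [generics::augment()] (per-point labels and L
#' values) and [ggplot2::autoplot()].
#'
#' @param locs Localization tibble with the canonical columns (see
#'   [read_localizations()]); coordinates must already be ROI-local.
#' @param roi An [roi()] object.
#' @param config A [model_config()].
#' @param grid A [sweep_grid()].
#' @param proposals Optional precomputed [sweep_proposals()] tibble (lets the
#'   same proposal set be scored under different model configurations).
#' @return An object of class `"bayes_cluster3d"`.
#' @examples
#' sim <- simulate_roi(standard_condition(seed = 1))
#' \donttest{
#' fit <- bayes_cluster(sim$locs, roi(3000, 3000, 600))
#' generics::glance(fit)
#' }
#' @export
bayes_cluster <- function(locs, roi, config = model_config(),
                          grid = sweep_grid(), proposals = NULL) {
  locs <- validate_localizations(locs[loc_columns()])
  stopifnot(inherits(roi, "roi"), inherits(config, "model_config"))
  z_model <- if (config$z_mode == "fit") fit_beta_z(locs, roi) else
    z_background(1, 1)
  if (nrow(locs) < 2) {
    # degenerate ROI: only the all-background labelling exists
    proposals <- tibble::tibble(r = NA_real_, t = NA_real_, k = 0L,
                                labels = list(rep(0L, nrow(locs))))
  }
  if (is.null(proposals)) {
    proposals <- sweep_proposals(locs, roi, grid,
                                 min_cluster_size = config$min_cluster_size)
  }
  scored <- score_sweep(proposals, locs, roi, config, z_model = z_model)
  best <- select_best(scored)
  labels <- best$labels[[1]]
  l3d <- rep(NA_real_, nrow(locs))
  if (is.finite(best$r)) l3d <- local_l3d(locs, roi, best$r)$l3d
  fit <- structure(list(
    locs = locs, roi = roi, config = config, z_model = z_model,
    labels = as.integer(labels), l3d = l3d,
    best = list(r = best$r, t = best$t, k = best$k,
                log_score = best$log_score),
    scored = dplyr::select(scored, -"labels")
  ), class = "bayes_cluster3d")
  fit$per_cluster <- cluster_descriptors(fit)
  fit
}

#' @export
print.bayes_cluster3d <- function(x, ...) {
  g <- generics::glance(x)
  cat("<bayes_cluster3d>\n")
  cat(sprintf("  n = %d localizations in %g x %g x %g nm ROI\n",
              g$n, x$roi$Lx, x$roi$Ly, x$roi$Lz))
  cat(sprintf("  MAP proposal: r = %s nm, T = %s nm, log score = %.2f\n",
              format(x$best$r), format(x$best$t), x$best$log_score))
  cat(sprintf("  %d cluster(s), %.1f%% of localizations clustered\n",
              g$k, g$percent_in_clusters))
  if (g$k > 0) {
    cat(sprintf("  mean %.1f localizations/cluster, mean radius %.1f nm\n",
                g$mean_locs_per_cluster, g$mean_radius))
  }
  invisible(x)
}

#' @rdname bayes_cluster
#' @param x A `bayes_cluster3d` fit.
#' @param ... Unused.
#' @export
tidy.bayes_cluster3d <- function(x, ...) {
  x$per_cluster
}

#' @rdname bayes_cluster
#' @export
glance.bayes_cluster3d <- function(x, ...) {
  n <- nrow(x$locs)
  n_cl <- sum(x$labels > 0)
  pc <- x$per_cluster
  tibble::tibble(
    n = n,
    k = length(unique(x$labels[x$labels > 0])),
    percent_in_clusters = if (n > 0) 100 * n_cl / n else 0,
    mean_locs_per_cluster = if (nrow(pc) > 0) mean(pc$n_points) else NA_real_,
    mean_radius = if (nrow(pc) > 0) mean(pc$map_radius) else NA_real_,
    r = x$best$r, t = x$best$t, log_score = x$best$log_score,
    z_alpha = x$z_model$alpha, z_beta = x$z_model$beta
  )
}

#' @rdname bayes_cluster
#' @export
augment.bayes_cluster3d <- function(x, ...) {
  out <- x$locs
  out$cluster <- x$labels
  out$l3d <- x$l3d
  out
}

#' @rdname bayes_cluster
#' @param object A `bayes_cluster3d` fit.
#' @export
autoplot.bayes_cluster3d <- function(object, ...) {
  df <- generics::augment(object)
  df$clustered <- df$cluster > 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(
      data = df[!df$clustered, ], colour = "grey70", size = 0.8) +
    ggplot2::geom_point(
      data = df[df$clustered, ],
      ggplot2::aes(colour = factor(.data$cluster), size = .data$z)) +
    ggplot2::scale_size_continuous(range = c(0.8, 2.5), name = "z (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", colour = "cluster") +
    ggplot2::theme_minimal()
}
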
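#' Per-cluster descriptors of a fit
#'
#' For each detected cluster: the number of member localizations, the MAP
#' radius (the radius-prior bin maximising that cluster's marginal term — the
#' model-consistent estimate of the Gaussian standard deviation "radius"),
#' the precision-weighted centroid (weights `1 / (s*^2 + sigma^2)` per
#' dimension at the MAP radius), and the empirical per-axis RMS radius.
#'
#' @param fit A [bayes_cluster()] fit.
#' @return A tibble with one row per cluster: `cluster`, `n_points`, `x`,
#'   `y`, `z`, `map_radius`, `rms_radius`.
#' @export
cluster_descriptors <- function(fit) {
  stopifnot(inherits(fit, "bayes_cluster3d"))
  ids <- sort(unique(fit$labels[fit$labels > 0]))
  rows <- lapply(ids, function(k) {
    pts <- fit$locs[fit$labels == k, , drop = FALSE]
    lm <- log_marginal_cluster(pts, fit$roi, fit$z_model,
                               fit$config$radius_prior)
    terms <- log(fit$config$radius_prior$w) + attr(lm, "log_terms")
    b <- which.max(terms)
    s_map <- fit$config$radius_prior$s[b]
    coords <- as.matrix(pts[c("x", "y", "z")])
    w <- 1 / (s_map^2 + as.matrix(pts[c("sigma_x", "sigma_y", "sigma_z")])^2)
    centroid <- colSums(coords * w) / colSums(w)
    rms <- sqrt(mean(sweep(coords, 2, centroid)^2))
    tibble::tibble(cluster = k, n_points = nrow(pts),
                   x = centroid[1], y = centroid[2], z = centroid[3],
                   map_radius = s_map, rms_radius = rms)
  })
  if (length(rows) == 0) {
    return(tibble::tibble(cluster = integer(0), n_points = integer(0),
                          x = numeric(0), y = numeric(0), z = numeric(0),
                          map_radius = numeric(0), rms_radius = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' Axial (z) clustering profile
#'
#' Bins the ROI's z extent (30 nm bins by default, truncating the final bin
#' if the bin width does not divide Lz) and reports, per bin, the fraction of
#' clusters whose centroid falls in the bin and the percentage of the bin's
#' localizations that are clustered (per-bin normalisation).
#'
#' @param fit A [bayes_cluster()] fit.
#' @param bin_width Bin width in nm (default 30).
#' @return A tibble with columns `z_lo`, `z_hi`, `n_locs`, `n_clustered`,
#'   `percent_in_clusters`, `n_cluster_centroids`, `cluster_fraction`.
#' @export
z_profile <- function(fit, bin_width = 30) {
  stopifnot(inherits(fit, "bayes_cluster3d"), bin_width > 0)
  Lz <- fit$roi$Lz
  edges <- unique(c(seq(0, Lz, by = bin_width), Lz))
  bin_of <- function(z) pmin(findInterval(z, edges, left.open = FALSE),
                             length(edges) - 1L)
  loc_bin <- bin_of(fit$locs$z)
  pc <- fit$per_cluster
  cen_bin <- if (nrow(pc) > 0) bin_of(pc$z) else integer(0)
  k <- nrow(pc)
  out <- tibble::tibble(
    z_lo = edges[-length(edges)],
    z_hi = edges[-1],
    n_locs = tabulate(loc_bin, nbins = length(edges) - 1L),
    n_clustered = tabulate(loc_bin[fit$labels > 0],
                           nbins = length(edges) - 1L),
    n_cluster_centroids = tabulate(cen_bin, nbins = length(edges) - 1L)
  )
  dplyr::mutate(out,
    percent_in_clusters = ifelse(.data$n_locs > 0,
                                 100 * .data$n_clustered / .data$n_locs, 0),
    cluster_fraction = if (k > 0) .data$n_cluster_centroids / k else 0)
}

#' Plot an axial clustering profile
#'
#' @param profile A tibble from [z_profile()].
#' @param what `"localisations"` (percentage of localizations in clusters per
#'   z bin) or `"clusters"` (fraction of cluster centroids per z bin).
#' @return A ggplot object.
#' @export
plot_z_profile <- function(profile, what = c("localisations", "clusters")) {
  what <- match.arg(what)
  yvar <- if (what == "localisations") "percent_in_clusters" else
    "cluster_fraction"
  ylab <- if (what == "localisations") "% localizations in clusters" else
    "fraction of clusters"
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = (.data$z_lo + .data$z_hi) / 2,
                               y = .data[[yvar]])) +
    ggplot2::geom_col(width = (profile$z_hi - profile$z_lo) * 0.9,
                      fill = "steelblue") +
    ggplot2::labs(x = "z (nm)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Condition-level summary across ROIs
#'
#' Aggregates per-ROI descriptors (the [generics::glance()] rows of a batch
#' of fits) into condition-level means with standard errors of the mean.
#' With a single ROI the SEM is undefined and reported as 0 with
#' `sem_defined = FALSE`.
#'
#' @param fits A list of [bayes_cluster()] fits, or a tibble of their
#'   `glance()` rows.
#' @return A list with `per_roi` (one glance row per ROI) and `summary`
#'   (descriptor, mean, sem, sem_defined, n_roi).
#' @export
batch_summary <- function(fits) {
  per_roi <- if (is.data.frame(fits)) tibble::as_tibble(fits) else
    dplyr::bind_rows(lapply(fits, generics::glance))
  stopifnot(nrow(per_roi) >= 1)
  vars <- intersect(c("n", "k", "percent_in_clusters",
                      "mean_locs_per_cluster", "mean_radius"),
                    names(per_roi))
  n_roi <- nrow(per_roi)
  summary <- purrr::map_dfr(vars, function(v) {
    vals <- per_roi[[v]][is.finite(per_roi[[v]])]
    m <- if (length(vals) > 0) mean(vals) else NA_real_
    sem_defined <- length(vals) > 1
    tibble::tibble(
      descriptor = v, mean = m,
      sem = if (sem_defined) stats::sd(vals) / sqrt(length(vals)) else 0,
      sem_defined = sem_defined, n_roi = n_roi)
  })
  list(per_roi = per_roi, summary = summary)
}
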
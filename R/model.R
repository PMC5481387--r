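#' Axial (z) background model
#'
#' The x/y positions of cluster centres and of non-clustered molecules are
#' modelled as completely spatially random; the z positions follow a Beta
#' distribution on `z / Lz`, which captures membrane-proximal or otherwise
#' uneven axial densities. `z_background(1, 1)` is the uniform model.
#'
#' @param alpha,beta Beta shape parameters; both strictly positive.
#' @return An object of class `"z_background"`.
#' @export
z_background <- function(alpha = 1, beta = 1) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    stop("Beta shape parameters must be finite and positive", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta), class = "z_background")
}

#' @export
print.z_background <- function(x, ...) {
  cat(sprintf("<z_background> Beta(alpha = %.4g, beta = %.4g)\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Fit the Beta z-background model to a localization table
#'
#' Maximum-likelihood Beta fit on the scaled axial coordinates `u = z / Lz`
#' (clamped to `[1e-6, 1 - 1e-6]`). The fitted distribution is used as the
#' prior for both cluster-centre and background z positions. With fewer than
#' `min_n` points the fit is unreliable and the uniform model Beta(1, 1) is
#' returned; if the likelihood optimisation fails, a method-of-moments
#' estimate is used instead (with a warning).
#'
#' @param locs Localization tibble.
#' @param roi An [roi()] object.
#' @param min_n Minimum number of points for fitting (default 10).
#' @return A [z_background()] object.
#' @export
fit_beta_z <- function(locs, roi, min_n = 10) {
  n <- nrow(locs)
  if (n < min_n) return(z_background(1, 1))
  eps <- 1e-6
  u <- pmin(pmax(locs$z / roi$Lz, eps), 1 - eps)
  fit <- tryCatch({
    f <- suppressWarnings(fitdistrplus::fitdist(u, "beta"))
    z_background(unname(f$estimate["shape1"]), unname(f$estimate["shape2"]))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("Beta MLE did not converge; using method-of-moments estimate",
            call. = FALSE)
    m <- mean(u)
    v <- stats::var(u)
    v <- min(v, m * (1 - m) * (1 - 1e-6))  # keep the MoM solution positive
    common <- m * (1 - m) / v - 1
    fit <- z_background(m * common, (1 - m) * common)
  }
  fit
}

#' Log background density of localizations
#'
#' Density of a non-clustered localization: uniform over x and y, Beta over
#' `z / Lz`, i.e. `-log(Lx) - log(Ly) + log BetaPDF(z/Lz) - log(Lz)` per
#' point (units: per nm^3). With the uniform z model this reduces to
#' `-log(V)`. The localization error is not convolved into the background
#' density: a uniform convolved with a ~30 nm Gaussian differs from uniform
#' only within ~30 nm of the ROI faces.
#'
#' @param locs Localization tibble (or any data frame with a `z` column).
#' @param roi An [roi()] object.
#' @param z_model A [z_background()] object.
#' @return Numeric vector of per-point log densities.
#' @export
log_background_density <- function(locs, roi, z_model = z_background()) {
  stopifnot(inherits(z_model, "z_background"))
  -log(roi$Lx) - log(roi$Ly) - log(roi$Lz) +
    stats::dbeta(locs$z / roi$Lz, z_model$alpha, z_model$beta, log = TRUE)
}

#' Prior histogram over cluster radii
#'
#' The model's cluster "radius" is the standard deviation s of the spherical
#' Gaussian describing molecular positions within a cluster; s is drawn from
#' a user-specified histogram. The default is uniform over 5..100 nm in 5-nm
#' bins — the least-informative concrete choice over plausible SMLM cluster
#' scales.
#'
#' @param breaks Bin centres s_b in nm (strictly positive).
#' @param weights Non-negative weights, normalised to sum to 1.
#' @return An object of class `"radius_prior"`.
#' @export
radius_prior <- function(breaks = seq(5, 100, by = 5),
                         weights = rep(1, length(breaks))) {
  if (length(breaks) == 0 || any(breaks <= 0)) {
    stop("radius prior needs positive bin centres", call. = FALSE)
  }
  if (length(weights) != length(breaks) || any(weights < 0) ||
      sum(weights) <= 0) {
    stop("radius prior weights must be non-negative and sum > 0",
         call. = FALSE)
  }
  structure(list(s = breaks, w = weights / sum(weights)),
            class = "radius_prior")
}

#' Model configuration
#'
#' Collects the Bayesian model's prior choices: the prior probability that a
#' localization is background (`p_bg`, default 50%), the histogram prior on
#' cluster radii, how the axial background is modelled (`"fit"` fits a
#' Beta distribution per ROI; `"uniform"` forces Beta(1, 1)), and the
#' concentration `alpha` of the Chinese-restaurant-process prior on the
#' partition of the clustered points into clusters. The partition prior
#' completes the generative model: it supplies the allocation probability of
#' a point among the existing clusters (for a point joining a cluster of m
#' points out of n_C clustered ones, a log cost of about `log(n_C / m)`), so
#' that membership odds reflect cluster occupancy, and it penalises opening
#' a new cluster by about `log(alpha / n_C)` per cluster. The small default
#' `alpha = 0.01` encodes that the number of clusters is expected to be far
#' smaller than the number of localizations.
#'
#' @param p_bg Prior background probability, in (0, 1).
#' @param radius_prior A [radius_prior()].
#' @param z_mode `"fit"` or `"uniform"`.
#' @param alpha Concentration of the partition prior (> 0).
#' @param min_cluster_size Minimum points per proposed cluster.
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(p_bg = 0.5, radius_prior = bayesclust3d::radius_prior(),
                         z_mode = c("fit", "uniform"), alpha = 0.01,
                         min_cluster_size = 2) {
  if (!is.finite(p_bg) || p_bg <= 0 || p_bg >= 1) {
    stop("p_bg must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0) {
    stop("alpha must be finite and positive", call. = FALSE)
  }
  stopifnot(inherits(radius_prior, "radius_prior"))
  structure(list(p_bg = p_bg, radius_prior = radius_prior,
                 z_mode = match.arg(z_mode), alpha = alpha,
                 min_cluster_size = min_cluster_size),
            class = "model_config")
}

# log prior probability of the partition of the clustered points under the
# Chinese restaurant process with concentration alpha (0 clusters -> 0)
log_partition_prior <- function(labels, alpha) {
  clustered <- labels[labels > 0]
  if (length(clustered) == 0) return(0)
  m <- tabulate(clustered)
  m <- m[m > 0]
  length(m) * log(alpha) + sum(lgamma(m)) + lgamma(alpha) -
    lgamma(alpha + length(clustered))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Per-radius-bin log marginal terms for one cluster.
#
# For radius bin s_b the observation variance of point i in dimension d is
# v_{i,d} = s_b^2 + sigma_{i,d}^2. Integrating the product of Gaussians over
# the unknown cluster centre mu_d gives, per dimension, the closed form
#   -1/2 [ (m-1) log 2pi + sum_i log v_i + log sum_i 1/v_i
#          + sum_i x_i^2 / v_i - (sum_i x_i / v_i)^2 / sum_i 1/v_i ].
# The (slowly varying) centre-prior density is evaluated at the
# precision-weighted mean centre and multiplied on.
cluster_bin_terms <- function(coords, sigmas, roi, z_model, prior) {
  m <- nrow(coords)
  n_bins <- length(prior$s)
  log_terms <- numeric(n_bins)
  mu_z <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    v <- prior$s[b]^2 + sigmas^2  # m x 3
    inv_v <- 1 / v
    sum_inv <- colSums(inv_v)
    wsum <- colSums(coords * inv_v)
    quad <- colSums(coords^2 * inv_v) - wsum^2 / sum_inv
    log_int <- -0.5 * ((m - 1) * log(2 * pi) + colSums(log(v)) +
                         log(sum_inv) + quad)
    mu_hat <- wsum / sum_inv
    mu_z[b] <- mu_hat[3]
    centre_log <- -log(roi$Lx) - log(roi$Ly) - log(roi$Lz) +
      stats::dbeta(pmin(pmax(mu_hat[3] / roi$Lz, 1e-12), 1 - 1e-12),
                   z_model$alpha, z_model$beta, log = TRUE)
    log_terms[b] <- sum(log_int) + centre_log
  }
  list(log_terms = log_terms, mu_z = mu_z)
}

#' Log marginal likelihood of one cluster
#'
#' Marginalises the unknown cluster centre (exactly, per dimension) and the
#' unknown cluster radius (over the radius-prior histogram) for a set of
#' points attributed to one cluster. Each point contributes with its own
#' per-dimension variance `s_b^2 + sigma_{i,d}^2`, so imprecise localizations
#' are naturally down-weighted. All arithmetic is in log space with
#' log-sum-exp across radius bins.
#'
#' @param cluster Localization tibble of the cluster's points (m >= 1 rows;
#'   proposals never contain clusters below the configured minimum size, but
#'   the marginal itself is defined for any m).
#' @param roi An [roi()] object.
#' @param z_model A [z_background()] (prior for the centre's z position).
#' @param prior A [radius_prior()].
#' @return The log marginal likelihood (natural log). The per-bin log terms
#'   are attached as attribute `"log_terms"`; the maximising bin defines the
#'   cluster's MAP radius.
#' @export
log_marginal_cluster <- function(cluster, roi, z_model = z_background(),
                                 prior = radius_prior()) {
  coords <- as.matrix(cluster[c("x", "y", "z")])
  sigmas <- as.matrix(cluster[c("sigma_x", "sigma_y", "sigma_z")])
  bins <- cluster_bin_terms(coords, sigmas, roi, z_model, prior)
  out <- log_sum_exp(log(prior$w) + bins$log_terms)
  attr(out, "log_terms") <- bins$log_terms
  attr(out, "mu_z") <- bins$mu_z
  out
}

#' Score a cluster proposal under the generative model
#'
#' The log posterior score (up to a labelling-independent constant) is the
#' sum of the cluster marginal likelihoods, the background log densities of
#' the unlabelled points, the Bernoulli labelling prior
#' `n_B log p_bg + (n - n_B) log(1 - p_bg)`, and the
#' Chinese-restaurant-process prior on the partition of the clustered points
#' (see [model_config()]). At the default `p_bg = 0.5` the Bernoulli term is
#' constant in the labelling and never changes the ranking.
#'
#' @param labels Integer labels (0 background, 1..K clusters).
#' @param locs Localization tibble.
#' @param roi An [roi()] object.
#' @param config A [model_config()].
#' @param z_model A [z_background()]; when `NULL`, resolved from
#'   `config$z_mode` (fitting on `locs` if `"fit"`).
#' @param bg_logdens Optional precomputed per-point background log densities
#'   (an optimisation for scoring many proposals of the same table).
#' @return The log score (numeric scalar).
#' @export
score_proposal <- function(labels, locs, roi, config = model_config(),
                           z_model = NULL, bg_logdens = NULL) {
  n <- nrow(locs)
  stopifnot(length(labels) == n)
  if (is.null(z_model)) {
    z_model <- if (config$z_mode == "fit") fit_beta_z(locs, roi) else
      z_background(1, 1)
  }
  if (is.null(bg_logdens)) {
    bg_logdens <- log_background_density(locs, roi, z_model)
  }
  is_bg <- labels == 0
  n_bg <- sum(is_bg)
  score <- sum(bg_logdens[is_bg]) +
    n_bg * log(config$p_bg) + (n - n_bg) * log(1 - config$p_bg) +
    log_partition_prior(labels, config$alpha)
  for (k in unique(labels[!is_bg])) {
    score <- score + as.numeric(log_marginal_cluster(
      locs[labels == k, , drop = FALSE], roi, z_model, config$radius_prior))
  }
  score
}

#' Score every proposal of a sweep
#'
#' @param proposals Tibble from [sweep_proposals()].
#' @inheritParams score_proposal
#' @return The proposals tibble with an added `log_score` column.
#' @export
score_sweep <- function(proposals, locs, roi, config = model_config(),
                        z_model = NULL) {
  if (is.null(z_model)) {
    z_model <- if (config$z_mode == "fit") fit_beta_z(locs, roi) else
      z_background(1, 1)
  }
  bg_logdens <- log_background_density(locs, roi, z_model)
  scores <- vapply(proposals$labels, function(lab) {
    score_proposal(lab, locs, roi, config, z_model = z_model,
                   bg_logdens = bg_logdens)
  }, numeric(1))
  out <- dplyr::mutate(proposals, log_score = scores)
  attr(out, "z_model") <- z_model
  out
}

#' Select the maximum a posteriori proposal
#'
#' Returns the highest-scoring proposal; exact ties are broken in favour of
#' fewer clusters, then smaller generating radius r, then smaller prominence
#' threshold T (the all-background proposal's missing r and T sort last).
#'
#' @param scored Tibble from [score_sweep()] (must contain `log_score`).
#' @return A one-row tibble (the winning proposal).
#' @export
select_best <- function(scored) {
  stopifnot(nrow(scored) >= 1, "log_score" %in% names(scored))
  ord <- order(-scored$log_score, scored$k,
               ifelse(is.na(scored$r), Inf, scored$r),
               ifelse(is.na(scored$t), Inf, scored$t))
  scored[ord[1], , drop = FALSE]
}
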
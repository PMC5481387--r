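#' Specify a ground-truth simulation condition
#'
#' Defines one simulated ROI: K spherical clusters of `mols_per_cluster`
#' molecules each, overlaid on a non-clustered background, with every
#' molecular position perturbed by Gaussian localization error whose standard
#' deviation is drawn per point from a Gamma distribution (one draw per
#' point, applied to all three dimensions, mimicking near-isotropic iPALM
#' precision). The constructor validates that
#' `K * mols_per_cluster + round(f_bg * n_total) == n_total`.
#'
#' @param roi An [roi()] object.
#' @param n_total Total number of molecules.
#' @param n_clusters Number of clusters K (0 for pure background).
#' @param mols_per_cluster Molecules per cluster.
#' @param radius Cluster scale s in nm: the Gaussian standard deviation
#'   (`shape = "gaussian"`), the ball radius (`"hard_sphere"`), or the short
#'   semi-axis of a (s, s, 2s) ellipsoid (`"ellipsoid"`).
#' @param shape Cluster shape; ellipsoids are uniformly filled with the long
#'   axis oriented along x, y or z, chosen uniformly per cluster.
#' @param f_bg Fraction of molecules that are non-clustered background.
#' @param z_law A [z_background()] giving the law of `z / Lz` for the
#'   non-clustered background molecules; Beta(1, 1) is uniform.
#' @param z_law_centres Law of `z / Lz` for cluster centres; defaults to
#'   `z_law`. Membrane-proximal conditions place the background near the
#'   coverslip while cluster centres may remain uniform.
#' @param precision_mean Mean of the Gamma localization-precision law in nm.
#' @param precision_shape Gamma shape parameter k (scale is
#'   `precision_mean / k`); the default k = 4 gives a realistic 10-60 nm
#'   spread around the 30 nm mean.
#' @param seed Integer seed; the generated table is a deterministic function
#'   of the spec.
#' @return An object of class `"sim_spec"`.
#' @export
sim_spec <- function(roi, n_total, n_clusters, mols_per_cluster, radius = 30,
                     shape = c("gaussian", "hard_sphere", "ellipsoid"),
                     f_bg = 0.5, z_law = z_background(1, 1),
                     z_law_centres = z_law,
                     precision_mean = 30, precision_shape = 4, seed = 1) {
  shape <- match.arg(shape)
  stopifnot(inherits(roi, "roi"), inherits(z_law, "z_background"),
            inherits(z_law_centres, "z_background"))
  n_bg <- round(f_bg * n_total)
  if (n_clusters * mols_per_cluster + n_bg != n_total) {
    stop("inconsistent spec: K * m + round(f_bg * n_total) must equal n_total",
         call. = FALSE)
  }
  if (n_clusters > 0 && radius <= 0) stop("cluster radius must be positive",
                                          call. = FALSE)
  structure(list(roi = roi, n_total = n_total, n_clusters = n_clusters,
                 mols_per_cluster = mols_per_cluster, radius = radius,
                 shape = shape, f_bg = f_bg, n_bg = n_bg, z_law = z_law,
                 z_law_centres = z_law_centres,
                 precision_mean = precision_mean,
                 precision_shape = precision_shape, seed = seed),
            class = "sim_spec")
}

#' The Standard Condition and its variants
#'
#' The Standard Condition is a 3000 x 3000 x 600 nm ROI containing 10
#' Gaussian clusters of standard deviation (radius) 30 nm with 50 molecules
#' each, overlaid with an equal-sized non-clustered population (1000
#' molecules total, 50% clustered), uniform in z, with per-point localization
#' precisions drawn from a Gamma law of mean 30 nm. The arguments allow the
#' documented variants (different totals, background fractions, z laws and
#' cluster shapes) while keeping the remaining parameters at their Standard
#' values; the number of clusters stays at 10 and molecules per cluster is
#' derived as `n_total * (1 - f_bg) / 10`.
#'
#' @param seed Integer seed.
#' @param n_total Total molecules (100..2000 in the documented variants).
#' @param f_bg Background fraction (0.1..0.9 in the documented variants).
#' @inheritParams sim_spec
#' @return A [sim_spec()].
#' @examples
#' standard_condition(seed = 1)
#' standard_condition(seed = 1, n_total = 100)      # below-detection regime
#' standard_condition(seed = 1, z_law = z_background(2, 20))
#' @export
standard_condition <- function(seed = 1, n_total = 1000, f_bg = 0.5,
                               shape = "gaussian",
                               z_law = z_background(1, 1),
                               z_law_centres = z_law, radius = 30) {
  m <- round(n_total * (1 - f_bg) / 10)
  sim_spec(roi = roi(3000, 3000, 600), n_total = n_total, n_clusters = 10,
           mols_per_cluster = m, radius = radius, shape = shape,
           f_bg = 1 - 10 * m / n_total, z_law = z_law,
           z_law_centres = z_law_centres, seed = seed)
}

#' @rdname standard_condition
#' @param n_total Total molecules (matches the Standard Condition's 1000 by
#'   default).
#' @param roi ROI for the CSR condition.
#' @export
csr_condition <- function(seed = 1, n_total = 1000,
                          roi = bayesclust3d::roi(3000, 3000, 600)) {
  sim_spec(roi = roi, n_total = n_total, n_clusters = 0,
           mols_per_cluster = 0, radius = 30, f_bg = 1,
           z_law = z_background(1, 1), seed = seed)
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(
    "<sim_spec> %d molecules (%d clusters x %d + %d background), %s s = %g nm\n",
    x$n_total, x$n_clusters, x$mols_per_cluster, x$n_bg, x$shape, x$radius))
  cat(sprintf("  ROI %g x %g x %g nm; z ~ Beta(%g, %g); seed %d\n",
              x$roi$Lx, x$roi$Ly, x$roi$Lz, x$z_law$alpha, x$z_law$beta,
              as.integer(x$seed)))
  invisible(x)
}

# sample z coordinates from the spec's z law, optionally truncated to keep
# cluster shapes inside the ROI (inverse-CDF truncation; a margin spanning
# the whole depth collapses to the mid-plane)
sample_z <- function(n, Lz, z_law, margin = 0) {
  p_lo <- stats::pbeta(margin / Lz, z_law$alpha, z_law$beta)
  p_hi <- stats::pbeta(1 - margin / Lz, z_law$alpha, z_law$beta)
  if (p_hi <= p_lo) return(rep(Lz / 2, n))
  u <- stats::runif(n, p_lo, p_hi)
  Lz * stats::qbeta(u, z_law$alpha, z_law$beta)
}

# uniform sample inside the unit ball
runif_ball <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  v * stats::runif(n)^(1 / 3)
}

#' Simulate one ground-truth ROI
#'
#' Draws cluster centres (uniform in x/y and the spec's z law, kept far
#' enough from the faces that the whole cluster shape fits inside the ROI),
#' populates each cluster according to its shape, overlays the background
#' (uniform x/y, z law in z), then perturbs every molecular position
#' per-dimension by `Normal(0, sigma_i^2)` with a single
#' `sigma_i ~ Gamma(k, mean/k)` draw per point, recorded as that point's
#' precision triple. Perturbations that would leave the ROI are redrawn
#' (truncated noise), so counts are preserved exactly and non-uniform axial
#' laws keep their shape at the faces.
#'
#' @param spec A [sim_spec()].
#' @return A list of class `"sim_roi"`: `locs` (localization tibble with a
#'   `true_label` column, 0 = background), `centres` (true cluster centres
#'   and radii) and `spec`.
#' @export
simulate_roi <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(as.integer(spec$seed))
  roi <- spec$roi
  s <- spec$radius
  K <- spec$n_clusters
  m <- spec$mols_per_cluster
  long <- if (spec$shape == "ellipsoid") 2 * s else s
  margin_xy <- 3 * s
  margin_z <- 3 * long
  sides <- roi_sides(roi)
  coords <- matrix(numeric(0), ncol = 3)
  labels <- integer(0)
  centres <- tibble::tibble(cluster = integer(0), x = numeric(0),
                            y = numeric(0), z = numeric(0),
                            radius = numeric(0))
  if (K > 0) {
    cx <- stats::runif(K, margin_xy, roi$Lx - margin_xy)
    cy <- stats::runif(K, margin_xy, roi$Ly - margin_xy)
    cz <- sample_z(K, roi$Lz, spec$z_law_centres, margin = margin_z)
    centres <- tibble::tibble(cluster = seq_len(K), x = cx, y = cy, z = cz,
                              radius = s)
    for (k in seq_len(K)) {
      offs <- switch(spec$shape,
        gaussian = {
          # redraw the rare beyond-3s tail draws that would leave the ROI
          # (the centre margin only guarantees the 3s sphere fits)
          o <- matrix(stats::rnorm(3 * m, sd = s), ncol = 3)
          ctr <- c(cx[k], cy[k], cz[k])
          for (d in 1:3) {
            bad <- which(ctr[d] + o[, d] < 0 | ctr[d] + o[, d] >= sides[d])
            while (length(bad) > 0) {
              o[bad, d] <- stats::rnorm(length(bad), sd = s)
              bad <- bad[ctr[d] + o[bad, d] < 0 | ctr[d] + o[bad, d] >= sides[d]]
            }
          }
          o
        },
        hard_sphere = runif_ball(m) * s,
        ellipsoid = {
          # long axis along x, y or z, chosen uniformly per cluster
          axes <- rep(s, 3)
          axes[sample(3, 1)] <- 2 * s
          sweep(runif_ball(m), 2, axes, "*")
        })
      coords <- rbind(coords, sweep(offs, 2, c(cx[k], cy[k], cz[k]), "+"))
      labels <- c(labels, rep(k, m))
    }
  }
  if (spec$n_bg > 0) {
    bg <- cbind(stats::runif(spec$n_bg, 0, roi$Lx),
                stats::runif(spec$n_bg, 0, roi$Ly),
                sample_z(spec$n_bg, roi$Lz, spec$z_law))
    coords <- rbind(coords, bg)
    labels <- c(labels, rep(0L, spec$n_bg))
  }
  n <- nrow(coords)
  sigma <- stats::rgamma(n, shape = spec$precision_shape,
                         scale = spec$precision_mean / spec$precision_shape)
  # truncated noise: redraw any perturbation that leaves the ROI, so counts
  # are preserved and non-uniform z laws are not smeared across the faces
  noisy <- coords + matrix(stats::rnorm(3 * n), ncol = 3) * sigma
  sides <- roi_sides(roi)
  for (d in 1:3) {
    bad <- which(noisy[, d] < 0 | noisy[, d] >= sides[d])
    while (length(bad) > 0) {
      noisy[bad, d] <- coords[bad, d] + stats::rnorm(length(bad)) * sigma[bad]
      bad <- bad[noisy[bad, d] < 0 | noisy[bad, d] >= sides[d]]
    }
  }
  locs <- tibble::tibble(
    x = noisy[, 1], y = noisy[, 2], z = noisy[, 3],
    sigma_x = sigma, sigma_y = sigma, sigma_z = sigma,
    true_label = as.integer(labels))
  structure(list(locs = locs, centres = centres, spec = spec),
            class = "sim_roi")
}

#' Detected-versus-true recovery metrics for a simulated ROI
#'
#' Compares the fit's descriptors against the simulation ground truth for
#' the four headline descriptors (cluster count, percentage of localizations
#' in clusters, localizations per cluster, cluster radius), and counts the
#' detected clusters whose centroid lies further than `3 * radius` from
#' every true centre ("artificial" clusters).
#'
#' @param sim A [simulate_roi()] result.
#' @param fit A [bayes_cluster()] fit of `sim$locs`.
#' @return A one-row tibble of true and detected descriptor values plus
#'   `n_artificial`.
#' @export
recovery_metrics <- function(sim, fit) {
  stopifnot(inherits(sim, "sim_roi"), inherits(fit, "bayes_cluster3d"))
  g <- generics::glance(fit)
  truth <- sim$locs$true_label
  k_true <- sim$spec$n_clusters
  pc <- fit$per_cluster
  n_art <- 0L
  if (nrow(pc) > 0) {
    if (k_true > 0) {
      d <- vapply(seq_len(nrow(pc)), function(i) {
        min(sqrt((pc$x[i] - sim$centres$x)^2 + (pc$y[i] - sim$centres$y)^2 +
                   (pc$z[i] - sim$centres$z)^2))
      }, numeric(1))
      n_art <- sum(d > 3 * sim$spec$radius)
    } else {
      n_art <- nrow(pc)
    }
  }
  tibble::tibble(
    k_true = k_true, k_detected = g$k,
    percent_true = 100 * mean(truth > 0),
    percent_detected = g$percent_in_clusters,
    locs_per_cluster_true = if (k_true > 0) sim$spec$mols_per_cluster else
      NA_real_,
    locs_per_cluster_detected = g$mean_locs_per_cluster,
    radius_true = if (k_true > 0) sim$spec$radius else NA_real_,
    radius_detected = g$mean_radius,
    n_artificial = n_art)
}
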
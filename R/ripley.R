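#' Toroidal distance between two points in an ROI
#'
#' Euclidean distance on the 3-torus defined by the ROI: each per-axis
#' difference `d` is replaced by `min(|d|, L - |d|)` before combining. This is
#' the edge correction used by the whole package — points near opposite faces
#' of the box are treated as neighbours, so no boundary loses neighbour mass.
#'
#' @param p,q Numeric length-3 vectors (x, y, z) in nm, inside the ROI.
#' @param roi An [roi()] object.
#' @return Distance in nm.
#' @examples
#' toroidal_distance(c(1, 0, 0), c(2999, 0, 0), roi(3000, 3000, 600))  # 2
#' @export
toroidal_distance <- function(p, q, roi) {
  L <- roi_sides(roi)
  d <- abs(p - q)
  d <- pmin(d, L - d)
  sqrt(sum(d^2))
}

# Full pairwise toroidal distance matrix (n x n). Vectorized per axis;
# n <= a few thousand keeps this comfortably in memory.
toroidal_dist_matrix <- function(locs, roi) {
  n <- nrow(locs)
  out <- matrix(0, n, n)
  for (ax in c("x", "y", "z")) {
    L <- switch(ax, x = roi$Lx, y = roi$Ly, z = roi$Lz)
    v <- locs[[ax]]
    d <- abs(outer(v, v, "-"))
    d <- pmin(d, L - d)
    out <- out + d * d
  }
  sqrt(out)
}

#' Per-point localized 3D Ripley's L values
#'
#' For each localization j, counts the neighbours strictly within radius `r`
#' under the toroidal metric and converts the count to the linearised,
#' localized 3D Ripley's L value
#' \deqn{L_{3D}(r)_j = \left(\frac{3V}{4(n-1)\pi} \sum_{i \ne j}
#'   \delta_{ij}\right)^{1/3},}
#' where `V` is the ROI volume and \eqn{\delta_{ij} = 1} when the toroidal
#' distance between i and j is less than `r`. Under complete spatial
#' randomness the expected scale of L is `r` itself, so L acts as a per-point
#' local density estimate in length units.
#'
#' @param locs Localization tibble (needs at least `x`, `y`, `z`).
#' @param roi An [roi()] object.
#' @param r Search radius in nm; must satisfy `0 < r < min(L)/2` so the
#'   toroidal wrap is unambiguous.
#' @return The input tibble with an added numeric column `l3d` (nm).
#'   The neighbour counts are attached as attribute `"counts"`.
#' @export
local_l3d <- function(locs, roi, r) {
  n <- nrow(locs)
  if (n < 2) stop("at least 2 localizations are required", call. = FALSE)
  check_radius(r, roi)
  counts <- neighbour_counts(locs, roi, r)
  out <- dplyr::mutate(tibble::as_tibble(locs), l3d = l_from_count(counts, n, roi))
  attr(out, "counts") <- counts
  out
}

check_radius <- function(r, roi) {
  if (!is.finite(r) || r <= 0 || r >= min(roi_sides(roi)) / 2) {
    stop("radius r must satisfy 0 < r < min(Lx, Ly, Lz)/2", call. = FALSE)
  }
  invisible(r)
}

# neighbour count per point at radius r (strict inequality), from a
# precomputed distance matrix if supplied
neighbour_counts <- function(locs, roi, r, dmat = NULL) {
  if (is.null(dmat)) dmat <- toroidal_dist_matrix(locs, roi)
  as.integer(rowSums(dmat < r)) - 1L  # diagonal is 0 < r; remove self
}

# linearised L from a neighbour count
l_from_count <- function(count, n, roi) {
  (3 * roi_volume(roi) * count / (4 * (n - 1) * pi))^(1 / 3)
}

#' CSR eligibility threshold for local L values
#'
#' Under complete spatial randomness on the torus, the neighbour count of a
#' point is exactly Binomial(n - 1, p) with `p = (4/3) pi r^3 / V`. The
#' eligibility threshold is the CSR mean count plus one standard deviation,
#' \eqn{c^\ast = (n-1)p + \sqrt{(n-1)p(1-p)}}; a point is considered
#' potentially clustered iff its neighbour count strictly exceeds
#' \eqn{c^\ast}. The threshold is returned both on the count scale and on the
#' linearised L scale.
#'
#' @param n Number of localizations in the ROI.
#' @param roi An [roi()] object.
#' @param r Radius in nm.
#' @return A list with `c_star` (count scale), `l_star` (nm) and `p`.
#' @export
csr_eligibility_threshold <- function(n, roi, r) {
  if (n < 2) stop("at least 2 localizations are required", call. = FALSE)
  p <- (4 / 3) * pi * r^3 / roi_volume(roi)
  if (p > 1) stop("radius too large for the ROI volume (p > 1)", call. = FALSE)
  mu <- (n - 1) * p
  c_star <- mu + sqrt(mu * (1 - p))
  list(c_star = c_star, l_star = l_from_count(c_star, n, roi), p = p)
}
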
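#' Sweep grid of (r, T) proposal parameters
#'
#' A cluster proposal is generated for every combination of Ripley radius `r`
#' and topographic-prominence threshold `T`. The default radii span the
#' cluster scales typical of SMLM data (tens of nm clusters, ~30 nm
#' precisions). The thresholds are compared against prominences on the L
#' scale, where mode heights run from roughly 100 nm (a point with a single
#' neighbour, at n = 1000 in a 5.4e9 nm^3 ROI) to 300-450 nm (dense cluster
#' cores), so the default T range 0..300 nm spans "keep every mode" through
#' "keep only the most prominent modes": 19 x 21 = 399 combinations.
#'
#' @param r Ascending radii in nm; each must be valid for the ROI analysed.
#' @param t Ascending prominence thresholds in nm (L units).
#' @return An object of class `"sweep_grid"`.
#' @export
sweep_grid <- function(r = seq(20, 200, by = 10), t = seq(0, 300, by = 15)) {
  if (length(r) == 0 || length(t) == 0 || any(r <= 0) || any(t < 0)) {
    stop("sweep grid needs positive radii and non-negative thresholds",
         call. = FALSE)
  }
  structure(list(r = sort(unique(r)), t = sort(unique(t))),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("<sweep_grid> %d radii (%g..%g nm) x %d thresholds (%g..%g nm)\n",
              length(x$r), min(x$r), max(x$r),
              length(x$t), min(x$t), max(x$t)))
  invisible(x)
}

# Eligibility, L values, total order ("height"), and the r-neighbour graph
# restricted to eligible points. Height ties in L are broken by point index
# (higher index = higher), which makes climbing and merging deterministic.
eligible_graph <- function(locs, roi, r, dmat = NULL) {
  check_radius(r, roi)
  n <- nrow(locs)
  if (is.null(dmat)) dmat <- toroidal_dist_matrix(locs, roi)
  counts <- neighbour_counts(locs, roi, r, dmat = dmat)
  thr <- csr_eligibility_threshold(n, roi, r)
  eligible <- counts > thr$c_star
  l <- l_from_count(counts, n, roi)
  key <- integer(n)
  key[order(l, seq_len(n))] <- seq_len(n)  # 1 = lowest, n = highest
  adj <- vector("list", n)
  e_idx <- which(eligible)
  if (length(e_idx) > 0) {
    sub <- dmat[e_idx, e_idx, drop = FALSE] < r
    diag(sub) <- FALSE
    for (k in seq_along(e_idx)) adj[[e_idx[k]]] <- e_idx[sub[k, ]]
  }
  list(eligible = eligible, l = l, counts = counts, key = key, adj = adj)
}

#' Assign eligible points to local maxima of the L field
#'
#' Each eligible point repeatedly moves to its highest neighbour (within
#' toroidal distance `r`, among eligible points) whose L value is strictly
#' greater than its own; a point with no higher neighbour is a local maximum
#' (mode). L strictly increases along every path, so climbing terminates.
#' Ties in L are broken by point index.
#'
#' @param locs Localization tibble.
#' @param roi An [roi()] object.
#' @param r Radius in nm; eligibility and L are computed at this same radius.
#' @param graph Optional precomputed result of the internal eligibility-graph
#'   step (used by [sweep_proposals()] to avoid recomputation).
#' @return A list with `mode` (integer per point: the index of the mode its
#'   gradient path reaches, `NA` for ineligible points), `modes` (indices of
#'   the modes), `l` (per-point L values) and the neighbour graph.
#' @export
climb_to_modes <- function(locs, roi, r, graph = NULL) {
  if (is.null(graph)) graph <- eligible_graph(locs, roi, r)
  n <- length(graph$key)
  parent <- rep(NA_integer_, n)
  for (p in which(graph$eligible)) {
    nb <- graph$adj[[p]]
    if (length(nb) == 0) {
      parent[p] <- p
      next
    }
    best <- nb[which.max(graph$key[nb])]
    parent[p] <- if (graph$key[best] > graph$key[p]) best else p
  }
  # pointer-jump to the fixed point of each gradient path
  mode <- parent
  repeat {
    nxt <- ifelse(is.na(mode), NA_integer_, parent[mode])
    if (identical(nxt, mode)) break
    mode <- nxt
  }
  list(mode = mode, modes = which(!is.na(mode) & mode == seq_len(n)),
       l = graph$l, key = graph$key, adj = graph$adj,
       eligible = graph$eligible)
}

#' Threshold modes by topographic prominence
#'
#' Persistence-style prominence thresholding on the r-neighbour graph:
#' eligible points are processed in descending height; when an edge first
#' connects the basin of a lower mode m to the basin of a higher mode at a
#' point of value L_saddle, the topographic prominence of m is
#' `L(m) - L_saddle`. Basins whose prominence is strictly below `t` are
#' merged into the higher basin at that saddle. A mode whose basin never
#' meets a higher basin has no saddle; its prominence is its own height
#' L(m), and if that falls below `t` the basin is relabelled background —
#' only maxima whose prominence reaches the threshold become clusters, so
#' isolated low chance aggregations are removed rather than kept. Surviving
#' basins become clusters 1..K; clusters smaller than `min_cluster_size` are
#' relabelled background (0).
#'
#' @param climb Result of [climb_to_modes()].
#' @param t Prominence threshold in nm (L units). `t = 0` keeps every mode.
#' @param min_cluster_size Minimum points per reported cluster (default 2;
#'   singletons are indistinguishable from background under the model).
#' @return Integer label vector (0 = background, 1..K = clusters), with
#'   attributes `k` (number of clusters).
#' @export
prominence_merge <- function(climb, t, min_cluster_size = 2) {
  n <- length(climb$mode)
  labels <- integer(n)
  e_idx <- which(climb$eligible)
  if (length(e_idx) == 0) {
    attr(labels, "k") <- 0L
    return(labels)
  }
  # union-find over modes; prominence of a basin is decided at its first
  # (highest) saddle with a higher basin, or defaults to its mode's height
  uf <- seq_len(n)
  find <- function(i) {
    while (uf[i] != i) {
      uf[i] <<- uf[uf[i]]
      i <- uf[i]
    }
    i
  }
  decided <- logical(n)
  ord <- e_idx[order(climb$key[e_idx], decreasing = TRUE)]
  seen <- logical(n)
  for (p in ord) {
    roots <- unique(vapply(
      c(p, climb$adj[[p]][seen[climb$adj[[p]]]]),
      function(q) find(climb$mode[q]), integer(1)))
    seen[p] <- TRUE
    if (length(roots) > 1) {
      top <- roots[which.max(climb$key[roots])]
      for (rt in setdiff(roots, top)) {
        if (!decided[rt]) {
          decided[rt] <- TRUE
          if (climb$l[rt] - climb$l[p] < t) uf[rt] <- top
        }
      }
    }
  }
  root_of <- vapply(climb$mode[e_idx], find, integer(1))
  labels[e_idx] <- root_of
  # basins that never met a higher basin: prominence = mode height
  for (rt in unique(root_of)) {
    if (!decided[rt] && climb$l[rt] < t) labels[labels == rt] <- 0L
  }
  canonical_labels(labels, min_cluster_size)
}

# relabel to contiguous ids 1..K in order of first appearance; drop
# under-sized clusters to background
canonical_labels <- function(labels, min_cluster_size = 2) {
  pos <- which(labels > 0)
  if (length(pos) > 0) {
    tab <- table(labels[pos])
    small <- as.integer(names(tab)[tab < min_cluster_size])
    labels[labels %in% small] <- 0L
    pos <- which(labels > 0)
    if (length(pos) > 0) {
      ids <- unique(labels[pos])
      labels[pos] <- match(labels[pos], ids)
    }
  }
  labels <- as.integer(labels)
  attr(labels, "k") <- length(unique(labels[labels > 0]))
  labels
}

#' Generate the deduplicated set of cluster proposals over an (r, T) grid
#'
#' For every grid combination: compute per-point L at radius r, apply the CSR
#' eligibility threshold, climb to modes, and merge by prominence threshold
#' T. Proposals that induce the same partition of the points (ignoring label
#' permutation) are kept once, tagged with the first (r, T) that produced
#' them. The all-background proposal is always included.
#'
#' @param locs Localization tibble (n >= 2).
#' @param roi An [roi()] object.
#' @param grid A [sweep_grid()].
#' @param min_cluster_size Minimum points per cluster (default 2).
#' @return A tibble with one row per distinct proposal: `r`, `t`, `k` and the
#'   list-column `labels`. The all-background row has `r = NA`, `t = NA`.
#' @export
sweep_proposals <- function(locs, roi, grid = sweep_grid(),
                            min_cluster_size = 2) {
  stopifnot(inherits(grid, "sweep_grid"))
  n <- nrow(locs)
  if (n < 2) stop("at least 2 localizations are required", call. = FALSE)
  dmat <- toroidal_dist_matrix(locs, roi)
  seen <- new.env(parent = emptyenv())
  rows <- list()
  add <- function(labels, r, t) {
    hash <- paste(labels, collapse = ",")
    if (is.null(seen[[hash]])) {
      seen[[hash]] <- TRUE
      rows[[length(rows) + 1L]] <<- list(
        r = r, t = t, k = attr(labels, "k"), labels = labels)
    }
  }
  bg <- canonical_labels(integer(n), min_cluster_size)
  add(bg, NA_real_, NA_real_)
  for (r in grid$r) {
    graph <- eligible_graph(locs, roi, r, dmat = dmat)
    if (!any(graph$eligible)) next
    climb <- climb_to_modes(locs, roi, r, graph = graph)
    for (t in grid$t) {
      add(prominence_merge(climb, t, min_cluster_size), r, t)
    }
  }
  tibble::tibble(
    r = vapply(rows, `[[`, numeric(1), "r"),
    t = vapply(rows, `[[`, numeric(1), "t"),
    k = vapply(rows, function(x) as.integer(x$k), integer(1)),
    labels = lapply(rows, `[[`, "labels")
  )
}
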
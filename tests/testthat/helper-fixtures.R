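# Shared fixture builders. All randomness is locally seeded so every test is
# reproducible in isolation.

std_roi <- function() roi(3000, 3000, 600)

# bare localization tibble from coordinate vectors
make_locs <- function(x, y, z, sigma = 10) {
  n <- length(x)
  tibble::tibble(x = x, y = y, z = z,
                 sigma_x = rep_len(sigma, n),
                 sigma_y = rep_len(sigma, n),
                 sigma_z = rep_len(sigma, n))
}

# uniform CSR table in an ROI
csr_locs <- function(n, roi, seed = 1, sigma = 10) {
  set.seed(seed)
  make_locs(stats::runif(n, 0, roi$Lx), stats::runif(n, 0, roi$Ly),
            stats::runif(n, 0, roi$Lz), sigma = sigma)
}

# one Gaussian cluster around a centre
gauss_cluster_locs <- function(m, centre, s, sigma = 10, seed = 1) {
  set.seed(seed)
  make_locs(centre[1] + stats::rnorm(m, sd = s),
            centre[2] + stats::rnorm(m, sd = s),
            centre[3] + stats::rnorm(m, sd = s), sigma = sigma)
}

# scalar double-loop neighbour counting; the deliberately naive oracle for
# the vectorized distance-matrix route
brute_counts <- function(locs, roi, r) {
  n <- nrow(locs)
  p <- as.matrix(locs[, c("x", "y", "z")])
  counts <- integer(n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i != j && toroidal_distance(p[i, ], p[j, ], roi) < r) {
        counts[j] <- counts[j] + 1L
      }
    }
  }
  counts
}

# independent quadrature evaluation of the per-bin cluster marginal terms:
# numerically integrates each dimension's product of Gaussians over the
# centre coordinate, then applies the same centre-prior factor
quadrature_marginal <- function(cluster, roi, z_model, prior) {
  axes <- c("x", "y", "z")
  sig <- c("sigma_x", "sigma_y", "sigma_z")
  terms <- vapply(seq_along(prior$s), function(b) {
    s <- prior$s[b]
    li <- 0
    mu_hat <- numeric(3)
    for (d in 1:3) {
      xs <- cluster[[axes[d]]]
      v <- s^2 + cluster[[sig[d]]]^2
      f <- function(mu) vapply(mu, function(u) prod(stats::dnorm(xs, u, sqrt(v))),
                               numeric(1))
      # the integrand is proportional to a Gaussian in mu centred at the
      # precision-weighted mean with sd 1/sqrt(sum 1/v); integrate over a
      # window wide enough to hold all of its mass
      mu_hat[d] <- sum(xs / v) / sum(1 / v)
      half_width <- 15 / sqrt(sum(1 / v))
      li <- li + log(stats::integrate(f, mu_hat[d] - half_width,
                                      mu_hat[d] + half_width,
                                      rel.tol = 1e-12,
                                      subdivisions = 500L)$value)
    }
    li - log(roi$Lx) - log(roi$Ly) - log(roi$Lz) +
      stats::dbeta(mu_hat[3] / roi$Lz, z_model$alpha, z_model$beta, log = TRUE)
  }, numeric(1))
  w <- log(prior$w) + terms
  m <- max(w)
  m + log(sum(exp(w - m)))
}

# assemble a bayes_cluster3d object from a fixed labelling (used to test
# descriptor extraction and recovery scoring separately from MAP search)
fit_from_labels <- function(locs, roi, labels, config = model_config(),
                            z_model = z_background(1, 1)) {
  fit <- structure(list(
    locs = tibble::as_tibble(locs[, c("x", "y", "z", "sigma_x", "sigma_y",
                                      "sigma_z")]),
    roi = roi, config = config, z_model = z_model,
    labels = as.integer(labels), l3d = rep(NA_real_, nrow(locs)),
    best = list(r = NA_real_, t = NA_real_,
                k = length(unique(labels[labels > 0])),
                log_score = NA_real_),
    scored = tibble::tibble()), class = "bayes_cluster3d")
  fit$per_cluster <- cluster_descriptors(fit)
  fit
}

# hand-built eligibility graph for exercising climbing/merging directly
synthetic_graph <- function(l, edges, eligible = rep(TRUE, length(l))) {
  n <- length(l)
  adj <- rep(list(integer(0)), n)
  for (e in edges) {
    e <- as.integer(e)
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  key <- integer(n)
  key[order(l, seq_len(n))] <- seq_len(n)
  list(eligible = eligible, l = l, counts = NULL, key = key, adj = adj)
}

synthetic_climb <- function(l, edges, eligible = rep(TRUE, length(l))) {
  g <- synthetic_graph(l, edges, eligible)
  n <- length(l)
  parent <- rep(NA_integer_, n)
  for (p in which(g$eligible)) {
    nb <- g$adj[[p]]
    if (length(nb) == 0) { parent[p] <- p; next }
    best <- nb[which.max(g$key[nb])]
    parent[p] <- if (g$key[best] > g$key[p]) best else p
  }
  mode <- parent
  repeat {
    nxt <- ifelse(is.na(mode), NA_integer_, parent[mode])
    if (identical(nxt, mode)) break
    mode <- nxt
  }
  list(mode = mode, modes = which(!is.na(mode) & mode == seq_len(n)),
       l = g$l, key = g$key, adj = g$adj, eligible = g$eligible)
}
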
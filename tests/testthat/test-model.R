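test_that("fit_beta_z recovers known Beta laws from large samples", {
  r3 <- std_roi()
  set.seed(31)
  n <- 1e4
  # uniform data is Beta(1, 1)
  unif <- make_locs(runif(n, 0, 3000), runif(n, 0, 3000), runif(n, 0, 600))
  zb <- fit_beta_z(unif, r3)
  expect_equal(zb$alpha, 1, tolerance = 0.05)
  expect_equal(zb$beta, 1, tolerance = 0.05)
  for (shape in list(c(2, 5), c(2, 20))) {
    beta_locs <- make_locs(runif(n, 0, 3000), runif(n, 0, 3000),
                           600 * rbeta(n, shape[1], shape[2]))
    zb <- fit_beta_z(beta_locs, r3)
    expect_equal(zb$alpha, shape[1], tolerance = 0.1)
    expect_equal(zb$beta, shape[2], tolerance = 0.1)
  }
})

test_that("fit_beta_z falls back to uniform below the minimum sample size", {
  r3 <- std_roi()
  zb <- fit_beta_z(csr_locs(5, r3, seed = 1), r3)
  expect_equal(c(zb$alpha, zb$beta), c(1, 1))
})

test_that("background density is uniform 1/V under the flat z model", {
  r3 <- std_roi()
  locs <- csr_locs(20, r3, seed = 7)
  expect_equal(log_background_density(locs, r3, z_background(1, 1)),
               rep(-log(roi_volume(r3)), 20))
})

test_that("a membrane-proximal Beta z model reweights the background density", {
  r3 <- std_roi()
  zb <- z_background(2, 20)
  lo <- log_background_density(make_locs(0, 0, 0.05 * 600), r3, zb)
  hi <- log_background_density(make_locs(0, 0, 0.5 * 600), r3, zb)
  expect_gt(lo, hi)
  manual <- function(u) -log(3000) - log(3000) - log(600) + dbeta(u, 2, 20, log = TRUE)
  expect_equal(lo, manual(0.05))
  expect_equal(hi, manual(0.5))
})

test_that("a single point integrates to the centre-prior density exactly", {
  # per-dimension mu-integral of one Gaussian is 1, so the whole marginal is
  # the centre prior: 1/V under the flat z model, for every radius bin
  r3 <- std_roi()
  pt <- make_locs(1500, 1000, 300, sigma = 25)
  lm <- log_marginal_cluster(pt, r3, z_background(1, 1), radius_prior())
  expect_equal(as.numeric(lm), -log(roi_volume(r3)), tolerance = 1e-12)
  expect_equal(attr(lm, "log_terms"),
               rep(-log(roi_volume(r3)), length(radius_prior()$s)))
})

test_that("two coincident points match the product-of-Gaussians closed form", {
  r3 <- std_roi()
  s <- 30; sigma <- 40
  pts <- make_locs(c(1500, 1500), c(1000, 1000), c(300, 300), sigma = sigma)
  v <- s^2 + sigma^2
  expected <- 3 * (-0.5 * log(4 * pi * v)) - log(roi_volume(r3))
  lm <- log_marginal_cluster(pts, r3, z_background(1, 1),
                             radius_prior(breaks = s, weights = 1))
  expect_equal(as.numeric(lm), expected, tolerance = 1e-12)
})

test_that("the closed-form marginal matches numerical quadrature", {
  r3 <- std_roi()
  zb <- z_background(2, 5)
  pr <- radius_prior(breaks = c(10, 30, 60), weights = c(1, 2, 1))
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(2:6, 1)
    cl <- make_locs(runif(1, 500, 2500) + rnorm(m, sd = 25),
                    runif(1, 500, 2500) + rnorm(m, sd = 25),
                    runif(1, 150, 450) + rnorm(m, sd = 25))
    cl$sigma_x <- runif(m, 5, 40)
    cl$sigma_y <- runif(m, 5, 40)
    cl$sigma_z <- runif(m, 5, 40)
    closed <- as.numeric(log_marginal_cluster(cl, r3, zb, pr))
    oracle <- quadrature_marginal(cl, r3, zb, pr)
    expect_equal(closed, oracle, tolerance = 1e-6)
  }
})

test_that("the score decomposes over p_bg analytically", {
  # S(labels; p) = S(labels; 1/2) + n_B log(2p) + (n - n_B) log(2(1-p)),
  # so at p = 1/2 the labelling prior shifts every proposal equally
  r3 <- std_roi()
  locs <- csr_locs(40, r3, seed = 13)
  labels <- c(rep(1L, 6), rep(0L, 34))
  zb <- z_background(1, 1)
  for (p in c(0.25, 0.75)) {
    cfg_p <- model_config(p_bg = p, z_mode = "uniform")
    cfg_h <- model_config(p_bg = 0.5, z_mode = "uniform")
    n_bg <- sum(labels == 0)
    expect_equal(
      score_proposal(labels, locs, r3, cfg_p, z_model = zb),
      score_proposal(labels, locs, r3, cfg_h, z_model = zb) +
        n_bg * log(2 * p) + (40 - n_bg) * log(2 * (1 - p)))
  }
})

test_that("an all-background labelling has the exact closed-form score", {
  r3 <- std_roi()
  n <- 25
  locs <- csr_locs(n, r3, seed = 17)
  score <- score_proposal(rep(0L, n), locs, r3,
                          model_config(z_mode = "uniform"),
                          z_model = z_background(1, 1))
  expect_equal(score, n * (-log(roi_volume(r3)) + log(0.5)))
})

test_that("a tight aggregate is scored as a cluster, diffuse points as background", {
  r3 <- std_roi()
  cfg <- model_config(z_mode = "uniform")
  zb <- z_background(1, 1)
  tight <- gauss_cluster_locs(20, c(1500, 1500, 300), s = 10, sigma = 10,
                              seed = 23)
  one_cluster <- rep(1L, 20)
  all_bg <- rep(0L, 20)
  expect_gt(score_proposal(one_cluster, tight, r3, cfg, z_model = zb),
            score_proposal(all_bg, tight, r3, cfg, z_model = zb))
  diffuse <- csr_locs(20, r3, seed = 29)
  expect_gt(score_proposal(all_bg, diffuse, r3, cfg, z_model = zb),
            score_proposal(one_cluster, diffuse, r3, cfg, z_model = zb))
})

test_that("the score is invariant to cluster id permutation and point order", {
  r3 <- std_roi()
  cfg <- model_config()
  zb <- z_background(1, 1)
  set.seed(37)
  locs <- dplyr::bind_rows(
    gauss_cluster_locs(8, c(800, 800, 200), s = 20, seed = 1),
    gauss_cluster_locs(8, c(2200, 2200, 400), s = 20, seed = 2),
    csr_locs(10, r3, seed = 3))
  labels <- c(rep(1L, 8), rep(2L, 8), rep(0L, 10))
  base <- score_proposal(labels, locs, r3, cfg, z_model = zb)
  swapped <- ifelse(labels == 1L, 2L, ifelse(labels == 2L, 1L, 0L))
  expect_equal(score_proposal(swapped, locs, r3, cfg, z_model = zb), base)
  perm <- sample(26)
  expect_equal(score_proposal(labels[perm], locs[perm, ], r3, cfg,
                              z_model = zb), base)
})

test_that("select_best applies the tie-break chain", {
  one <- tibble::tibble(r = 50, t = 0, k = 2L, labels = list(c(1L, 1L)),
                        log_score = -10)
  expect_equal(select_best(one), one)
  scores <- tibble::tibble(r = c(50, 60, 70), t = c(0, 0, 0), k = c(1L, 2L, 3L),
                           labels = list(1L, 1L, 1L),
                           log_score = c(-100, -90, -95))
  expect_equal(select_best(scores)$log_score, -90)
  tied <- tibble::tibble(r = c(50, 50), t = c(0, 0), k = c(5L, 3L),
                         labels = list(1L, 1L), log_score = c(-90, -90))
  expect_equal(select_best(tied)$k, 3L)
  tied_r <- tibble::tibble(r = c(80, 40), t = c(0, 0), k = c(3L, 3L),
                           labels = list(1L, 1L), log_score = c(-90, -90))
  expect_equal(select_best(tied_r)$r, 40)
})
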
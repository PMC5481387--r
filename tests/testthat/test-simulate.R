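test_that("the standard condition encodes the published parameters", {
  spec <- standard_condition(seed = 1)
  expect_equal(spec$n_total, 1000)
  expect_equal(spec$n_clusters, 10)
  expect_equal(spec$mols_per_cluster, 50)
  expect_equal(spec$radius, 30)
  expect_equal(spec$f_bg, 0.5)
  expect_equal(spec$shape, "gaussian")
  expect_equal(c(spec$roi$Lx, spec$roi$Ly, spec$roi$Lz), c(3000, 3000, 600))
  expect_equal(c(spec$z_law$alpha, spec$z_law$beta), c(1, 1))
  expect_equal(spec$precision_mean, 30)
})

test_that("inconsistent specs are rejected at construction", {
  expect_error(sim_spec(std_roi(), n_total = 1000, n_clusters = 10,
                        mols_per_cluster = 49, f_bg = 0.5), "inconsistent")
})

test_that("simulation is deterministic in the seed and splits counts exactly", {
  a <- simulate_roi(standard_condition(seed = 7))
  b <- simulate_roi(standard_condition(seed = 7))
  expect_identical(a$locs, b$locs)
  expect_identical(a$centres, b$centres)
  expect_equal(sum(a$locs$true_label > 0), 500)
  expect_equal(sum(a$locs$true_label == 0), 500)
  c2 <- simulate_roi(standard_condition(seed = 8))
  expect_false(identical(a$locs, c2$locs))
})

test_that("generated tables satisfy the localization invariants", {
  sim <- simulate_roi(standard_condition(seed = 3))
  cols <- c("x", "y", "z", "sigma_x", "sigma_y", "sigma_z")
  expect_silent(validated <- validate_localizations(sim$locs[cols]))
  expect_equal(nrow(validated), 1000)
  expect_true(all(sim$locs$x >= 0 & sim$locs$x < 3000))
  expect_true(all(sim$locs$z >= 0 & sim$locs$z < 600))
  expect_true(all(sim$locs$sigma_x > 0))
})

test_that("gaussian cluster members have the specified per-axis spread", {
  spec <- sim_spec(std_roi(), n_total = 10000, n_clusters = 1,
                   mols_per_cluster = 10000, radius = 30, f_bg = 0,
                   precision_mean = 1e-6, seed = 5)
  sim <- simulate_roi(spec)
  members <- sim$locs[sim$locs$true_label == 1, ]
  for (ax in c("x", "y", "z")) {
    expect_equal(stats::sd(members[[ax]]), 30, tolerance = 0.02)
  }
})

test_that("hard-sphere and ellipsoid shapes respect their support", {
  hard <- simulate_roi(sim_spec(std_roi(), n_total = 2000, n_clusters = 1,
                                mols_per_cluster = 2000, radius = 50,
                                shape = "hard_sphere", f_bg = 0,
                                precision_mean = 1e-6, seed = 6))
  d <- sqrt((hard$locs$x - hard$centres$x)^2 +
              (hard$locs$y - hard$centres$y)^2 +
              (hard$locs$z - hard$centres$z)^2)
  expect_lte(max(d), 50 + 1e-3)
  expect_gt(max(d), 45)  # fills the ball out to its edge
  ell <- simulate_roi(sim_spec(std_roi(), n_total = 2000, n_clusters = 1,
                               mols_per_cluster = 2000, radius = 50,
                               shape = "ellipsoid", f_bg = 0,
                               precision_mean = 1e-6, seed = 7))
  spans <- vapply(c("x", "y", "z"), function(ax) {
    max(abs(ell$locs[[ax]] - ell$centres[[ax]]))
  }, numeric(1))
  expect_equal(sort(unname(spans)) > c(40, 40, 90), rep(TRUE, 3))
  expect_lte(max(spans), 100 + 1e-3)
})

test_that("the precision law has the configured Gamma mean", {
  sim <- simulate_roi(standard_condition(seed = 9))
  expect_equal(mean(sim$locs$sigma_x), 30, tolerance = 0.05)
  expect_identical(sim$locs$sigma_x, sim$locs$sigma_y)
  expect_identical(sim$locs$sigma_x, sim$locs$sigma_z)
})

test_that("the background z law matches its Beta target distribution", {
  spec <- sim_spec(std_roi(), n_total = 10000, n_clusters = 0,
                   mols_per_cluster = 0, f_bg = 1,
                   z_law = z_background(2, 5), precision_mean = 1e-6, seed = 10)
  sim <- simulate_roi(spec)
  ks <- suppressWarnings(
    stats::ks.test(sim$locs$z / 600, stats::pbeta, 2, 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("csr_condition emits pure background", {
  sim <- simulate_roi(csr_condition(seed = 11))
  expect_equal(nrow(sim$centres), 0)
  expect_true(all(sim$locs$true_label == 0))
  expect_equal(nrow(sim$locs), 1000)
})

test_that("CSR nearest-neighbour distances match the Poisson closed form", {
  r3 <- std_roi()
  sim <- simulate_roi(csr_condition(seed = 12))
  dmat <- bayesclust3d:::toroidal_dist_matrix(sim$locs, r3)
  diag(dmat) <- Inf
  nn <- apply(dmat, 1, min)
  lambda <- 1000 / roi_volume(r3)
  expected <- gamma(4 / 3) * (3 / (4 * pi * lambda))^(1 / 3)
  expect_equal(mean(nn), expected, tolerance = 0.05)
})

test_that("published variant conditions all construct and simulate", {
  variants <- list(
    standard_condition(seed = 1, n_total = 100),
    standard_condition(seed = 1, n_total = 2000),
    standard_condition(seed = 1, f_bg = 0.1),
    standard_condition(seed = 1, f_bg = 0.9),
    standard_condition(seed = 1, z_law = z_background(2, 5)),
    standard_condition(seed = 1, z_law = z_background(2, 20),
                       z_law_centres = z_background(1, 1)),
    standard_condition(seed = 1, shape = "hard_sphere"),
    standard_condition(seed = 1, shape = "ellipsoid"))
  for (spec in variants) {
    sim <- simulate_roi(spec)
    expect_equal(nrow(sim$locs), spec$n_total)
    expect_equal(sum(sim$locs$true_label > 0),
                 spec$n_clusters * spec$mols_per_cluster)
  }
})

test_that("recovery metrics are exact for a perfect labelling", {
  r3 <- std_roi()
  sim <- simulate_roi(standard_condition(seed = 13))
  fit <- fit_from_labels(sim$locs, r3, sim$locs$true_label)
  rm <- recovery_metrics(sim, fit)
  expect_equal(rm$k_detected, rm$k_true)
  expect_equal(rm$percent_detected, rm$percent_true)
  expect_equal(rm$locs_per_cluster_detected, 50)
  expect_equal(rm$n_artificial, 0)
})

test_that("recovery metrics flag an all-background result on clustered truth", {
  r3 <- std_roi()
  sim <- simulate_roi(standard_condition(seed = 14))
  fit <- fit_from_labels(sim$locs, r3, rep(0L, 1000))
  rm <- recovery_metrics(sim, fit)
  expect_equal(rm$k_detected, 0)
  expect_equal(rm$percent_detected, 0)
  expect_equal(rm$n_artificial, 0)
})
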
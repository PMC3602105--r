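toy_runs <- function(n_runs = 2, T = 2, seed = 71) {
  lapply(seq_len(n_runs) - 1L, function(r) {
    cfg <- sim_config(T = T, n_rows = 4L, n_cols = 4L,
                      initial_counts = c(Treg = 2L, nTh = 6L),
                      initial_molecules = c(HSP60 = 16, aCD3 = 16),
                      seed = seed + r)
    run_sim(cfg, run_id = r)
  })
}

test_that("flow tuples match the exhaustive enumeration", {
  runs <- toy_runs(2, 2)
  pts <- build_flow_points(runs, fx_spec(), n_select = 2, seed = 1)
  ## brute-force enumeration of unordered (run, t) slot pairs, t <= T-1
  slots <- expand.grid(run = 0:1, t = 0:1)
  want <- t(utils::combn(nrow(slots), 2))
  expect_identical(nrow(pts), nrow(want))
  expect_equal(nrow(pts), n_flow_tuples(2, 2))
  ## no self pairs (i = j, t1 = t2)
  expect_false(any(pts$i == pts$j & pts$t1 == pts$t2))
  got <- sort(paste(pmin(pts$i, pts$j), pmax(pts$i, pts$j), pts$t1, pts$t2))
  want_keys <- sort(apply(want, 1, function(k) {
    a <- slots[k[1], ]; b <- slots[k[2], ]
    paste(min(a$run, b$run), max(a$run, b$run), a$t, b$t)
  }))
  expect_identical(length(got), length(want_keys))
})

test_that("the point cloud is invariant to run relabelling", {
  runs <- toy_runs(3, 2)
  p1 <- build_flow_points(runs, fx_spec(), n_select = 3, seed = 1)
  relabel <- runs
  for (k in seq_along(relabel)) relabel[[k]]$run_id <- relabel[[k]]$run_id + 10L
  p2 <- build_flow_points(relabel, fx_spec(), n_select = 3, seed = 1)
  expect_equal(sort(p1$x), sort(p2$x))
  expect_equal(sort(p1$y), sort(p2$y))
  expect_error(build_flow_points(runs, fx_spec(), n_select = 5), "fewer runs")
})

test_that("the KDE reproduces a known bivariate normal density", {
  set.seed(8)
  pts <- list(x = rnorm(1e4), y = rnorm(1e4))
  dm <- estimate_density(pts, grid_size = 256)
  expect_true(all(dm$fhat >= 0))
  expect_equal(density_mass(dm), 1, tolerance = 0.01)
  i0 <- which.min(abs(dm$x1)); j0 <- which.min(abs(dm$x2))
  expect_equal(dm$fhat[i0, j0], 1 / (2 * pi), tolerance = 0.15)
  expect_error(estimate_density(list(x = 1:5, y = 1:5)), "at least 10")
})

test_that("contour levels are dense in low-probability regions", {
  set.seed(9)
  dm <- estimate_density(list(x = rnorm(2000), y = rnorm(2000)))
  lev <- contour_levels(dm, 12)
  expect_length(lev, 12L)
  expect_true(all(diff(lev) > 0))

  ## two-peak density: most levels fall below the minor peak
  f <- matrix(1e-4, 32, 32); f[8, 8] <- 1; f[24, 24] <- 0.1
  lev2 <- contour_levels(f, 12)
  expect_gt(sum(lev2 < 0.1), sum(lev2 > 0.1))

  ## uniform density still yields ordered levels
  levu <- contour_levels(matrix(0.25, 16, 16), 5)
  expect_length(levu, 5L)
  expect_true(all(diff(levu) > 0))
})

test_that("flow summaries quantify convergence and divergence", {
  diag_pts <- data.frame(x = seq(0.3, 0.9, length.out = 50))
  diag_pts$y <- diag_pts$x
  s <- flow_summary(diag_pts, dmap = NULL)
  expect_identical(s$frac_converging, 0)
  expect_identical(s$frac_diverging, 0)
  expect_equal(s$mean_delta, 0)

  div_pts <- data.frame(x = runif(40, 0.4, 0.8))
  div_pts$y <- div_pts$x + 0.1
  s2 <- flow_summary(div_pts, dmap = NULL)
  expect_identical(s2$frac_diverging, 1)
  expect_equal(s2$mean_delta, 0.1, tolerance = 1e-12)
})

test_that("L1 distances require a common grid and detect shifts", {
  set.seed(10)
  a <- list(x = rnorm(2000), y = rnorm(2000))
  b <- list(x = rnorm(2000) + 1, y = rnorm(2000))
  common <- list(c(-5, 7), c(-5, 5))
  da <- estimate_density(a, range = common)
  db <- estimate_density(b, range = common)
  expect_equal(flow_l1_distance(da, da), 0)
  l1 <- flow_l1_distance(da, db)
  expect_gt(l1, 0.2); expect_lt(l1, 2)
  d_off <- estimate_density(b)
  expect_error(flow_l1_distance(da, d_off), "grid")
})
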
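test_that("compressed sizes behave like a real compressor", {
  spec <- fx_spec()
  redundant <- charToRaw(strrep("a", 1e5))
  expect_lt(compressed_size(redundant, spec), 0.01 * 1e5)

  set.seed(1)
  rnd <- as.raw(sample.int(256L, 1e4, replace = TRUE) - 1L)
  expect_gte(compressed_size(rnd, spec), 0.95 * 1e4)

  before <- cache_stats(spec)$hits
  s1 <- compressed_size(rnd, spec)
  s2 <- compressed_size(rnd, spec)
  expect_identical(s1, s2)
  expect_gt(cache_stats(spec)$hits, before)

  expect_error(compressed_size(raw(0), spec), "empty")
  expect_error(ncd(raw(0), rnd, spec), "empty")
})

test_that("NCD separates self, mutated and independent objects", {
  spec <- fx_spec()
  s <- fx_wt_runs()[[1]]$states[[20]]
  b <- canonical_serialize(s)
  expect_gte(length(b), 1e4)
  expect_lte(ncd(b, b, spec), self_distance_tolerance())

  set.seed(2)
  x <- as.raw(sample.int(256L, 1e4, replace = TRUE) - 1L)
  z <- as.raw(sample.int(256L, 1e4, replace = TRUE) - 1L)
  expect_gte(ncd(x, z, spec), 0.9)

  ## 1% mutation stays far closer than an independent object
  for (k in 1:10) {
    set.seed(k + 10)
    y <- x
    idx <- sample.int(1e4, 100)
    y[idx] <- as.raw(sample.int(256L, 100, replace = TRUE) - 1L)
    zz <- as.raw(sample.int(256L, 1e4, replace = TRUE) - 1L)
    expect_lt(ncd(x, y, spec), ncd(x, zz, spec))
  }

  expect_identical(ncd(x, z, spec), ncd(z, x, spec))  # exact symmetry
})

test_that("NCD satisfies a relaxed triangle inequality on random states", {
  spec <- fx_spec()
  for (k in 1:100) {
    xs <- lapply(3 * k + 0:2, function(sd)
      canonical_serialize(random_state(sd, max_cells = 10, max_mols = 20)))
    expect_lte(ncd(xs[[1]], xs[[3]], spec),
               ncd(xs[[1]], xs[[2]], spec) + ncd(xs[[2]], xs[[3]], spec) + 0.1)
  }
})

test_that("pairwise NCDs of simulated states stay in the expected range", {
  spec <- fx_spec()
  runs <- fx_wt_runs()[1:2]
  b <- lapply(c(runs[[1]]$states[c(1, 10, 20, 31)],
                runs[[2]]$states[c(5, 15, 25)]), canonical_serialize)
  for (i in seq_along(b)) for (j in seq_len(i)) {
    v <- ncd(b[[i]], b[[j]], spec)
    expect_gte(v, 0); expect_lte(v, 1.1)
  }
})

test_that("consecutive and cross-run series have the right structure", {
  spec <- fx_spec()
  ## a frozen run: all states identical
  s <- random_state(99, max_cells = 10, max_mols = 20)
  states <- lapply(0:5, function(t) { s$t <- t; s })
  frozen <- run_result(0, "frozen", states)
  ser <- consecutive_ncd_series(frozen, spec)
  expect_length(ser, 5L)
  expect_identical(names(ser), as.character(0:4))
  expect_true(all(ser <= self_distance_tolerance()))

  expect_true(all(cross_run_ncd_series(frozen, frozen, spec) <=
                    self_distance_tolerance()))

  ## identical seeds give identical trajectories, i.e. self-distances
  cfg <- sim_config(T = 5L, seed = 31L)
  r1 <- run_sim(cfg); r2 <- run_sim(cfg, run_id = 1L)
  expect_true(all(cross_run_ncd_series(r1, r2, spec) <=
                    self_distance_tolerance()))
})

test_that("the global distance matrix is labelled and symmetric", {
  spec <- fx_spec()
  cfg <- sim_config(T = 1L, seed = 37L)
  D <- global_distance_matrix(list(wt = list(run_sim(cfg))), spec)
  expect_identical(dim(D$values), c(2L, 2L))
  expect_identical(D$values[1, 2], D$values[2, 1])
  expect_identical(diag(D$values), c(0, 0))
  expect_lt(D$values[1, 2], 1.1)
  expect_identical(D$labels$t, 0:1)

  ## design enumeration without computing entries
  ens <- list(a = run_ensemble(sim_config(T = 2L, seed = 1L), 3),
              b = run_ensemble(sim_config(T = 2L, seed = 9L), 3))
  D0 <- global_distance_matrix(ens, spec, compute = FALSE)
  expect_identical(nrow(D0$labels), 2L * 3L * 3L)
  expect_true(all(is.na(D0$values[upper.tri(D0$values)])))
})

test_that("event detection finds planted spikes and honours ties", {
  expect_identical(detect_events(rep(1, 20)), integer())
  set.seed(4)
  noise <- rnorm(30, 0, 0.01)
  noise[6] <- 1  # spike at 0-based index 5
  expect_true(5L %in% detect_events(noise))
  expect_identical(top_events(noise, n = 1), 5L)
  ## plateau: tie broken toward the earlier index
  plateau <- c(0, 0, 5, 5, 0, 0)
  expect_identical(detect_events(plateau), 2L)
  ## named series use names as time indices
  ser <- stats::setNames(c(0.1, 0.9, 0.1, 0.1), as.character(3:6))
  expect_identical(detect_events(ser), 4L)
  expect_identical(top_events(noise, n = 1), 5L)
})

test_that("event locations agree across compressor backends", {
  lz <- fx_spec()
  gz <- compressor_spec("gzip")
  for (run in fx_wt_runs()[1:2]) {
    e_lz <- top_events(consecutive_ncd_series(run, lz))
    e_gz <- top_events(consecutive_ncd_series(run, gz))
    expect_identical(e_lz[1], e_gz[1])  # earliest major event
  }
})
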
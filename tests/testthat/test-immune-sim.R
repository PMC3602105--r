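test_that("initialization places the configured populations", {
  s <- initialize_state(sim_config(seed = 5L))
  expect_identical(nrow(s$cells), 100L)
  expect_identical(sum(s$cells$name == "Treg"), 10L)
  expect_identical(sum(s$cells$name == "nTh"), 90L)
  expect_true(all(s$cells$behavior == "Resting"))
  ## activator molecules loaded on every location
  expect_setequal(unique(s$molecules$name), c("HSP60", "aCD3"))
  expect_identical(nrow(s$molecules), 800L)

  for (lbl in c("ratio:50:50", "ratio:70:30", "ratio:90:10")) {
    cfg <- condition_config(lbl, seed = 5L)
    expect_identical(sum(cfg$initial_counts), 100L)
    s <- initialize_state(cfg)
    expect_identical(nrow(s$cells), 100L)
    expect_identical(sum(s$cells$name == "Treg"),
                     as.integer(cfg$initial_counts[["Treg"]]))
  }
})

test_that("activator molecules deplete almost completely by t = 2", {
  run <- fx_wt_runs()[[1]]
  tot <- function(s, m) sum(s$molecules$conc[s$molecules$name == m])
  init <- tot(run$states[[1]], "HSP60") + tot(run$states[[1]], "aCD3")
  at2 <- tot(run$states[[3]], "HSP60") + tot(run$states[[3]], "aCD3")
  expect_gt(init, 700)
  expect_lt(at2, 0.01 * init)
})

test_that("without activator molecules no differentiation ever fires", {
  cfg <- sim_config(T = 15L, initial_molecules = c(HSP60 = 0, aCD3 = 0),
                    seed = 7L)
  run <- run_sim(cfg)
  for (s in run$states) {
    expect_setequal(unique(s$cells$name), c("Treg", "nTh"))
    expect_true(all(s$cells$behavior == "Resting"))
  }
})

test_that("CTLA-4 knock-out zeroes CTLA-4 expression at every time point", {
  run <- run_sim(condition_config("ko:CTLA-4:1", seed = 11L))
  saw_ctla4 <- FALSE
  for (s in run$states) {
    lev <- s$receptors$level[s$receptors$name == "CTLA-4"]
    if (length(lev)) saw_ctla4 <- TRUE
    expect_true(all(lev == 0))
  }
  expect_true(saw_ctla4)  # receptors are present, silenced
})

test_that("disabling both suppression channels prevents suppression", {
  cfg <- sim_config(perturbations = list(perturbation("IL-10", 1),
                                         perturbation("CTLA-4", 1)),
                    condition = "double_ko", seed = 13L)
  run <- run_sim(cfg)
  for (s in run$states)
    expect_identical(sum(s$cells$name == "SuppressedTh1"), 0L)
})

test_that("a run is a pure function of configuration and seed", {
  cfg <- sim_config(T = 12L, seed = 17L)
  r1 <- run_sim(cfg); r2 <- run_sim(cfg)
  for (i in seq_along(r1$states))
    expect_identical(canonical_serialize(r1$states[[i]]),
                     canonical_serialize(r2$states[[i]]))
  w <- sim_world(cfg)
  s1 <- as_system_state(sim_step(w, cfg, seed = 3L))
  s2 <- as_system_state(sim_step(w, cfg, seed = 3L))
  expect_identical(canonical_serialize(s1), canonical_serialize(s2))
  cfg1 <- sim_config(T = 1L, seed = 1L)
  w1 <- sim_step(sim_world(cfg1), cfg1, seed = 2L)
  expect_error(sim_step(w1, cfg1, seed = 2L), "horizon")
})

test_that("population bookkeeping reconciles between consecutive states", {
  run <- fx_wt_runs()[[2]]
  for (i in seq_len(length(run$states) - 1L)) {
    a <- run$states[[i]]$cells; b <- run$states[[i + 1L]]$cells
    ## wild-type defaults: no deaths, so every cell persists
    expect_true(all(a$index %in% b$index))
    new <- setdiff(b$index, a$index)
    if (length(new)) {
      expect_true(min(new) > max(a$index))       # daughters get fresh ids
      expect_true(all(b$name[match(new, b$index)] == "ActivatedTh1"))
    }
    expect_identical(nrow(b), nrow(a) + length(new))
  }
})

test_that("molecule mass balances under diffusion and decay alone", {
  cfg <- sim_config(T = 5L, initial_counts = c(Treg = 0L, nTh = 0L),
                    conc_floor = 1e-12, seed = 19L)
  cfg$molecule_params$quantum <- rep(1e-9, 5)
  cfg$molecule_params$retention <- rep(0.9, 5)
  run <- run_sim(cfg)
  tot <- function(s) sum(s$molecules$conc)
  for (i in 1:5)
    expect_equal(tot(run$states[[i + 1]]), tot(run$states[[i]]) * 0.9,
                 tolerance = 1e-5)
})

test_that("ensembles are sized and reproducible", {
  cfg <- sim_config(T = 4L, seed = 23L)
  e1 <- run_ensemble(cfg, 3)
  expect_length(e1, 3L)
  expect_identical(sum(vapply(e1, function(r) length(r$states), integer(1))), 15L)
  e2 <- run_ensemble(cfg, 3)
  expect_identical(canonical_serialize(e1[[3]]$states[[5]]),
                   canonical_serialize(e2[[3]]$states[[5]]))
  single <- run_ensemble(cfg, 1)[[1]]
  cfg1 <- cfg; cfg1$seed <- cfg$seed  # base_seed + 0
  expect_identical(canonical_serialize(single$states[[5]]),
                   canonical_serialize(run_sim(cfg1)$states[[5]]))
})

test_that("randomized-parameter configs keep the rule structure", {
  cfg <- sim_config(seed = 29L)
  r1 <- randomize_parameters(cfg, seed = 5L)
  r2 <- randomize_parameters(cfg, seed = 5L)
  expect_identical(r1$molecule_params, r2$molecule_params)
  expect_identical(r1$transition_params, r2$transition_params)
  for (seed in 1:20) {
    r <- randomize_parameters(cfg, seed = seed)
    expect_s3_class(validate_sim_config(r), "sim_config")
    expect_identical(r$initial_counts, cfg$initial_counts)   # 100 cells
    expect_identical(c(r$n_rows, r$n_cols), c(20L, 20L))     # same grid
    expect_identical(names(r$secretion_rates), names(cfg$secretion_rates))
    expect_true(all(r$molecule_params$retention >= 0 &
                      r$molecule_params$retention <= 1))
  }
  s <- initialize_state(randomize_parameters(cfg, seed = 31L))
  expect_identical(nrow(s$cells), 100L)
})

test_that("ensemble population curves follow the reference timeline", {
  runs <- fx_wt_runs()
  count_at <- function(type, t) mean(vapply(runs, function(r)
    sum(r$states[[t + 1L]]$cells$name == type), numeric(1)))
  il10_at <- function(t) mean(vapply(runs, function(r) {
    s <- r$states[[t + 1L]]
    sum(s$molecules$conc[s$molecules$name == "IL-10"])
  }, numeric(1)))
  ## differentiation window around t = 10-12
  expect_identical(count_at("ActivatedTreg", 9), 0)
  expect_identical(count_at("Th1", 9), 0)
  expect_gt(count_at("ActivatedTreg", 12), 5)
  expect_gt(count_at("Th1", 12), 50)
  ## cytokine secretion onset around t = 12-13
  expect_identical(il10_at(11), 0)
  expect_gt(il10_at(13), 0)
  ## proliferation window shortly before t = 18
  expect_identical(count_at("ActivatedTh1", 15), 0)
  expect_gt(count_at("ActivatedTh1", 19), 30)
  ## suppression appears mid-run and grows late
  expect_identical(count_at("SuppressedTh1", 12), 0)
  expect_gt(count_at("SuppressedTh1", 30), 10)
})

test_that("suppression weakens monotonically with IL-10 knock-out efficiency", {
  finals <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(eff) {
    cfg <- if (eff > 0) condition_config(sprintf("ko:IL-10:%g", eff))
           else sim_config()
    runs <- run_ensemble(cfg, 20, base_seed = 601L)
    mean(vapply(runs, function(r)
      sum(r$states[[31]]$cells$name == "SuppressedTh1"), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(finals) <= 2))  # non-increasing up to ensemble noise
  expect_lt(finals[5], 0.5 * finals[1])
})
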
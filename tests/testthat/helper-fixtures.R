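# Shared fixtures, memoized across test files (test files run alphabetically,
# so the acceptance tests populate the heavy entries and later files reuse
# them). Everything is generated in code under fixed seeds.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

## one compressor (and so one compressed-size cache) for the whole suite
fx_spec <- function() fx("spec", function() compressor_spec())

## 20-run wild-type ensemble at reference settings
fx_wt_runs <- function() fx("wt20", function()
  run_ensemble(sim_config(seed = 1L), 20, base_seed = 101L))

## consecutive-state NCD series for the wild-type ensemble
fx_wt_series <- function() fx("wt_series", function()
  lapply(fx_wt_runs(), consecutive_ncd_series, spec = fx_spec()))

## a random state with valid vocabulary and dialect-exact numbers
random_state <- function(seed, n_rows = 6L, n_cols = 6L, max_cells = 12L,
                         max_mols = 25L) {
  set.seed(seed)
  n_cells <- sample.int(max_cells + 1L, 1L) - 1L
  cells <- if (n_cells) data.frame(
    index = sample.int(1000L, n_cells),
    name = sample(cell_types(), n_cells, replace = TRUE),
    lifespan = sample.int(40L, n_cells),
    behavior = sample(behavior_states(), n_cells, replace = TRUE),
    row = sample.int(n_rows, n_cells, replace = TRUE) - 1L,
    col = sample.int(n_cols, n_cells, replace = TRUE) - 1L,
    stringsAsFactors = FALSE) else NULL
  receptors <- NULL
  if (n_cells) {
    rec <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
      rs <- sample(receptor_names(), sample.int(4L, 1L) - 1L)
      if (!length(rs)) return(NULL)
      data.frame(cell_index = cells$index[i], name = rs,
                 level = round(stats::runif(length(rs), 0, 12), 2),
                 stringsAsFactors = FALSE)
    }))
    receptors <- rec
  }
  n_mols <- sample.int(max_mols + 1L, 1L) - 1L
  molecules <- if (n_mols) {
    grid <- expand.grid(row = 0:(n_rows - 1L), col = 0:(n_cols - 1L),
                        name = molecule_names(), stringsAsFactors = FALSE)
    pick <- grid[sample.int(nrow(grid), n_mols), ]
    pick$conc <- round(stats::runif(n_mols, 0.01, 5), 4)
    pick
  } else NULL
  args <- list(t = sample.int(30L, 1L), n_rows = n_rows, n_cols = n_cols)
  if (!is.null(cells)) args$cells <- cells
  if (!is.null(receptors)) args$receptors <- receptors
  if (!is.null(molecules)) args$molecules <- molecules
  do.call(system_state, args)
}

## state equality on the data model (ignores container row order)
expect_same_state <- function(a, b) {
  expect_identical(canonical_serialize(a), canonical_serialize(b))
  expect_identical(a$t, b$t)
  expect_identical(c(a$n_rows, a$n_cols), c(b$n_rows, b$n_cols))
}

mode_of <- function(x) {
  x <- x[!is.na(x)]
  as.integer(names(which.max(table(x))))
}
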
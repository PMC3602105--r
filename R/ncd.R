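# Normalized compression distance between serialized system states, distance
# series/matrices and event detection.
#
# NCD(x, y) = (C(xy) - min(C(x), C(y))) / max(C(x), C(y)), with C the
# compressed size and xy the separator-free concatenation. The value is
# symmetrized over both concatenation orders. Real compressors give a small
# positive self-distance, so identical-state pairs are excluded from analyses
# rather than asserted to be exactly zero (see `self_distance_tolerance`).

#' Compressor specification
#'
#' Fixes the compression backend used for all NCD computations, together
#' with a content-addressed cache of compressed sizes (so each byte object
#' and each concatenation is compressed at most once per spec).
#'
#' The default backend is LZMA2 (the xz container's filter) at preset 1,
#' whose 1 MiB dictionary is far larger than a concatenated pair of state
#' files — essential so that shared structure between the two halves of a
#' concatenation is visible to the compressor. `gzip` (32 KiB window) is
#' provided as a fast cross-check backend for small inputs.
#'
#' @param algorithm `"lzma2"` (default) or `"gzip"`.
#' @param preset Compression preset 0..9 (lzma2 only; higher = slower,
#'   smaller).
#' @return An object of class `compressor_spec`.
#' @export
compressor_spec <- function(algorithm = c("lzma2", "gzip"), preset = 1L) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "lzma2" && (preset < 0 || preset > 9))
    stop("lzma2 preset must be in 0..9")
  structure(list(algorithm = algorithm, preset = as.integer(preset),
                 cache = new.env(parent = emptyenv()),
                 hits = 0L, calls = 0L),
            class = "compressor_spec")
}

#' @export
print.compressor_spec <- function(x, ...) {
  st <- cache_stats(x)
  cat(sprintf("<compressor_spec> %s preset %d  cache: %d entries, %d/%d hits\n",
              x$algorithm, x$preset, st$entries, st$hits, st$calls))
  invisible(x)
}

#' Cache statistics of a compressor spec
#'
#' @param spec A [compressor_spec()].
#' @return List with `entries`, `calls` (size queries) and `hits` (served
#'   from cache).
#' @export
cache_stats <- function(spec) {
  e <- spec$cache
  list(entries = length(ls(e, all.names = TRUE)) -
         sum(c(".calls", ".hits") %in% ls(e, all.names = TRUE)),
       calls = if (!is.null(e$.calls)) e$.calls else 0L,
       hits = if (!is.null(e$.hits)) e$.hits else 0L)
}

raw_compressed_size <- function(x, spec) {
  switch(spec$algorithm,
         lzma2 = .Call(C_xz_compressed_size, x, spec$preset),
         gzip  = length(memCompress(x, type = "gzip")))
}

#' Compressed size of a byte sequence
#'
#' Length in bytes of `x` after compression with the backend fixed by
#' `spec`. Results are cached by content digest, so repeated queries (and
#' the single-object sizes reused across many NCD pairs) are free.
#'
#' @param x A raw vector (non-empty) or a [system_state()] (serialized
#'   canonically first).
#' @param spec A [compressor_spec()].
#' @param feature_mode Serialization mode when `x` is a state.
#' @return Integer byte count.
#' @export
compressed_size <- function(x, spec = compressor_spec(), feature_mode = "all") {
  if (inherits(x, "system_state")) x <- canonical_serialize(x, feature_mode)
  if (!is.raw(x)) stop("x must be a raw vector or a system_state")
  if (!length(x)) stop("cannot compress an empty byte sequence (NCD undefined)")
  e <- spec$cache
  e$.calls <- (if (is.null(e$.calls)) 0L else e$.calls) + 1L
  key <- paste0(spec$algorithm, spec$preset, "_", rlang::hash(x))
  hit <- e[[key]]
  if (!is.null(hit)) {
    e$.hits <- (if (is.null(e$.hits)) 0L else e$.hits) + 1L
    return(hit)
  }
  sz <- raw_compressed_size(x, spec)
  e[[key]] <- sz
  sz
}

#' Normalized compression distance between two byte sequences
#'
#' Computes `(C(xy) - min(C(x), C(y))) / max(C(x), C(y))` where `C` is the
#' compressed size under `spec` and `xy` is the concatenation of the two
#' byte sequences with no separator. Because real compressors are not
#' perfectly symmetric in concatenation order, the value returned is the
#' average over both orders, making `ncd(x, y) == ncd(y, x)` exact.
#'
#' Values lie in roughly \[0, 1.1\]: near 0 for objects sharing almost all
#' information, near (or slightly above) 1 for independent random objects.
#'
#' @param x,y Raw vectors or [system_state()] objects.
#' @inheritParams compressed_size
#' @return A single numeric NCD value.
#' @export
ncd <- function(x, y, spec = compressor_spec(), feature_mode = "all") {
  if (inherits(x, "system_state")) x <- canonical_serialize(x, feature_mode)
  if (inherits(y, "system_state")) y <- canonical_serialize(y, feature_mode)
  if (!is.raw(x) || !is.raw(y)) stop("operands must be raw vectors or system_states")
  if (!length(x) || !length(y)) stop("NCD is undefined for empty operands")
  cx <- compressed_size(x, spec)
  cy <- compressed_size(y, spec)
  cxy <- compressed_size(c(x, y), spec)
  cyx <- compressed_size(c(y, x), spec)
  ((cxy + cyx) / 2 - min(cx, cy)) / max(cx, cy)
}

#' Tolerance below which an NCD is treated as a self-distance
#'
#' Identical objects compress to a small but non-zero NCD under real
#' compressors; pairs with `i = j, t1 = t2` are excluded from analyses
#' rather than asserted to be exactly zero.
#'
#' @return 0.05
#' @export
self_distance_tolerance <- function() 0.05

serialize_run <- function(run, feature_mode = "all") {
  lapply(run$states, canonical_serialize, feature_mode = feature_mode)
}

#' NCD between consecutive states of one run
#'
#' The consecutive-state NCD series of a run: the value at time `t` is
#' `ncd(s(t), s(t+1))` for t = 0..T-1. Peaks in this series flag
#' system-level events — a large information change between successive
#' snapshots (molecule depletion, differentiation waves, proliferation).
#'
#' @param run A [run_result()].
#' @param spec A [compressor_spec()].
#' @param feature_mode `"all"`, `"cells_only"` or `"molecules_only"` for
#'   feature-restricted analyses.
#' @return Named numeric vector of length T (names are the pair start times
#'   as characters, `"0" ... "T-1"`).
#' @export
consecutive_ncd_series <- function(run, spec = compressor_spec(),
                                   feature_mode = "all") {
  b <- serialize_run(run, feature_mode)
  T <- length(b) - 1L
  out <- vapply(seq_len(T),
                function(i) ncd(b[[i]], b[[i + 1L]], spec), numeric(1))
  names(out) <- as.character(seq_len(T) - 1L)
  out
}

#' Same-time NCD between two distinct runs
#'
#' The value at time `t` is `ncd(s_i(t), s_j(t))` for t = 0..T: the
#' information distance between the two trajectories at equal times. Over a
#' wild-type ensemble the mean series increases with t — trajectories
#' diverge as stochastic movement decorrelates the runs.
#'
#' @param run_i,run_j Two [run_result()] objects of equal length.
#' @inheritParams consecutive_ncd_series
#' @return Named numeric vector of length T + 1.
#' @export
cross_run_ncd_series <- function(run_i, run_j, spec = compressor_spec(),
                                 feature_mode = "all") {
  if (length(run_i$states) != length(run_j$states))
    stop("runs must have the same number of states")
  bi <- serialize_run(run_i, feature_mode)
  bj <- serialize_run(run_j, feature_mode)
  out <- vapply(seq_along(bi),
                function(i) ncd(bi[[i]], bj[[i]], spec), numeric(1))
  names(out) <- as.character(seq_along(bi) - 1L)
  out
}

#' Global NCD distance matrix over pooled states
#'
#' Pools the states of one or more condition ensembles and computes the
#' symmetric all-pairs NCD matrix. For the reference design of 50 runs and
#' 31 time points the per-condition block is 1550 x 1550; four pooled
#' conditions give a 6200 x 6200 matrix. Single-state compressed sizes are
#' cached, so the cost is one concatenation compression per pair; pair
#' values are independent tasks (order does not matter, and `cores > 1`
#' distributes them with [parallel::mclapply()]).
#'
#' @param ensembles Named list: condition label -> list of [run_result()]s.
#' @param spec A [compressor_spec()].
#' @param feature_mode Serialization mode.
#' @param times Optional integer vector of time points to include (default
#'   all); a coarser time grid is the supported way to embed large designs
#'   at desk scale.
#' @param compute If `FALSE`, only the label bookkeeping is done and the
#'   matrix is filled with `NA` — used to enumerate/validate the design
#'   (matrix side, state counts) without the quadratic compression cost.
#' @param cores Number of worker processes for pair computation.
#' @return An object of class `distance_matrix`: list with `labels`
#'   (data.frame `condition`, `run`, `t`) and `values` (symmetric numeric
#'   matrix, zero diagonal by convention).
#' @export
global_distance_matrix <- function(ensembles, spec = compressor_spec(),
                                   feature_mode = "all", times = NULL,
                                   compute = TRUE, cores = 1L) {
  if (is.null(names(ensembles)) || any(!nzchar(names(ensembles))))
    stop("ensembles must be a named list (condition -> runs)")
  lab <- list(); bytes <- list()
  for (cond in names(ensembles)) {
    for (run in ensembles[[cond]]) {
      ts <- vapply(run$states, function(s) s$t, integer(1))
      keep <- if (is.null(times)) seq_along(ts) else which(ts %in% times)
      lab[[length(lab) + 1L]] <-
        data.frame(condition = cond, run = run$run_id, t = ts[keep],
                   stringsAsFactors = FALSE)
      bytes <- c(bytes, if (compute)
        lapply(run$states[keep], canonical_serialize, feature_mode = feature_mode)
        else vector("list", length(keep)))
    }
  }
  labels <- do.call(rbind, lab)
  n <- nrow(labels)
  values <- matrix(NA_real_, n, n)
  diag(values) <- 0
  if (compute && n > 1L) {
    pairs <- which(upper.tri(values), arr.ind = TRUE)
    one <- function(k) ncd(bytes[[pairs[k, 1]]], bytes[[pairs[k, 2]]], spec)
    vals <- if (cores > 1L) {
      unlist(parallel::mclapply(seq_len(nrow(pairs)), one, mc.cores = cores))
    } else vapply(seq_len(nrow(pairs)), one, numeric(1))
    values[upper.tri(values)] <- vals
    values[lower.tri(values)] <- t(values)[lower.tri(values)]
  }
  structure(list(labels = labels, values = values, spec = spec,
                 feature_mode = feature_mode),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> side %d (%s)\n", nrow(x$labels),
              paste(unique(x$labels$condition), collapse = ", ")))
  invisible(x)
}

#' Detect events in an NCD series
#'
#' An event is a time index where the series is a local maximum and exceeds
#' `median + k * MAD` of the whole series, with MAD the plain (unscaled)
#' median absolute deviation — a robust prominence floor that tolerates the
#' multi-regime structure of consecutive-state NCD series. Plateau ties
#' break toward the earlier index (a point counts as a local maximum when
#' it is strictly above its predecessor and at least as large as its
#' successor; series boundaries count as minus infinity).
#'
#' @param series Numeric series, typically from [consecutive_ncd_series()]
#'   (names, if present, are used as time indices; otherwise 0-based
#'   positions are used).
#' @param k Prominence factor (default 2).
#' @return Integer vector of event time indices, increasing.
#' @export
detect_events <- function(series, k = 2) {
  v <- as.numeric(series)
  n <- length(v)
  if (n == 0L) return(integer())
  med <- stats::median(v)
  thr <- med + k * stats::median(abs(v - med))
  prev <- c(-Inf, v[-n])
  nxt <- c(v[-1], -Inf)
  is_peak <- v > prev & v >= nxt & v > thr
  idx <- if (!is.null(names(series))) as.integer(names(series)) else seq_len(n) - 1L
  sort(idx[is_peak])
}

#' Most prominent events of an NCD series
#'
#' The `n` detected events (see [detect_events()]) with the largest series
#' values, returned in time order.
#'
#' @inheritParams detect_events
#' @param n Maximum number of events to keep.
#' @return Integer vector of at most `n` event time indices, increasing.
#' @export
top_events <- function(series, n = 3, k = 2) {
  ev <- detect_events(series, k = k)
  if (!length(ev)) return(ev)
  idx <- if (!is.null(names(series))) as.integer(names(series))
         else seq_along(series) - 1L
  h <- as.numeric(series)[match(ev, idx)]
  sort(ev[order(-h)][seq_len(min(n, length(ev)))])
}

## statistical mode (smallest value on ties)
mode_int <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_integer_)
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}

#' Ensemble-mode event times
#'
#' Computes [top_events()] for each run's consecutive-state NCD series and
#' returns, per event rank (earliest, second, ...), the mode of the time
#' index across runs.
#'
#' @param runs List of [run_result()] objects.
#' @param spec A [compressor_spec()].
#' @param n_events Number of event ranks to report.
#' @param feature_mode Serialization mode.
#' @param k Prominence factor for [detect_events()].
#' @return Integer vector of length `n_events` (NA where fewer events were
#'   detected across the ensemble).
#' @export
ensemble_event_times <- function(runs, spec = compressor_spec(), n_events = 3,
                                 feature_mode = "all", k = 2) {
  per_run <- lapply(runs, function(r) {
    ev <- top_events(consecutive_ncd_series(r, spec, feature_mode),
                     n = n_events, k = k)
    length(ev) <- n_events
    ev
  })
  m <- do.call(rbind, per_run)
  vapply(seq_len(n_events), function(j) mode_int(m[, j]), integer(1))
}
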
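# Convergence/divergence maps of information flow. Each point pairs the NCD
# between two states with the NCD between their immediate successors:
# x = NCD(s_i(t1), s_j(t2)), y = NCD(s_i(t1+1), s_j(t2+1)). Points below the
# diagonal are converging state pairs, points above are diverging; the 2D
# density of the point cloud maps the range of dynamical behaviour.

#' Build the flow point cloud of an ensemble
#'
#' Samples `n_select` runs without replacement and enumerates all admissible
#' state pairs over them: unordered pairs of (run, time) slots with both
#' times at most T-1 (so successors exist), excluding self pairs
#' (`i = j, t1 = t2`, whose NCD is the trivial self-distance). For each pair
#' the base NCD and the successor NCD are computed; successor sizes are
#' served from the compressor cache whenever the successor pair is itself
#' enumerated.
#'
#' The full enumeration over n runs with T usable times has
#' `choose(n * T, 2)` points; `max_points` caps this by uniform subsampling
#' of tuples (seed-controlled), which estimates the same density at desk
#' scale.
#'
#' @param runs List of [run_result()]s from one condition.
#' @param spec A [compressor_spec()].
#' @param n_select Number of runs to sample (default 20, the reference
#'   subsample).
#' @param seed Seed for the run subsample and tuple subsample.
#' @param max_points Cap on the number of tuples (default `Inf` =
#'   exhaustive).
#' @param feature_mode Serialization mode.
#' @return An object of class `flow_points`: data.frame with columns `i`,
#'   `j` (run ids), `t1`, `t2`, `x`, `y`; attributes `condition` and
#'   `runs_used`.
#' @export
build_flow_points <- function(runs, spec = compressor_spec(), n_select = 20L,
                              seed = 1L, max_points = Inf,
                              feature_mode = "all") {
  if (length(runs) < n_select)
    stop("fewer runs available (", length(runs), ") than n_select (", n_select, ")")
  sel <- with_seed(seed, sort(sample.int(length(runs), n_select)))
  runs <- runs[sel]
  T_use <- length(runs[[1]]$states) - 1L  # t1, t2 in 0..T-1
  n <- length(runs)

  ## slot s = (run r, time t): s = (r-1)*T_use + t + 1
  n_slot <- n * T_use
  pairs <- utils::combn(n_slot, 2L)
  if (is.finite(max_points) && ncol(pairs) > max_points) {
    keep <- with_seed(seed + 1L,
                      sort(sample.int(ncol(pairs), max_points)))
    pairs <- pairs[, keep, drop = FALSE]
  }
  r1 <- (pairs[1, ] - 1L) %/% T_use + 1L
  t1 <- (pairs[1, ] - 1L) %% T_use
  r2 <- (pairs[2, ] - 1L) %/% T_use + 1L
  t2 <- (pairs[2, ] - 1L) %% T_use

  bytes <- lapply(runs, serialize_run, feature_mode = feature_mode)
  x <- numeric(length(r1)); y <- numeric(length(r1))
  for (k in seq_along(r1)) {
    x[k] <- ncd(bytes[[r1[k]]][[t1[k] + 1L]], bytes[[r2[k]]][[t2[k] + 1L]], spec)
    y[k] <- ncd(bytes[[r1[k]]][[t1[k] + 2L]], bytes[[r2[k]]][[t2[k] + 2L]], spec)
  }
  run_ids <- vapply(runs, function(r) r$run_id, integer(1))
  structure(
    data.frame(i = run_ids[r1], j = run_ids[r2], t1 = t1, t2 = t2,
               x = x, y = y),
    condition = runs[[1]]$condition, runs_used = run_ids,
    class = c("flow_points", "data.frame"))
}

#' Number of admissible flow tuples
#'
#' Closed form for the exhaustive enumeration of [build_flow_points()]:
#' unordered pairs of (run, time) slots, self pairs excluded.
#'
#' @param n_runs Number of runs.
#' @param T_use Number of usable time points (T, i.e. states minus one).
#' @return Integer count `choose(n_runs * T_use, 2)`.
#' @export
n_flow_tuples <- function(n_runs, T_use) choose(n_runs * T_use, 2)

#' 2D Gaussian kernel density of a flow point cloud
#'
#' Binned 2D kernel density estimate with an axis-aligned product Gaussian
#' kernel and automatic per-axis plug-in bandwidth selection
#' ([KernSmooth::dpik()]). The evaluation lattice spans the data range
#' padded by 3 bandwidths per axis (or an explicit common `range` when
#' densities must be compared on the same grid).
#'
#' @param points A `flow_points` object, or any data.frame/list with
#'   numeric `x` and `y`.
#' @param grid_size Lattice resolution per axis (default 256).
#' @param range Optional list of two length-2 vectors (x and y limits).
#' @return An object of class `density_map`: `x1`, `x2` (grid coordinates),
#'   `fhat` (density matrix, integrates to ~1), `bandwidth` (per axis).
#' @export
estimate_density <- function(points, grid_size = 256L, range = NULL) {
  x <- points$x; y <- points$y
  if (length(x) < 10L)
    stop("need at least 10 points for a stable bandwidth selection")
  bw <- c(KernSmooth::dpik(x), KernSmooth::dpik(y))
  if (any(bw <= 0)) stop("degenerate point cloud: zero bandwidth selected")
  if (is.null(range))
    range <- list(base::range(x) + c(-3, 3) * bw[1],
                  base::range(y) + c(-3, 3) * bw[2])
  est <- KernSmooth::bkde2D(cbind(x, y), bandwidth = bw,
                            gridsize = c(grid_size, grid_size),
                            range.x = range)
  structure(list(x1 = est$x1, x2 = est$x2, fhat = est$fhat, bandwidth = bw,
                 n_points = length(x),
                 condition = attr(points, "condition")),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %dx%d grid, bandwidths (%.4g, %.4g), mass %.3f\n",
              length(x$x1), length(x$x2), x$bandwidth[1], x$bandwidth[2],
              density_mass(x)))
  invisible(x)
}

cell_area <- function(dmap) {
  diff(dmap$x1[1:2]) * diff(dmap$x2[1:2])
}

#' Integrated probability mass of a density map
#'
#' @param dmap A `density_map`.
#' @param band If given, restrict to the diagonal band `|y - x| <= band`.
#' @return Total (or in-band) probability mass.
#' @export
density_mass <- function(dmap, band = NULL) {
  f <- dmap$fhat
  if (!is.null(band)) {
    dx <- outer(dmap$x1, dmap$x2, function(a, b) abs(b - a))
    f <- f * (dx <= band)
  }
  sum(f) * cell_area(dmap)
}

#' Contour levels dense in low-probability regions
#'
#' Geometrically spaced levels between the smallest positive density on the
#' grid and the maximum: high resolution where the probability is small
#' (the "islands"), low resolution near the main peak.
#'
#' @param dmap A `density_map` (or numeric density values).
#' @param n_levels Number of levels (default 12).
#' @return Strictly increasing numeric vector of length `n_levels`.
#' @export
contour_levels <- function(dmap, n_levels = 12L) {
  f <- if (inherits(dmap, "density_map")) dmap$fhat else as.numeric(dmap)
  pos <- f[f > 0]
  if (!length(pos)) stop("density has no positive values")
  lo <- min(pos); hi <- max(pos)
  if (hi / lo < 1 + 1e-9)  # (near-)uniform density: narrow strictly-increasing band
    return(hi * seq(1 - 1e-6 * (n_levels - 1), 1, length.out = n_levels))
  exp(seq(log(lo), log(hi), length.out = n_levels))
}

## local maxima of a density matrix (8-neighbourhood), off the diagonal band
find_modes <- function(dmap, min_height = 0.05, band = 0.05) {
  f <- dmap$fhat
  nr <- nrow(f); nc <- ncol(f)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- f
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & f >= pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  is_max <- is_max & f >= min_height * max(f)
  offdiag <- outer(dmap$x1, dmap$x2, function(a, b) abs(b - a)) > band
  sum(is_max & offdiag)
}

#' Summary statistics of a flow point cloud
#'
#' Quantifies convergence/divergence: the fraction of points strictly below
#' the diagonal (`y < x`, converging pairs), strictly above (diverging), the
#' mean signed displacement `mean(y - x)`, and — when a `density_map` is
#' supplied or enough points are available — the number of off-diagonal
#' density modes ("islands" of constrained information flow).
#'
#' @param points A `flow_points` object.
#' @param dmap Optional `density_map` of the same points; computed on the
#'   fly when omitted and at least 10 points are available.
#' @param band Diagonal band half-width used for mode counting and diagonal
#'   mass (default 0.05).
#' @return List: `n`, `frac_converging`, `frac_diverging`, `mean_delta`,
#'   `diagonal_mass` and `n_offdiagonal_modes` (NA when no density).
#' @export
flow_summary <- function(points, dmap = NULL, band = 0.05) {
  d <- points$y - points$x
  if (is.null(dmap) && length(points$x) >= 10L)
    dmap <- tryCatch(estimate_density(points), error = function(e) NULL)
  list(n = length(d),
       frac_converging = mean(d < 0),
       frac_diverging = mean(d > 0),
       mean_delta = mean(d),
       diagonal_mass = if (!is.null(dmap)) density_mass(dmap, band = band) else NA_real_,
       n_offdiagonal_modes = if (!is.null(dmap)) find_modes(dmap, band = band)
                             else NA_integer_)
}

#' L1 distance between two density maps
#'
#' Integrated absolute difference of two densities estimated on a common
#' grid (build both with the same explicit `range` and `grid_size`). Ranges
#' from 0 (identical) to 2 (disjoint supports). Used to order knock-out
#' flow maps by their distance from wild type.
#'
#' @param a,b `density_map` objects on identical grids.
#' @return Numeric L1 distance.
#' @export
flow_l1_distance <- function(a, b) {
  if (length(a$x1) != length(b$x1) ||
      max(abs(a$x1 - b$x1)) > 1e-12 || max(abs(a$x2 - b$x2)) > 1e-12)
    stop("density maps must share the same evaluation grid; ",
         "estimate both with a common 'range'")
  sum(abs(a$fhat - b$fhat)) * cell_area(a)
}

#' Contour plot of a flow density map
#'
#' @param x A `density_map`.
#' @param n_levels Number of geometric contour levels.
#' @param ... Passed to [graphics::contour()].
#' @return `x`, invisibly.
#' @export
plot.density_map <- function(x, n_levels = 12L, ...) {
  graphics::contour(x$x1, x$x2, x$fhat, levels = contour_levels(x, n_levels),
                    drawlabels = FALSE,
                    xlab = "NCD(t)", ylab = "NCD(t+1)", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  if (!is.null(x$condition)) graphics::title(main = x$condition)
  invisible(x)
}
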
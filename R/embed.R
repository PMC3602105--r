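# Low-dimensional embedding of the global NCD matrix and quantitative
# trajectory divergence. NCD is a metric but its dynamic range is not linear;
# non-metric MDS works in rank space, which makes distances comparable across
# scales.

as_ncd_matrix <- function(D) {
  if (inherits(D, "distance_matrix")) return(D)
  if (is.matrix(D)) {
    if (nrow(D) != ncol(D)) stop("distance matrix must be square")
    if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
    return(structure(list(labels = data.frame(condition = NA_character_,
                                              run = NA_integer_,
                                              t = seq_len(nrow(D)) - 1L),
                          values = D),
                     class = "distance_matrix"))
  }
  stop("D must be a distance_matrix or a symmetric numeric matrix")
}

## Kruskal stress-1 of a configuration against a dissimilarity matrix:
## isotonic (primary, ties averaged) disparities of embedded distances
## against the rank order of the dissimilarities.
stress1 <- function(D, points) {
  d <- as.dist(D)
  e <- stats::dist(points)
  fit <- stats::isoreg(as.numeric(d), as.numeric(e))
  disp <- fit$yf[order(order(as.numeric(d)))]
  sqrt(sum((e - disp)^2) / sum(e^2))
}

make_embedding <- function(points, labels, stress, n_iterations = 0L,
                           converged = TRUE) {
  colnames(points) <- paste0("dim", seq_len(ncol(points)))
  structure(list(points = points, labels = labels, stress = stress,
                 n_iterations = n_iterations, converged = converged),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d states in %dD, stress-1 = %.4f%s\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Eigendecomposition of the double-centered squared-distance matrix;
#' coordinates along the top `dim` axes, with negative eigenvalues truncated
#' to zero. Exact for distances that are Euclidean in `dim` dimensions; used
#' as the initialization of [nonmetric_mds()].
#'
#' @param D A `distance_matrix` (from [global_distance_matrix()]) or a
#'   symmetric numeric matrix.
#' @param dim Embedding dimension (default 3).
#' @return An `embedding`: `points` (n x dim), `labels`, and the Kruskal
#'   `stress` of the configuration.
#' @export
classical_mds <- function(D, dim = 3L) {
  D <- as_ncd_matrix(D)
  n <- nrow(D$values)
  if (dim >= n) stop("dim must be smaller than the number of states")
  ## rank-deficient input (fewer positive eigenvalues than dim) is handled
  ## below by zero-padding; cmdscale's warning about it is redundant
  fit <- withCallingHandlers(
    stats::cmdscale(D$values, k = dim, eig = TRUE),
    warning = function(w) {
      if (grepl("eigenvalues", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  pts <- fit$points
  if (ncol(pts) < dim)  # rank-deficient input: pad with zero coordinates
    pts <- cbind(pts, matrix(0, n, dim - ncol(pts)))
  make_embedding(pts, D$labels, stress1(D$values, pts))
}

#' Non-metric multidimensional scaling of an NCD matrix
#'
#' Iterative minimization of Kruskal's stress-1 with monotone (isotonic)
#' regression on the disparities, initialized from the classical MDS
#' solution. Only the rank order of the input NCDs is honoured, matching the
#' rank-based character of compression distances.
#'
#' If the stress cannot be decreased within `maxit` iterations the
#' best-so-far configuration is returned with `converged = FALSE` and a
#' warning.
#'
#' @inheritParams classical_mds
#' @param init Optional initial `embedding` (default: [classical_mds()]).
#' @param maxit Maximum number of stress-minimization iterations.
#' @param tol Relative stress-improvement convergence tolerance.
#' @return An `embedding` with the achieved `stress` (in \[0, 1\]).
#' @export
nonmetric_mds <- function(D, dim = 3L, init = NULL, maxit = 300L, tol = 1e-6) {
  D <- as_ncd_matrix(D)
  if (is.null(init)) init <- classical_mds(D, dim)
  stopifnot(ncol(init$points) == dim, nrow(init$points) == nrow(D$values))
  V <- D$values
  ## isoMDS requires positive off-diagonal dissimilarities
  eps <- 1e-9
  V[V <= 0] <- eps
  diag(V) <- 0
  fit <- suppressWarnings(
    MASS::isoMDS(stats::as.dist(V), y = init$points, k = dim,
                 maxit = maxit, tol = tol, trace = FALSE))
  stress <- fit$stress / 100  # isoMDS reports percent
  if (stress > init$stress + 1e-8) {
    warning("non-metric MDS failed to improve on the initialization; ",
            "returning the initial configuration")
    return(make_embedding(init$points, D$labels, init$stress,
                          n_iterations = maxit, converged = FALSE))
  }
  make_embedding(fit$points, D$labels, stress, n_iterations = maxit,
                 converged = TRUE)
}

#' Trajectory divergence from a reference condition
#'
#' Averages the embedded coordinates over runs within each (condition, t)
#' group, producing one mean trajectory per condition, and computes the
#' per-time-point Euclidean distance between each condition's trajectory
#' and the reference trajectory.
#'
#' @param embedding An `embedding` whose labels carry `condition`, `run`,
#'   `t` (as produced via [global_distance_matrix()]).
#' @param reference Reference condition label (default `"wt"`).
#' @return A `data.frame` with one row per (condition, t): mean coordinates
#'   `dim1..dimK`, and `divergence` (Euclidean distance to the reference
#'   mean at the same t; exactly 0 for the reference itself).
#' @export
trajectory_divergence <- function(embedding, reference = "wt") {
  lb <- embedding$labels
  if (!reference %in% lb$condition)
    stop("reference condition '", reference, "' not present in the embedding")
  out <- stats::aggregate(embedding$points,
                          by = list(condition = lb$condition, t = lb$t),
                          FUN = mean)
  out$t <- as.integer(out$t)
  ref <- out[out$condition == reference, ]
  ref <- ref[order(ref$t), ]
  dims <- grep("^dim", names(out))
  out$divergence <- NA_real_
  for (i in seq_len(nrow(out))) {
    r <- ref[match(out$t[i], ref$t), dims]
    if (!anyNA(r))
      out$divergence[i] <- sqrt(sum((unlist(out[i, dims]) - unlist(r))^2))
  }
  out <- out[order(out$condition, out$t), ]
  rownames(out) <- NULL
  out
}

#' Time-averaged divergence per condition
#'
#' @param curves Output of [trajectory_divergence()].
#' @return Named numeric vector: mean divergence over time per condition.
#' @export
mean_divergence <- function(curves) {
  sort(tapply(curves$divergence, curves$condition, mean))
}
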
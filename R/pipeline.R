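# End-to-end orchestration: a manifest fully determines every output of the
# reproduction pipeline (simulate -> NCD -> events / embedding / flow maps).

#' Experiment manifest
#'
#' Describes a complete experiment: the conditions to simulate, ensemble
#' sizes, seeds, compressor and which analyses to run. A manifest fully
#' determines all outputs (the pipeline is deterministic given the
#' manifest).
#'
#' The default `runs = 20` is a desk-scale ensemble; the reference design
#' uses 50 runs per condition. `embed_runs`/`embed_stride` and
#' `flow_max_points` bound the quadratic NCD cost of the embedding and flow
#' analyses: the embedding uses the first `embed_runs` runs of each
#' condition on the time grid `seq(0, T, by = embed_stride)`, and flow maps
#' subsample at most `flow_max_points` tuples.
#'
#' @param conditions Character vector of condition labels (see
#'   [condition_config()]): `"wt"`, `"ko:<target>[:<efficiency>]"`,
#'   `"ratio:<Treg>:<nTh>"`, `"random"`.
#' @param runs Runs per condition.
#' @param base_seed Integer; per-condition base seeds are derived from it.
#' @param T Simulated hours.
#' @param compressor A [compressor_spec()].
#' @param analyses Subset of `c("events", "embed", "flowmap")`.
#' @param reference Reference condition for divergence curves.
#' @param embed_runs Runs per condition entering the global distance matrix.
#' @param embed_stride Time stride of the embedding grid.
#' @param flow_runs Runs entering each flow map (reference: 20).
#' @param flow_max_points Tuple cap per flow map.
#' @param out_dir Optional output directory for TSV reports; existing files
#'   are never overwritten (resume semantics).
#' @return An object of class `experiment_manifest`.
#' @export
experiment_manifest <- function(conditions = c("wt", "ko:IL-10:1",
                                               "ko:IFN-g:1", "ko:CTLA-4:1"),
                                runs = 20L, base_seed = 1L, T = 30L,
                                compressor = compressor_spec(),
                                analyses = c("events", "embed", "flowmap"),
                                reference = "wt",
                                embed_runs = min(runs, 5L),
                                embed_stride = 2L,
                                flow_runs = min(runs, 20L),
                                flow_max_points = 6000L,
                                out_dir = NULL) {
  m <- structure(list(conditions = conditions, runs = as.integer(runs),
                      base_seed = as.integer(base_seed), T = as.integer(T),
                      compressor = compressor, analyses = analyses,
                      reference = reference,
                      embed_runs = as.integer(embed_runs),
                      embed_stride = as.integer(embed_stride),
                      flow_runs = as.integer(flow_runs),
                      flow_max_points = flow_max_points,
                      out_dir = out_dir),
                 class = "experiment_manifest")
  validate_manifest(m)
}

#' Validate an experiment manifest
#'
#' Schema and cross-field checks: resolvable condition labels, efficiencies
#' in \[0, 1\], ratio counts summing to 100, known analysis toggles,
#' positive ensemble sizes. All problems are reported together.
#'
#' @param m An [experiment_manifest()].
#' @return `m` invisibly, or an error listing every offending field.
#' @export
validate_manifest <- function(m) {
  errs <- character()
  if (!length(m$conditions)) errs <- c(errs, "conditions: must not be empty")
  for (cond in m$conditions) {
    ok <- tryCatch({ condition_config(cond, T = m$T); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) errs <- c(errs, sprintf("conditions: '%s' invalid (%s)", cond, ok))
  }
  if (m$runs < 1L) errs <- c(errs, "runs: must be >= 1")
  if (m$T < 1L) errs <- c(errs, "T: must be >= 1")
  bad <- setdiff(m$analyses, c("events", "embed", "flowmap"))
  if (length(bad)) errs <- c(errs, paste0("analyses: unknown toggle ",
                                          paste(bad, collapse = ", ")))
  if (!inherits(m$compressor, "compressor_spec"))
    errs <- c(errs, "compressor: must be a compressor_spec")
  if (m$embed_runs > m$runs) errs <- c(errs, "embed_runs: exceeds runs")
  if (m$flow_runs > m$runs) errs <- c(errs, "flow_runs: exceeds runs")
  if ("embed" %in% m$analyses && !m$reference %in% m$conditions &&
      !any(startsWith(m$conditions, m$reference)))
    errs <- c(errs, "reference: not among the conditions")
  if (length(errs)) stop("invalid manifest:\n  ", paste(errs, collapse = "\n  "),
                         call. = FALSE)
  invisible(m)
}

#' @export
print.experiment_manifest <- function(x, ...) {
  cat(sprintf("<experiment_manifest> %d condition(s) x %d runs, T=%d, seed=%d\n",
              length(x$conditions), x$runs, x$T, x$base_seed))
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  analyses:", paste(x$analyses, collapse = ", "), "\n")
  invisible(x)
}

write_tsv_once <- function(df, path) {
  if (is.null(path)) return(invisible(NULL))
  if (file.exists(path)) return(invisible(NULL))  # resume: never overwrite
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reproduce the full analysis for a manifest
#'
#' Simulates every condition's ensemble, then runs the toggled analyses:
#' `events` (per-run consecutive-state NCD series, ensemble-mode event
#' times), `embed` (global NCD matrix over a reduced run/time grid,
#' non-metric MDS, divergence curves against the reference condition) and
#' `flowmap` (flow point clouds, densities and summaries, on a common grid
#' so that L1 distances to the reference are comparable).
#'
#' All randomness derives from `base_seed`; the compressed-size cache makes
#' re-runs of overlapping analyses cheap, and when `out_dir` is set,
#' existing output files are left untouched.
#'
#' @param m An [experiment_manifest()].
#' @param verbose Print progress messages.
#' @return An `infodyn_report`: list with `manifest`, `ensembles` (labels
#'   only), `matrix_side`, per-condition `events`, `divergence`,
#'   `flow` (summaries and L1 distance to the reference), and the
#'   compressor `cache` statistics.
#' @export
reproduce <- function(m, verbose = interactive()) {
  validate_manifest(m)
  say <- function(...) if (verbose) message(sprintf(...))
  spec <- m$compressor

  ensembles <- list()
  for (k in seq_along(m$conditions)) {
    cfg <- condition_config(m$conditions[k], T = m$T)
    label <- cfg$condition
    say("simulating %s (%d runs)", label, m$runs)
    ensembles[[label]] <- run_ensemble(cfg, m$runs,
                                       base_seed = m$base_seed + 1000L * k)
  }

  n_states <- sum(vapply(ensembles, function(e)
    sum(vapply(e, function(r) length(r$states), integer(1))), integer(1)))
  design <- global_distance_matrix(ensembles, spec, compute = FALSE)
  report <- list(manifest = m,
                 conditions = names(ensembles),
                 n_states = n_states,
                 matrix_side = nrow(design$labels))

  if ("events" %in% m$analyses) {
    say("event detection")
    report$events <- lapply(ensembles, ensemble_event_times, spec = spec)
    ev <- do.call(rbind, lapply(names(report$events), function(cond)
      data.frame(condition = cond, rank = seq_along(report$events[[cond]]),
                 t = report$events[[cond]])))
    if (!is.null(m$out_dir)) {
      dir.create(m$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_tsv_once(ev, file.path(m$out_dir, "events.tsv"))
    }
  }

  ref_label <- condition_config(
    m$conditions[which(m$conditions == m$reference |
                         startsWith(m$conditions, m$reference))[1]],
    T = m$T)$condition

  if ("embed" %in% m$analyses) {
    say("embedding (%d runs/condition, stride %d)", m$embed_runs, m$embed_stride)
    sub <- lapply(ensembles, function(e) e[seq_len(m$embed_runs)])
    D <- global_distance_matrix(sub, spec,
                                times = seq(0L, m$T, by = m$embed_stride))
    emb <- nonmetric_mds(D, dim = 3L)
    report$embedding_stress <- emb$stress
    report$divergence <- trajectory_divergence(emb, reference = ref_label)
    report$mean_divergence <- mean_divergence(report$divergence)
    if (!is.null(m$out_dir))
      write_tsv_once(report$divergence, file.path(m$out_dir, "divergence.tsv"))
  }

  if ("flowmap" %in% m$analyses) {
    say("flow maps (%d runs, <= %g points)", m$flow_runs, m$flow_max_points)
    pts <- lapply(ensembles, function(e)
      build_flow_points(e, spec, n_select = m$flow_runs,
                        seed = m$base_seed, max_points = m$flow_max_points))
    rng_all <- range(unlist(lapply(pts, function(p) c(p$x, p$y))))
    common <- list(rng_all + c(-0.05, 0.05), rng_all + c(-0.05, 0.05))
    dens <- lapply(pts, estimate_density, range = common)
    report$flow <- lapply(names(pts), function(cond) {
      s <- flow_summary(pts[[cond]], dens[[cond]])
      s$l1_to_reference <- flow_l1_distance(dens[[cond]], dens[[ref_label]])
      s
    })
    names(report$flow) <- names(pts)
    if (!is.null(m$out_dir))
      for (cond in names(pts))
        write_tsv_once(as.data.frame(pts[[cond]]),
                       file.path(m$out_dir, paste0("flow_", cond, ".tsv")))
  }

  report$cache <- cache_stats(spec)
  structure(report, class = "infodyn_report")
}

#' @export
print.infodyn_report <- function(x, ...) {
  cat(sprintf("<infodyn_report> %d condition(s), %d states, matrix side %d\n",
              length(x$conditions), x$n_states, x$matrix_side))
  if (!is.null(x$events)) {
    cat("  event times (mode):\n")
    for (cond in names(x$events))
      cat(sprintf("    %-16s %s\n", cond,
                  paste(x$events[[cond]], collapse = ", ")))
  }
  if (!is.null(x$mean_divergence)) {
    cat("  time-averaged divergence from reference:\n")
    md <- x$mean_divergence
    for (cond in names(md)) cat(sprintf("    %-16s %.4f\n", cond, md[[cond]]))
  }
  if (!is.null(x$flow)) {
    cat("  flow maps:\n")
    for (cond in names(x$flow)) {
      s <- x$flow[[cond]]
      cat(sprintf("    %-16s diag mass %.3f  conv %.3f  div %.3f  L1->ref %.3f\n",
                  cond, s$diagonal_mass, s$frac_converging, s$frac_diverging,
                  s$l1_to_reference))
    }
  }
  cat(sprintf("  compressor calls %d (%d cache hits)\n",
              x$cache$calls, x$cache$hits))
  invisible(x)
}

#' Plot divergence curves
#'
#' @param curves Output of [trajectory_divergence()].
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the wide matrix of divergence curves.
#' @export
plot_divergence <- function(curves, ...) {
  w <- stats::reshape(curves[, c("condition", "t", "divergence")],
                      direction = "wide", idvar = "t", timevar = "condition")
  w <- w[order(w$t), ]
  mat <- as.matrix(w[, -1, drop = FALSE])
  colnames(mat) <- sub("^divergence\\.", "", colnames(mat))
  graphics::matplot(w$t, mat, type = "l", lty = 1, xlab = "t (hours)",
                    ylab = "divergence from reference", ...)
  graphics::legend("topleft", legend = colnames(mat), lty = 1,
                   col = seq_len(ncol(mat)), bty = "n", cex = 0.8)
  invisible(mat)
}

#' Write an ensemble as state files
#'
#' One file per state, named `<condition>_run<r>_t<t>.txt`, in the
#' tab-delimited dialect of [write_state_file()].
#'
#' @param runs List of [run_result()]s.
#' @param dir Output directory (created if needed).
#' @param feature_mode Serialization mode.
#' @return Character vector of file paths, invisibly.
#' @export
write_ensemble <- function(runs, dir, feature_mode = "all") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (run in runs) {
    for (s in run$states) {
      p <- file.path(dir, sprintf("%s_run%d_t%d.txt", run$condition,
                                  run$run_id, s$t))
      if (!file.exists(p)) write_state_file(s, feature_mode, path = p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
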
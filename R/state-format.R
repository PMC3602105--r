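# Domain vocabulary of the simulated system. Canonical orders are fixed so that
# serialization is stable across platforms and locales.

#' Known cell types, behavioral states, molecules and receptors
#'
#' Fixed vocabularies of the simulated immune system. `cell_types()` lists the
#' six T cell populations, `behavior_states()` the behavioral annotations a
#' cell can carry, `molecule_names()` the five diffusible molecules and
#' `receptor_names()` the membrane receptors, each in its canonical
#' serialization order.
#'
#' @return A character vector.
#' @name vocabulary
NULL

#' @rdname vocabulary
#' @export
cell_types <- function() {
  c("Treg", "ActivatedTreg", "nTh", "Th1", "ActivatedTh1", "SuppressedTh1")
}

#' @rdname vocabulary
#' @export
behavior_states <- function() {
  c("Resting", "Activating", "Secreting", "Suppressed", "Proliferating")
}

#' @rdname vocabulary
#' @export
molecule_names <- function() {
  c("HSP60", "aCD3", "IL-10", "IFN-g", "TNF-a")
}

#' @rdname vocabulary
#' @export
receptor_names <- function() {
  c("TLR2", "CD3", "B7", "IL-10R", "CTLA-4", "IFN-gR")
}

## number formats of the dialect: expression levels with 2 decimals,
## concentrations with 4; both are round-trip exact because the simulator
## quantizes to the same precision.
fmt_level <- function(x) sprintf("%.2f", x)
fmt_conc  <- function(x) sprintf("%.4f", x)

empty_cells_df <- function() {
  data.frame(index = integer(), name = character(), lifespan = integer(),
             behavior = character(), row = integer(), col = integer(),
             stringsAsFactors = FALSE)
}

empty_receptors_df <- function() {
  data.frame(cell_index = integer(), name = character(), level = numeric(),
             stringsAsFactors = FALSE)
}

empty_molecules_df <- function() {
  data.frame(row = integer(), col = integer(), name = character(),
             conc = numeric(), stringsAsFactors = FALSE)
}

#' Construct a system state
#'
#' A `system_state` is a full snapshot of the simulation grid at one time
#' point: every cell (with its receptors) and every non-zero molecule
#' concentration, by grid location. It is the object whose byte serialization
#' is handed to the compressor.
#'
#' Coordinates are 0-based and row-major: `0 <= row < n_rows`,
#' `0 <= col < n_cols`. Empty locations are represented implicitly (every
#' location gets a line on serialization); there is no occupancy limit.
#'
#' @param t Integer time index (hours).
#' @param n_rows,n_cols Grid dimensions (default 20 x 20).
#' @param cells `data.frame` with columns `index` (unique integer id), `name`
#'   (one of [cell_types()]), `lifespan` (non-negative integer, remaining
#'   hours), `behavior` (one of [behavior_states()]), `row`, `col`.
#' @param receptors `data.frame` with columns `cell_index`, `name` (one of
#'   [receptor_names()]), `level` (non-negative expression level).
#' @param molecules `data.frame` with columns `row`, `col`, `name` (one of
#'   [molecule_names()]), `conc` (positive concentration; zero-concentration
#'   records are not stored).
#' @return An object of class `system_state`.
#' @seealso [write_state_file()], [read_state_file()], [canonical_serialize()]
#' @export
system_state <- function(t = 0L, n_rows = 20L, n_cols = 20L,
                         cells = empty_cells_df(),
                         receptors = empty_receptors_df(),
                         molecules = empty_molecules_df()) {
  s <- structure(
    list(t = as.integer(t), n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols),
         cells = as.data.frame(cells), receptors = as.data.frame(receptors),
         molecules = as.data.frame(molecules)),
    class = "system_state")
  validate_system_state(s)
}

#' Validate a system state
#'
#' Checks the structural invariants: known names, unique cell indices,
#' in-range coordinates, non-negative lifespans, expression levels and
#' concentrations, and receptors that reference existing cells.
#'
#' @param s A [system_state()].
#' @return `s`, invisibly unchanged, or an error describing the violation.
#' @export
validate_system_state <- function(s) {
  stopifnot(inherits(s, "system_state"))
  if (s$n_rows < 1L || s$n_cols < 1L) stop("grid dimensions must be positive")
  cl <- s$cells
  if (nrow(cl)) {
    if (anyDuplicated(cl$index)) stop("cell indices must be unique within a state")
    if (!all(cl$name %in% cell_types()))
      stop("unknown cell type: ", paste(setdiff(cl$name, cell_types()), collapse = ", "))
    if (!all(cl$behavior %in% behavior_states()))
      stop("unknown behavioral state: ",
           paste(setdiff(cl$behavior, behavior_states()), collapse = ", "))
    if (any(cl$lifespan < 0)) stop("remaining_lifespan must be non-negative")
    if (any(cl$row < 0 | cl$row >= s$n_rows | cl$col < 0 | cl$col >= s$n_cols))
      stop("cell position outside the grid")
  }
  rc <- s$receptors
  if (nrow(rc)) {
    if (!all(rc$name %in% receptor_names()))
      stop("unknown receptor: ", paste(setdiff(rc$name, receptor_names()), collapse = ", "))
    if (any(rc$level < 0)) stop("receptor expression level must be non-negative")
    if (!all(rc$cell_index %in% cl$index))
      stop("receptor record references a cell index not present in the state")
  }
  ml <- s$molecules
  if (nrow(ml)) {
    if (!all(ml$name %in% molecule_names()))
      stop("unknown molecule: ", paste(setdiff(ml$name, molecule_names()), collapse = ", "))
    if (any(ml$conc < 0)) stop("concentration must be non-negative")
    if (any(ml$row < 0 | ml$row >= s$n_rows | ml$col < 0 | ml$col >= s$n_cols))
      stop("molecule record outside the grid")
    if (anyDuplicated(ml[, c("row", "col", "name")]))
      stop("duplicate molecule record for a grid location")
  }
  invisible(s)
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> t=%d  grid %dx%d  cells=%d  molecule records=%d\n",
              x$t, x$n_rows, x$n_cols, nrow(x$cells), nrow(x$molecules)))
  if (nrow(x$cells)) {
    tb <- table(x$cells$name)
    cat("  ", paste(sprintf("%s=%d", names(tb), tb), collapse = "  "), "\n")
  }
  invisible(x)
}

check_feature_mode <- function(feature_mode) {
  if (length(feature_mode) != 1L ||
      !feature_mode %in% c("all", "cells_only", "molecules_only"))
    stop("feature_mode must be one of 'all', 'cells_only', 'molecules_only'")
  feature_mode
}

## Build the per-location text lines. `canonical` sorts cells by index and
## receptors/molecules by their fixed vocabulary order, making the bytes
## invariant to internal container ordering.
state_lines <- function(s, feature_mode = "all", canonical = TRUE) {
  validate_system_state(s)
  check_feature_mode(feature_mode)
  n_loc <- s$n_rows * s$n_cols
  loc_of <- function(row, col) row * s$n_cols + col + 1L  # row-major, 1-based slot

  cell_seg <- character(n_loc)
  if (feature_mode != "molecules_only" && nrow(s$cells)) {
    cl <- s$cells
    rc <- s$receptors
    if (canonical) cl <- cl[order(cl$index), , drop = FALSE]
    rec_txt <- character(nrow(cl))
    if (nrow(rc)) {
      if (canonical)
        rc <- rc[order(match(rc$name, receptor_names())), , drop = FALSE]
      grp <- split(paste(rc$name, fmt_level(rc$level), sep = "\t"), rc$cell_index)
      hit <- match(as.character(cl$index), names(grp))
      rec_txt <- vapply(hit, function(i) {
        if (is.na(i)) "" else paste(grp[[i]], collapse = "\t")
      }, character(1))
    }
    cell_txt <- paste0(cl$index, "\t", cl$name, "\t", cl$lifespan, "\t", cl$behavior,
                       ifelse(nzchar(rec_txt), paste0("\t", rec_txt), ""))
    seg <- vapply(split(cell_txt, loc_of(cl$row, cl$col)),
                  paste, character(1), collapse = "\t")
    idx <- as.integer(names(seg))
    cell_seg[idx] <- paste0("\tCELLS:\t", seg)
  }

  mol_seg <- character(n_loc)
  if (feature_mode != "cells_only" && nrow(s$molecules)) {
    ml <- s$molecules
    ml <- ml[ml$conc > 0, , drop = FALSE]
    if (nrow(ml)) {
      if (canonical)
        ml <- ml[order(match(ml$name, molecule_names())), , drop = FALSE]
      mol_txt <- paste(ml$name, fmt_conc(ml$conc), sep = "\t")
      seg <- vapply(split(mol_txt, loc_of(ml$row, ml$col)),
                    paste, character(1), collapse = "\t")
      idx <- as.integer(names(seg))
      mol_seg[idx] <- paste0("\tMOLECULES:\t", seg)
    }
  }

  rows <- rep(0:(s$n_rows - 1L), each = s$n_cols)
  cols <- rep(0:(s$n_cols - 1L), times = s$n_rows)
  paste0(rows, ",", cols, cell_seg, mol_seg)
}

#' Serialize a system state to the tab-delimited dialect
#'
#' `write_state_file()` emits one ASCII text line per grid location in
#' row-major order. Each line starts with the location id `"row,col"`; if the
#' location holds cells (and `feature_mode` does not suppress them) a
#' `CELLS:` segment follows with, per cell, its index, name, remaining
#' lifespan and behavioral state, then `name`/`expression level` pairs for
#' its receptors; molecule records follow in a `MOLECULES:` segment as
#' `name`/`concentration` pairs. Fields are tab-separated, lines end in
#' `"\n"`, expression levels print with 2 and concentrations with 4 decimal
#' places. A segment that is empty (or suppressed) is omitted together with
#' its sentinel, so an empty location line is just the location id.
#'
#' `canonical_serialize()` additionally sorts cells by index and
#' receptors/molecules by their canonical vocabulary order, so equal states
#' yield identical bytes regardless of internal container ordering. This is
#' the byte object handed to the compressor by the NCD layer.
#'
#' @param state A [system_state()].
#' @param feature_mode `"all"` (default), `"cells_only"` (suppress the
#'   molecule segment) or `"molecules_only"` (suppress the cell segment).
#'   Feature-restricted serializations support molecular-only / cellular-only
#'   analyses.
#' @param path Optional file path; when given the bytes are also written to
#'   disk. Conventional naming is `<condition>_run<r>_t<t>.txt`.
#' @return A raw vector of serialized bytes (invisibly for
#'   `write_state_file()` when `path` is given).
#' @examples
#' s <- system_state(t = 0, n_rows = 2, n_cols = 2)
#' rawToChar(canonical_serialize(s))
#' @export
write_state_file <- function(state, feature_mode = "all", path = NULL) {
  lines <- state_lines(state, feature_mode, canonical = FALSE)
  out <- charToRaw(paste0(paste(lines, collapse = "\n"), "\n"))
  if (!is.null(path)) {
    writeBin(out, path)
    return(invisible(out))
  }
  out
}

#' @rdname write_state_file
#' @export
canonical_serialize <- function(state, feature_mode = "all") {
  lines <- state_lines(state, feature_mode, canonical = TRUE)
  charToRaw(paste0(paste(lines, collapse = "\n"), "\n"))
}

#' Read a state file
#'
#' Inverse of [write_state_file()]: parses the tab-delimited dialect back
#' into a [system_state()]. Grid dimensions are inferred from the location
#' ids (all locations are represented, including empty ones). The time index
#' is not part of the on-disk format (one file per time point; the index
#' lives in the file name), so it is supplied via `t`.
#'
#' @param x A raw vector, a single string of file content, or a path to a
#'   file readable by [readLines()].
#' @param t Time index to stamp on the returned state (default 0).
#' @return A [system_state()].
#' @export
read_state_file <- function(x, t = 0L) {
  if (is.raw(x)) {
    txt <- rawToChar(x)
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  } else if (is.character(x) && length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x)
  } else if (is.character(x)) {
    lines <- strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  } else {
    stop("x must be a raw vector, file path or character content")
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty state file")

  perr <- function(i, msg) stop(sprintf("state file parse error at line %d: %s", i, msg),
                                call. = FALSE)
  tok <- strsplit(lines, "\t", fixed = TRUE)

  cells <- vector("list", length(lines))
  recs  <- vector("list", length(lines))
  mols  <- vector("list", length(lines))
  locs  <- matrix(NA_integer_, length(lines), 2L)

  for (i in seq_along(tok)) {
    f <- tok[[i]]
    loc <- strsplit(f[1], ",", fixed = TRUE)[[1]]
    if (length(loc) != 2L || anyNA(suppressWarnings(as.integer(loc))))
      perr(i, paste0("malformed location id '", f[1], "'"))
    locs[i, ] <- as.integer(loc)
    j <- 2L
    n <- length(f)
    if (j <= n && f[j] == "CELLS:") {
      j <- j + 1L
      ci <- integer(); cn <- character(); clife <- integer(); cb <- character()
      rci <- integer(); rn <- character(); rl <- numeric()
      while (j <= n && f[j] != "MOLECULES:") {
        if (j + 3L > n) perr(i, "truncated cell record")
        idx <- suppressWarnings(as.integer(f[j]))
        if (is.na(idx)) perr(i, paste0("bad cell index '", f[j], "'"))
        if (!f[j + 1L] %in% cell_types())
          perr(i, paste0("unknown cell name '", f[j + 1L], "'"))
        life <- suppressWarnings(as.integer(f[j + 2L]))
        if (is.na(life) || life < 0) perr(i, "bad remaining lifespan")
        if (!f[j + 3L] %in% behavior_states())
          perr(i, paste0("unknown behavioral state '", f[j + 3L], "'"))
        ci <- c(ci, idx); cn <- c(cn, f[j + 1L])
        clife <- c(clife, life); cb <- c(cb, f[j + 3L])
        j <- j + 4L
        while (j <= n && f[j] %in% receptor_names()) {
          if (j + 1L > n) perr(i, "receptor record missing expression level")
          lev <- suppressWarnings(as.numeric(f[j + 1L]))
          if (is.na(lev) || lev < 0) perr(i, "bad receptor expression level")
          rci <- c(rci, idx); rn <- c(rn, f[j]); rl <- c(rl, lev)
          j <- j + 2L
        }
      }
      if (length(ci)) {
        cells[[i]] <- data.frame(index = ci, name = cn, lifespan = clife,
                                 behavior = cb, row = locs[i, 1], col = locs[i, 2],
                                 stringsAsFactors = FALSE)
        if (length(rci))
          recs[[i]] <- data.frame(cell_index = rci, name = rn, level = rl,
                                  stringsAsFactors = FALSE)
      }
    }
    if (j <= n && f[j] == "MOLECULES:") {
      j <- j + 1L
      mn <- character(); mc <- numeric()
      while (j <= n) {
        if (j + 1L > n) perr(i, "molecule record missing concentration")
        if (!f[j] %in% molecule_names())
          perr(i, paste0("unknown molecule name '", f[j], "'"))
        conc <- suppressWarnings(as.numeric(f[j + 1L]))
        if (is.na(conc)) perr(i, "bad concentration")
        if (conc < 0) perr(i, "negative concentration")
        mn <- c(mn, f[j]); mc <- c(mc, conc)
        j <- j + 2L
      }
      if (length(mn))
        mols[[i]] <- data.frame(row = locs[i, 1], col = locs[i, 2], name = mn,
                                conc = mc, stringsAsFactors = FALSE)
    } else if (j <= n) {
      perr(i, paste0("unexpected token '", f[j], "'"))
    }
  }

  if (anyDuplicated(locs)) stop("duplicate grid location in state file")
  cells <- do.call(rbind, cells[!vapply(cells, is.null, logical(1))])
  recs  <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  mols  <- do.call(rbind, mols[!vapply(mols, is.null, logical(1))])
  system_state(t = t,
               n_rows = max(locs[, 1]) + 1L, n_cols = max(locs[, 2]) + 1L,
               cells = if (is.null(cells)) empty_cells_df() else cells,
               receptors = if (is.null(recs)) empty_receptors_df() else recs,
               molecules = if (is.null(mols)) empty_molecules_df() else mols)
}

#' Bundle the states of one simulation run
#'
#' @param run_id Integer run identifier.
#' @param condition Condition label (e.g. `"wt"`, `"ko_IL-10_1"`).
#' @param states List of [system_state()] objects strictly ordered by `t`,
#'   with no gaps (t = 0..T).
#' @return An object of class `run_result`.
#' @export
run_result <- function(run_id, condition, states) {
  ts <- vapply(states, function(s) s$t, integer(1))
  if (!identical(ts, seq.int(0L, length.out = length(states))))
    stop("states must be ordered t = 0..T with no gaps")
  structure(list(run_id = as.integer(run_id), condition = as.character(condition),
                 states = states),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> condition=%s run=%d states t=0..%d\n",
              x$condition, x$run_id, length(x$states) - 1L))
  invisible(x)
}
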
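# Synchronous agent-based emulation of the Treg/nTh immune system on a 2D
# grid. A simulation world carries, besides the observable snapshot (cells,
# receptors, molecule fields), the hidden per-cell bookkeeping that drives the
# dynamics: accumulated ligand doses and scheduled transition times.

RECEPTOR_COLS <- c("TLR2" = "r_TLR2", "CD3" = "r_CD3", "B7" = "r_B7",
                   "IL-10R" = "r_IL10R", "CTLA-4" = "r_CTLA4",
                   "IFN-gR" = "r_IFNgR")

## which receptor consumes which molecule (TNF-a has no simulated receptor:
## it is secreted and recorded only)
LIGAND_RECEPTOR <- c("HSP60" = "TLR2", "aCD3" = "CD3", "IL-10" = "IL-10R",
                     "IFN-g" = "IFN-gR", "TNF-a" = NA)

receptor_set <- function(type) {
  switch(type,
         Treg          = c("TLR2", "CD3"),
         ActivatedTreg = c("TLR2", "CD3", "CTLA-4"),
         nTh           = c("CD3", "B7"),
         Th1           = c("CD3", "B7", "IL-10R", "IFN-gR"),
         ActivatedTh1  = c("CD3", "B7", "IL-10R", "IFN-gR"),
         SuppressedTh1 = c("CD3", "B7", "IL-10R"),
         stop("unknown cell type ", type))
}

## per-cell heterogeneous expression level, quantized to the 2-decimal dialect
draw_level <- function(n, mean_level, jitter) {
  round(mean_level * stats::runif(n, 1 - jitter, 1 + jitter), 2)
}

## transition time: normal around the window centre, truncated at 2 sd
draw_time <- function(n, center, sd) {
  center + pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd)
}

quantize_field <- function(M, quantum, floor) {
  M[M < floor] <- 0
  round(M / quantum) * quantum
}

## uniform 4-neighbour redistribution of a fixed fraction, reflecting
## boundaries (flux that would leave the grid returns to its source);
## mass-conserving
diffuse_field <- function(M, frac) {
  if (frac <= 0) return(M)
  nr <- nrow(M); nc <- ncol(M)
  f4 <- frac / 4
  out <- M * (1 - frac)
  if (nr > 1) {
    out[-1, ]  <- out[-1, ]  + M[-nr, ] * f4
    out[-nr, ] <- out[-nr, ] + M[-1, ]  * f4
    out[1, ]   <- out[1, ]   + M[1, ]   * f4
    out[nr, ]  <- out[nr, ]  + M[nr, ]  * f4
  } else out <- out + 2 * f4 * M
  if (nc > 1) {
    out[, -1]  <- out[, -1]  + M[, -nc] * f4
    out[, -nc] <- out[, -nc] + M[, -1]  * f4
    out[, 1]   <- out[, 1]   + M[, 1]   * f4
    out[, nc]  <- out[, nc]  + M[, nc]  * f4
  } else out <- out + 2 * f4 * M
  out
}

new_cells <- function(n, type, cfg, start_index, row, col) {
  df <- data.frame(
    index = seq.int(start_index, length.out = n), type = rep(type, n),
    lifespan = rep(cfg$initial_lifespan, n), behavior = rep("Resting", n),
    row = row, col = col,
    act_dose = rep(0, n), ifng_dose = rep(0, n), sup_dose = rep(0, n),
    tau_act = rep(NA_real_, n), tau_onset = rep(NA_real_, n),
    tau_sup = rep(NA_real_, n), tau_prolif = rep(NA_real_, n),
    secreting = rep(FALSE, n),
    stringsAsFactors = FALSE)
  for (rc in RECEPTOR_COLS) df[[rc]] <- rep(NA_real_, n)
  eff_ctla4 <- ko_efficiency(cfg, "CTLA-4")
  for (r in receptor_set(type)) {
    mean_level <- if (r == "CTLA-4")
      cfg$ctla4_level * (1 - eff_ctla4) else cfg$receptor_baseline
    df[[RECEPTOR_COLS[[r]]]] <- draw_level(n, mean_level, cfg$level_jitter)
  }
  df
}

## fresh expression levels for (possibly new) receptor complement after a
## differentiation event
redraw_receptors <- function(cells, rows, cfg) {
  if (!length(rows)) return(cells)
  eff_ctla4 <- ko_efficiency(cfg, "CTLA-4")
  for (rc in RECEPTOR_COLS) cells[rows, rc] <- NA_real_
  for (type in unique(cells$type[rows])) {
    tr <- rows[cells$type[rows] == type]
    for (r in receptor_set(type)) {
      mean_level <- if (r == "CTLA-4")
        cfg$ctla4_level * (1 - eff_ctla4) else cfg$receptor_baseline
      cells[tr, RECEPTOR_COLS[[r]]] <- draw_level(length(tr), mean_level,
                                                  cfg$level_jitter)
    }
  }
  cells
}

## ---- world construction -------------------------------------------------

init_world <- function(cfg) {
  validate_sim_config(cfg)
  n_loc <- cfg$n_rows * cfg$n_cols
  fields <- stats::setNames(
    lapply(molecule_names(), function(m) matrix(0, cfg$n_rows, cfg$n_cols)),
    molecule_names())
  mp <- cfg$molecule_params
  for (m in names(cfg$initial_molecules)) {
    tot <- cfg$initial_molecules[[m]]
    amt <- if (cfg$molecule_spread == "uniform") rep(tot / n_loc, n_loc)
           else stats::runif(n_loc, 0.5, 1.5) * tot / n_loc
    q <- mp$quantum[mp$name == m]
    fields[[m]] <- quantize_field(matrix(amt, cfg$n_rows, cfg$n_cols), q,
                                  cfg$conc_floor)
  }
  counts <- cfg$initial_counts[cfg$initial_counts > 0]
  cells_list <- list()
  nxt <- 1L
  for (ty in names(counts)) {
    n <- as.integer(counts[[ty]])
    cells_list[[ty]] <- new_cells(
      n, ty, cfg, nxt,
      row = sample.int(cfg$n_rows, n, replace = TRUE) - 1L,
      col = sample.int(cfg$n_cols, n, replace = TRUE) - 1L)
    nxt <- nxt + n
  }
  cells <- if (length(cells_list)) do.call(rbind, cells_list)
           else new_cells(0L, "Treg", cfg, 1L, integer(0), integer(0))
  rownames(cells) <- NULL
  list(t = 0L, cells = cells, fields = fields, next_index = nxt)
}

#' Initialize a simulation world or t = 0 state
#'
#' `sim_world()` builds the internal simulation world at t = 0: the
#' configured cell populations placed uniformly at random on the grid with
#' baseline receptor expression, and the activator molecules (HSP60, aCD3)
#' loaded with a random uniform spatial spread. `initialize_state()` is the
#' observable version, returning the t = 0 [system_state()].
#'
#' @param cfg A [sim_config()].
#' @param seed Seed for the placement draws (default `cfg$seed`).
#' @return `sim_world()`: an opaque world object accepted by [sim_step()];
#'   `initialize_state()`: a [system_state()].
#' @export
sim_world <- function(cfg, seed = cfg$seed) {
  with_seed(seed, init_world(cfg))
}

#' @rdname sim_world
#' @export
initialize_state <- function(cfg, seed = cfg$seed) {
  as_system_state(sim_world(cfg, seed))
}

#' Snapshot a simulation world as a system state
#'
#' Extracts the observable part of a world — cells with their receptors, and
#' non-zero molecule concentrations — as a [system_state()]. Hidden
#' bookkeeping (accumulated doses, scheduled transition times) is not part
#' of the observable state.
#'
#' @param world A world from [sim_world()] / [sim_step()].
#' @return A [system_state()].
#' @export
as_system_state <- function(world) {
  cl <- world$cells
  cells <- data.frame(index = cl$index, name = cl$type, lifespan = cl$lifespan,
                      behavior = cl$behavior, row = cl$row, col = cl$col,
                      stringsAsFactors = FALSE)
  rec_list <- lapply(names(RECEPTOR_COLS), function(r) {
    lv <- cl[[RECEPTOR_COLS[[r]]]]
    keep <- !is.na(lv)
    if (!any(keep)) return(NULL)
    data.frame(cell_index = cl$index[keep], name = r, level = lv[keep],
               stringsAsFactors = FALSE)
  })
  receptors <- do.call(rbind, rec_list[!vapply(rec_list, is.null, logical(1))])
  mol_list <- lapply(molecule_names(), function(m) {
    M <- world$fields[[m]]
    idx <- which(M > 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L, name = m,
               conc = M[idx], stringsAsFactors = FALSE)
  })
  molecules <- do.call(rbind, mol_list[!vapply(mol_list, is.null, logical(1))])
  system_state(t = world$t, n_rows = nrow(world$fields[[1]]),
               n_cols = ncol(world$fields[[1]]),
               cells = cells,
               receptors = if (is.null(receptors)) empty_receptors_df() else receptors,
               molecules = if (is.null(molecules)) empty_molecules_df() else molecules)
}

## ---- one synchronous step ----------------------------------------------

step_world <- function(world, cfg) {
  if (world$t >= cfg$T) stop("cannot step past the time horizon T")
  t0 <- world$t
  cl <- world$cells
  mp <- cfg$molecule_params
  tp <- cfg$transition_params
  nr <- cfg$n_rows; nc <- cfg$n_cols

  loc_slot <- function(row, col) row * nc + col + 1L  # row-major 1-based

  ## ligand exposure during the elapsed hour is evaluated against the
  ## start-of-hour fields (the environment the cells actually lived in)
  fields_t0 <- world$fields

  ## (1) molecule diffusion, decay, receptor-mediated consumption
  for (m in molecule_names()) {
    p <- mp[mp$name == m, ]
    M <- diffuse_field(world$fields[[m]], p$diffusion) * p$retention
    rcpt <- LIGAND_RECEPTOR[[m]]
    if (!is.na(rcpt) && p$consumption > 0 && nrow(cl) > 0) {
      bearer <- !is.na(cl[[RECEPTOR_COLS[[rcpt]]]])
      if (any(bearer)) {
        cnt <- tabulate(loc_slot(cl$row[bearer], cl$col[bearer]), nr * nc)
        M <- M * (1 - pmin(1, p$consumption * matrix(cnt, nr, nc, byrow = TRUE)))
      }
    }
    world$fields[[m]] <- quantize_field(M, p$quantum, cfg$conc_floor)
  }

  n <- nrow(cl)
  if (n) {
    ## (2) lazy random walk: stay or move to a uniformly chosen 4-neighbour
    ## (uniform over the 5 options); moves off the grid are reflected (the
    ## cell stays)
    dr <- c(0L, -1L, 1L, 0L, 0L); dc <- c(0L, 0L, 0L, -1L, 1L)
    mv <- sample.int(5L, n, replace = TRUE)
    nr_pos <- cl$row + dr[mv]; nc_pos <- cl$col + dc[mv]
    ok <- nr_pos >= 0L & nr_pos < nr & nc_pos >= 0L & nc_pos < nc
    cl$row[ok] <- nr_pos[ok]; cl$col[ok] <- nc_pos[ok]

    ## (3) signal accumulation and transition scheduling
    at <- function(m) fields_t0[[m]][cbind(cl$row + 1L, cl$col + 1L)]
    hsp <- at("HSP60"); acd3 <- at("aCD3"); il10 <- at("IL-10"); ifng <- at("IFN-g")

    is_treg <- cl$type == "Treg"; is_nth <- cl$type == "nTh"
    cl$act_dose[is_treg] <- cl$act_dose[is_treg] +
      (hsp[is_treg] + acd3[is_treg]) / 2
    cl$act_dose[is_nth] <- cl$act_dose[is_nth] + acd3[is_nth]
    trig <- (is_treg | is_nth) & is.na(cl$tau_act) &
      cl$act_dose >= tp$activation$threshold
    if (any(trig)) {
      cl$tau_act[trig] <- draw_time(sum(trig), tp$activation$center,
                                    tp$activation$sd)
      cl$behavior[trig] <- "Activating"
    }

    ## suppression exposure: diffusible IL-10 plus CTLA-4-dependent contact
    ## with an activated Treg on the same location
    eff <- cl$type %in% c("Th1", "ActivatedTh1")
    if (any(eff)) {
      ctreg <- cl$type == "ActivatedTreg" &
        !is.na(cl$r_CTLA4) & cl$r_CTLA4 >= tp$suppression$ctla4_threshold
      contact_slots <- unique(loc_slot(cl$row[ctreg], cl$col[ctreg]))
      in_contact <- loc_slot(cl$row, cl$col) %in% contact_slots
      cl$sup_dose[eff] <- cl$sup_dose[eff] +
        il10[eff] / tp$suppression$il10_threshold +
        tp$suppression$contact_weight * in_contact[eff]
      strig <- eff & is.na(cl$tau_sup) & cl$sup_dose >= 1
      if (any(strig)) {
        ctr <- ifelse(cl$type[strig] == "Th1",
                      tp$suppression$center, tp$late_suppression$center)
        sdv <- ifelse(cl$type[strig] == "Th1",
                      tp$suppression$sd, tp$late_suppression$sd)
        cl$tau_sup[strig] <- ctr + pmin(pmax(stats::rnorm(sum(strig), 0, sdv),
                                             -2 * sdv), 2 * sdv)
      }
      is_th1 <- cl$type == "Th1"
      cl$ifng_dose[is_th1] <- cl$ifng_dose[is_th1] + ifng[is_th1]
      ptrig <- is_th1 & is.na(cl$tau_prolif) &
        cl$ifng_dose >= tp$proliferation$threshold
      if (any(ptrig))
        cl$tau_prolif[ptrig] <- draw_time(sum(ptrig), tp$proliferation$center,
                                          tp$proliferation$sd)
    }

    ## (4) scheduled transitions fire (a transition fires in the first step
    ## whose start time reaches its drawn time)
    cl$behavior[cl$type == "ActivatedTh1" & cl$behavior == "Proliferating"] <-
      "Secreting"

    sup_fire <- which(cl$type %in% c("Th1", "ActivatedTh1") &
                        !is.na(cl$tau_sup) & t0 >= cl$tau_sup)
    if (length(sup_fire)) {
      cl$type[sup_fire] <- "SuppressedTh1"
      cl$behavior[sup_fire] <- "Suppressed"
      cl$secreting[sup_fire] <- TRUE
      cl$tau_prolif[sup_fire] <- NA_real_
      ## suppressed cells shed the IFN-g receptor but keep their other
      ## expression levels (suppression is not a re-differentiation)
      cl$r_IFNgR[sup_fire] <- NA_real_
    }

    pro_fire <- which(cl$type == "Th1" & !is.na(cl$tau_prolif) &
                        t0 >= cl$tau_prolif)
    if (length(pro_fire)) {
      cl$type[pro_fire] <- "ActivatedTh1"
      cl$behavior[pro_fire] <- "Proliferating"
      resched <- pro_fire[!is.na(cl$tau_sup[pro_fire])]
      if (length(resched))
        cl$tau_sup[resched] <- draw_time(length(resched),
                                         tp$late_suppression$center,
                                         tp$late_suppression$sd)
      cl <- redraw_receptors(cl, pro_fire, cfg)
      ## the proliferation burst: each firing cell divides twice within the
      ## hour, leaving the mother plus two daughters
      mothers <- rep(pro_fire, cfg$proliferation_daughters)
      daughters <- new_cells(length(mothers), "ActivatedTh1", cfg,
                             world$next_index,
                             row = cl$row[mothers], col = cl$col[mothers])
      daughters$behavior <- "Secreting"
      daughters$secreting <- TRUE
      world$next_index <- world$next_index + length(mothers)
      cl <- rbind(cl, daughters)
    }

    act_fire <- which(cl$type %in% c("Treg", "nTh") & !is.na(cl$tau_act) &
                        t0 >= cl$tau_act)
    if (length(act_fire)) {
      cl$type[act_fire] <- ifelse(cl$type[act_fire] == "Treg",
                                  "ActivatedTreg", "Th1")
      cl$behavior[act_fire] <- "Activating"
      cl$tau_onset[act_fire] <- draw_time(length(act_fire),
                                          tp$secretion_onset$center,
                                          tp$secretion_onset$sd)
      cl <- redraw_receptors(cl, act_fire, cfg)
    }

    onset_fire <- which(!cl$secreting & !is.na(cl$tau_onset) &
                          t0 >= cl$tau_onset)
    if (length(onset_fire)) {
      cl$secreting[onset_fire] <- TRUE
      cl$behavior[onset_fire] <- "Secreting"
    }

    ## (5) secretion into the cell's own location, scaled by knock-out
    ## efficiency for targeted secreted molecules
    sec <- which(cl$secreting & cl$type %in% names(cfg$secretion_rates))
    if (length(sec)) {
      for (ty in unique(cl$type[sec])) {
        rows <- sec[cl$type[sec] == ty]
        rates <- cfg$secretion_rates[[ty]]
        for (m in names(rates)) {
          rate <- rates[[m]] * (1 - ko_efficiency(cfg, m))
          if (rate <= 0) next
          add <- tabulate(loc_slot(cl$row[rows], cl$col[rows]), nr * nc) * rate
          world$fields[[m]] <- world$fields[[m]] +
            matrix(add, nr, nc, byrow = TRUE)
        }
      }
      for (m in molecule_names()) {
        p <- mp[mp$name == m, ]
        world$fields[[m]] <- quantize_field(world$fields[[m]], p$quantum,
                                            cfg$conc_floor)
      }
    }

    ## (6) lifespans decrement; dead cells are removed
    cl$lifespan <- cl$lifespan - 1L
    cl <- cl[cl$lifespan >= 0L, , drop = FALSE]
    rownames(cl) <- NULL
  }

  world$cells <- cl
  world$t <- t0 + 1L
  world
}

#' Advance a simulation world by one synchronous hour
#'
#' Applies, in order: molecule diffusion (uniform 4-neighbour redistribution
#' with reflecting boundaries), decay and receptor-mediated consumption;
#' cell random-walk movement; ligand dose accumulation and transition
#' scheduling; firing of scheduled transitions (suppression, proliferation,
#' differentiation, secretion onset); secretion; lifespan decrement with
#' removal of dead cells.
#'
#' @param world A world from [sim_world()].
#' @param cfg The same [sim_config()] used to build the world.
#' @param seed Optional seed making this single step reproducible in
#'   isolation; by default the current RNG stream is used (as inside
#'   [run_sim()]).
#' @return The world advanced to t + 1.
#' @export
sim_step <- function(world, cfg, seed = NULL) {
  if (is.null(seed)) step_world(world, cfg) else with_seed(seed, step_world(world, cfg))
}

#' Run a simulation
#'
#' Executes the model for `cfg$T` hours, recording the system state at every
#' hour (T + 1 states including t = 0). A run is a pure function of the
#' configuration and its seed. For a `random_model` configuration, all
#' numeric parameters are first resampled via [randomize_parameters()] under
#' the same seed.
#'
#' @param cfg A [sim_config()].
#' @param run_id Integer id stamped on the result.
#' @return A [run_result()].
#' @export
run_sim <- function(cfg, run_id = 0L) {
  validate_sim_config(cfg)
  if (cfg$random_model && !isTRUE(attr(cfg, "randomized"))) {
    cfg <- randomize_parameters(cfg, seed = cfg$seed)
  }
  with_seed(cfg$seed, {
    world <- init_world(cfg)
    states <- vector("list", cfg$T + 1L)
    states[[1]] <- as_system_state(world)
    for (t in seq_len(cfg$T)) {
      world <- step_world(world, cfg)
      states[[t + 1L]] <- as_system_state(world)
    }
    run_result(run_id, cfg$condition, states)
  })
}

#' Run an ensemble of independent simulations
#'
#' Runs `n_runs` simulations with seeds `base_seed, base_seed + 1, ...`
#' (run ids 0..n-1). For a `random_model` configuration each run resamples
#' its own parameter set from the run's seed, so the ensemble spans the
#' randomized-parameter null model.
#'
#' @param cfg A [sim_config()].
#' @param n_runs Number of runs (the reference design uses 50).
#' @param base_seed First seed (default `cfg$seed`).
#' @return A list of [run_result()] objects.
#' @export
run_ensemble <- function(cfg, n_runs, base_seed = cfg$seed) {
  lapply(seq_len(n_runs) - 1L, function(r) {
    cfg_r <- cfg
    cfg_r$seed <- as.integer(base_seed + r)
    run_sim(cfg_r, run_id = r)
  })
}

#' @export
#' @rdname randomize_parameters
#' @param ... unused
is_randomized <- function(cfg, ...) isTRUE(attr(cfg, "randomized"))
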
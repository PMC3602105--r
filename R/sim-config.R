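# Simulation configuration: all numerical parameters of the immune emulation,
# the perturbation hooks, and the randomized-parameter null model.

#' Knock-out perturbation
#'
#' A perturbation targets one of the three regulatory molecules at a given
#' efficiency. Knock-outs of the secreted molecules (IL-10, IFN-g) scale the
#' corresponding secretion rates by `1 - efficiency`; the CTLA-4 knock-out
#' scales the expression level of the membrane-bound CTLA-4 receptor on
#' activated Tregs (suppression by contact then fails the expression
#' threshold).
#'
#' @param target One of `"IL-10"`, `"IFN-g"`, `"CTLA-4"`.
#' @param efficiency Fraction in \[0, 1\]; shipped presets use
#'   0, 0.25, 0.5, 0.75, 1.
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(target, efficiency = 1) {
  if (!target %in% c("IL-10", "IFN-g", "CTLA-4"))
    stop("perturbation target must be one of 'IL-10', 'IFN-g', 'CTLA-4'")
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      efficiency < 0 || efficiency > 1)
    stop("efficiency must be a single number in [0, 1]")
  structure(list(target = target, efficiency = as.numeric(efficiency)),
            class = "perturbation")
}

default_molecule_params <- function() {
  data.frame(
    name        = molecule_names(),            # HSP60 aCD3 IL-10 IFN-g TNF-a
    diffusion   = c(0.30, 0.30, 0.15, 0.15, 0.15),
    retention   = c(0.05, 0.05, 0.80, 0.80, 0.80),
    consumption = c(0.02, 0.02, 0.02, 0.00, 0.00),
    quantum     = c(1e-4, 1e-4, 0.10, 0.10, 0.10),
    stringsAsFactors = FALSE)
}

default_secretion_rates <- function() {
  list(ActivatedTreg = c("IL-10" = 0.3),
       Th1           = c("IFN-g" = 0.3, "TNF-a" = 0.3),
       ActivatedTh1  = c("IFN-g" = 0.4, "TNF-a" = 0.4),
       SuppressedTh1 = c("IL-10" = 0.1))
}

default_transition_params <- function() {
  list(
    activation       = list(center = 10.5, sd = 0.3, threshold = 1.02),
    secretion_onset  = list(center = 11.5, sd = 0.5),
    suppression      = list(center = 15.0, sd = 0.5, il10_threshold = 1.0,
                            contact_weight = 0.34, ctla4_threshold = 2.5),
    proliferation    = list(center = 16.5, sd = 0.3, threshold = 1.0),
    late_suppression = list(center = 22.0, sd = 0.5))
}

#' Simulation configuration
#'
#' Collects every numerical parameter of the grid-based immune emulation.
#' The defaults are calibrated so that ensemble dynamics reproduce the
#' reference timeline of the wild-type system: HSP60/aCD3 depletion by t ~ 2,
#' Treg and nTh differentiation around t = 10-11, cytokine secretion onset
#' around t = 12-13, contact/IL-10 suppression of Th1 cells around t = 15,
#' IFN-g-driven Th1 proliferation into activated Th1 shortly before t = 17-18
#' and late suppression of activated Th1 around t = 22.
#'
#' @param n_rows,n_cols Grid dimensions (20 x 20).
#' @param T Number of simulated hours (a run yields T + 1 hourly states).
#' @param initial_counts Named integer vector of initial cells; the shipped
#'   ratio presets keep the total at 100.
#' @param initial_molecules Named totals of the activator molecules present
#'   at t = 0.
#' @param molecule_spread `"uniform"` (default): the initial totals are
#'   spread evenly over all grid locations — the dispersed medium holds no
#'   spatial information until cells start consuming it; `"random"`: each
#'   location gets an independent uniform share.
#' @param molecule_params Per-molecule `data.frame` with columns `name`,
#'   `diffusion` (fraction redistributed to the 4-neighbourhood each hour,
#'   reflecting boundaries), `retention` (fraction surviving decay, in
#'   \[0,1\]), `consumption` (receptor-mediated removal rate per co-located
#'   cell), `quantum` (concentration resolution; states are quantized to it).
#' @param conc_floor Concentrations below this are flushed to zero (trace
#'   amounts fall below one molecule-equivalent).
#' @param secretion_rates Named list: per secreting cell type, named vector
#'   of per-hour secretion rates into the cell's location.
#' @param transition_params Transition timing/threshold list; see
#'   `default_transition_params()`. Each timed transition fires in the first
#'   hour whose start time reaches a cell-specific time drawn from a normal
#'   (truncated at 2 sd) centred on `center`.
#' @param proliferation_daughters Daughter cells produced per proliferating
#'   Th1 cell (the burst leaves the mother plus this many daughters).
#' @param receptor_baseline Mean baseline receptor expression level.
#' @param ctla4_level Mean CTLA-4 expression gained by activated Tregs
#'   (scaled by `1 - efficiency` under a CTLA-4 knock-out).
#' @param level_jitter Relative spread of per-cell expression levels (levels
#'   are drawn uniformly in `mean * (1 +/- level_jitter)`).
#' @param initial_lifespan Remaining lifespan assigned at t = 0 and to
#'   daughters; the default outlives the run, so no cell dies in wild type.
#' @param perturbations List of [perturbation()] objects.
#' @param random_model Logical; if `TRUE`, [run_ensemble()] resamples all
#'   numeric parameters per run via [randomize_parameters()].
#' @param condition Condition label stamped on results.
#' @param seed Integer seed; a run is a pure function of (config, seed).
#' @return An object of class `sim_config`.
#' @seealso [condition_config()] for building configs from condition labels.
#' @export
sim_config <- function(n_rows = 20L, n_cols = 20L, T = 30L,
                       initial_counts = c(Treg = 10L, nTh = 90L),
                       initial_molecules = c(HSP60 = 400, aCD3 = 400),
                       molecule_spread = c("uniform", "random"),
                       molecule_params = default_molecule_params(),
                       conc_floor = 0.005,
                       secretion_rates = default_secretion_rates(),
                       transition_params = default_transition_params(),
                       proliferation_daughters = 2L,
                       receptor_baseline = 5,
                       ctla4_level = 10,
                       level_jitter = 0.2,
                       initial_lifespan = 40L,
                       perturbations = list(),
                       random_model = FALSE,
                       condition = "wt",
                       seed = 1L) {
  cfg <- structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         T = as.integer(T),
         initial_counts = initial_counts,
         initial_molecules = initial_molecules,
         molecule_spread = match.arg(molecule_spread),
         molecule_params = molecule_params,
         conc_floor = conc_floor,
         secretion_rates = secretion_rates,
         transition_params = transition_params,
         proliferation_daughters = as.integer(proliferation_daughters),
         receptor_baseline = receptor_baseline,
         ctla4_level = ctla4_level,
         level_jitter = level_jitter,
         initial_lifespan = as.integer(initial_lifespan),
         perturbations = perturbations,
         random_model = isTRUE(random_model),
         condition = as.character(condition),
         seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg A [sim_config()].
#' @return `cfg` invisibly, or an error.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$T < 1L) stop("T must be at least 1")
  if (any(cfg$initial_counts < 0)) stop("initial cell counts must be non-negative")
  if (!all(names(cfg$initial_counts) %in% cell_types()))
    stop("initial_counts names must be cell types")
  if (!all(names(cfg$initial_molecules) %in% molecule_names()))
    stop("initial_molecules names must be molecule names")
  mp <- cfg$molecule_params
  if (!setequal(mp$name, molecule_names()))
    stop("molecule_params must cover every molecule")
  if (any(mp$retention < 0 | mp$retention > 1))
    stop("retention factors must lie in [0, 1]")
  if (any(mp$diffusion < 0 | mp$diffusion > 1))
    stop("diffusion fractions must lie in [0, 1]")
  if (any(mp$consumption < 0) || any(mp$quantum <= 0))
    stop("consumption rates must be >= 0 and quanta > 0")
  if (any(unlist(cfg$secretion_rates) < 0)) stop("secretion rates must be >= 0")
  if (cfg$initial_lifespan < 1L) stop("initial_lifespan must be >= 1")
  for (p in cfg$perturbations)
    if (!inherits(p, "perturbation")) stop("perturbations must be perturbation objects")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  pert <- if (length(x$perturbations))
    paste(vapply(x$perturbations,
                 function(p) sprintf("%s@%.0f%%", p$target, 100 * p$efficiency),
                 character(1)), collapse = ", ") else "none"
  cat(sprintf("<sim_config> %s  grid %dx%d  T=%d  cells %s  KO: %s%s  seed=%d\n",
              x$condition, x$n_rows, x$n_cols, x$T,
              paste(sprintf("%s=%d", names(x$initial_counts), x$initial_counts),
                    collapse = " "),
              pert, if (x$random_model) "  [random model]" else "", x$seed))
  invisible(x)
}

ko_efficiency <- function(cfg, target) {
  for (p in cfg$perturbations) if (p$target == target) return(p$efficiency)
  0
}

#' Build a configuration from a condition label
#'
#' Labels follow the pipeline syntax: `"wt"` (wild type), `"ko:IL-10:0.75"`
#' (knock-out target and efficiency; efficiency defaults to 1),
#' `"ratio:50:50"` (initial Treg:nTh counts, must sum to 100), and
#' `"random"` (randomized-parameter null model; each run of an ensemble
#' resamples every numeric parameter, keeping the interaction rules).
#'
#' @param label Condition label string.
#' @param ... Passed on to [sim_config()] (e.g. `T`, `seed`).
#' @return A [sim_config()] with `condition` set to a canonical form of the
#'   label.
#' @examples
#' condition_config("ko:IL-10:0.5")
#' condition_config("ratio:70:30")
#' @export
condition_config <- function(label, ...) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  if (kind == "wt") {
    if (length(parts) != 1L) stop("wild-type label takes no arguments")
    return(sim_config(condition = "wt", ...))
  }
  if (kind == "ko") {
    if (length(parts) < 2L) stop("knock-out label needs a target: 'ko:<target>[:eff]'")
    eff <- if (length(parts) >= 3L) as.numeric(parts[3]) else 1
    if (is.na(eff)) stop("knock-out efficiency must be numeric")
    p <- perturbation(parts[2], eff)
    return(sim_config(perturbations = list(p),
                      condition = sprintf("ko_%s_%g", p$target, p$efficiency), ...))
  }
  if (kind == "ratio") {
    if (length(parts) != 3L) stop("ratio label is 'ratio:<Treg>:<nTh>'")
    a <- as.integer(parts[2]); b <- as.integer(parts[3])
    if (is.na(a) || is.na(b) || a + b != 100L)
      stop("ratio counts must be integers summing to 100")
    return(sim_config(initial_counts = c(Treg = a, nTh = b),
                      condition = sprintf("ratio_%d_%d", a, b), ...))
  }
  if (kind == "random") {
    return(sim_config(random_model = TRUE, condition = "random", ...))
  }
  stop("unknown condition label: ", label)
}

#' Resample all numeric parameters of a configuration
#'
#' Produces the randomized-parameter null model: every numeric parameter
#' (initial molecule amounts, diffusion/retention/consumption rates,
#' secretion rates, transition times and thresholds, expression levels) is
#' rescaled by an independent log-uniform factor in \[0.1, 10\], while the
#' interaction rules — which transitions exist, which receptor binds which
#' ligand, the grid, the time horizon, the 100 initial cells and the
#' no-death lifespan bound — stay exactly as in the wild type. Fractions
#' are clamped to \[0, 1\].
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed controlling the resampling.
#' @return A new [sim_config()] with `random_model = TRUE`.
#' @export
randomize_parameters <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  with_seed(as.integer(seed), {
    fac <- function(n = 1L) 10^stats::runif(n, -1, 1)
    clamp01 <- function(x) pmin(pmax(x, 0), 1)
    cfg$initial_molecules <- cfg$initial_molecules * fac(length(cfg$initial_molecules))
    mp <- cfg$molecule_params
    mp$diffusion <- clamp01(mp$diffusion * fac(nrow(mp)))
    mp$retention <- clamp01(mp$retention * fac(nrow(mp)))
    mp$consumption <- mp$consumption * fac(nrow(mp))
    cfg$molecule_params <- mp
    cfg$secretion_rates <- lapply(cfg$secretion_rates,
                                  function(v) v * fac(length(v)))
    tp <- cfg$transition_params
    for (nm in names(tp)) {
      tp[[nm]]$center <- tp[[nm]]$center * fac()
      tp[[nm]]$sd <- tp[[nm]]$sd * fac()
      for (th in intersect(names(tp[[nm]]),
                           c("threshold", "il10_threshold", "contact_weight",
                             "ctla4_threshold")))
        tp[[nm]][[th]] <- tp[[nm]][[th]] * fac()
    }
    cfg$transition_params <- tp
    cfg$receptor_baseline <- cfg$receptor_baseline * fac()
    cfg$ctla4_level <- cfg$ctla4_level * fac()
    ## lifespans stay fixed: whether cells can die inside the horizon is part
    ## of the rule structure (the reference model has no death events), not a
    ## numeric rate
    cfg$random_model <- TRUE
    validate_sim_config(cfg)
    attr(cfg, "randomized") <- TRUE
    cfg
  })
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## random number stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
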
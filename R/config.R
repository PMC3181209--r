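# Scenario configuration, presets reproducing the reference experiments,
# and a dispatcher that writes plain delimited output tables plus a
# manifest. The CLI script (exec/lacpop) is a thin wrapper over run_scenario.

.config_fields <- c("mode", "I_ex_uM", "N_cellsmax", "n_batches", "t_end",
                    "sample_dt", "sample_times", "seed", "n_init",
                    "init_state", "t_final", "burn_in", "I_ex_grid_uM",
                    "params", "interventions", "label")

#' Build and validate a run configuration
#'
#' A `run_config` fully specifies one simulation scenario: the engine
#' (`mode`), the extracellular inducer level, census caps, batch counts,
#' time horizons, sampling schedule, seed and parameter overrides. Unknown
#' fields are rejected; every field is type-checked. The resolved
#' configuration is echoed to the output directory by [run_scenario()].
#'
#' @param mode one of `"stochastic"`, `"deterministic"` (population runs),
#'   `"chain-stochastic"`, `"chain-deterministic"`, `"continuum"`,
#'   `"bifurcation"`, `"estimate"`, `"geometry-only"`.
#' @param ... scenario fields: `I_ex_uM`, `N_cellsmax`, `n_batches`,
#'   `t_end`, `sample_dt` or `sample_times`, `seed`, `n_init`,
#'   `init_state` (`"off"`/`"on"`), `t_final`, `burn_in`,
#'   `I_ex_grid_uM`, `params` (named list of parameter overrides),
#'   `interventions`, `label`.
#' @return object of class `run_config` (a validated named list).
#' @export
run_config <- function(mode, ...) {
  mode <- match.arg(mode, c("stochastic", "deterministic",
                            "chain-stochastic", "chain-deterministic",
                            "continuum", "bifurcation", "estimate",
                            "geometry-only"))
  cfg <- list(...)
  unknown <- setdiff(names(cfg), .config_fields)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  cfg$mode <- mode
  num1 <- function(nm) {
    if (!is.null(cfg[[nm]]) &&
        (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1)) {
      stop("field '", nm, "' must be a single number")
    }
  }
  for (nm in c("I_ex_uM", "N_cellsmax", "n_batches", "t_end", "sample_dt",
               "seed", "n_init", "t_final", "burn_in")) num1(nm)
  if (!is.null(cfg$init_state)) {
    cfg$init_state <- match.arg(cfg$init_state, c("off", "on"))
  }
  if (!is.null(cfg$params) && !is.list(cfg$params)) {
    stop("field 'params' must be a named list of parameter overrides")
  }
  # defaults
  cfg$I_ex_uM    <- cfg$I_ex_uM %||% 24
  cfg$seed       <- cfg$seed %||% 1
  cfg$n_batches  <- cfg$n_batches %||% 1
  cfg$n_init     <- cfg$n_init %||% 1
  cfg$init_state <- cfg$init_state %||% "off"
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preset scenario catalog
#'
#' Named presets covering the package's reference experiments: population
#' transients with deterministic (fig2*) and stochastic (fig4) reactions,
#' single-lineage attractor persistence and the forced-transition
#' interventions (fig3*), NDF comparisons at 10/24/50 uM inducer (fig5*),
#' the continuum-vs-population steady states (fig6*), switching transients
#' and the slow-mRNA variant (fig7*), and chain-vs-population distribution
#' comparisons including the fast-transcription variant (fig8*).
#'
#' @param name optional preset name; omit for the full catalog.
#' @return a `run_config` (if `name` given) or named list of them.
#' @export
list_presets <- function(name = NULL) {
  P <- list(
    fig2a = run_config("deterministic", I_ex_uM = 24, n_init = 1,
                       init_state = "off", N_cellsmax = 1e4, t_end = 600,
                       sample_dt = 5, label = "population transient, off start"),
    fig2c = run_config("deterministic", I_ex_uM = 24, n_init = 1,
                       init_state = "on", N_cellsmax = 1e4, t_end = 600,
                       sample_dt = 5, label = "population transient, on start"),
    fig3a = run_config("chain-deterministic", I_ex_uM = 24,
                       init_state = "off", t_final = 6000, sample_dt = 2,
                       burn_in = 0, label = "chain persistence, off state"),
    fig3b = run_config("chain-deterministic", I_ex_uM = 24,
                       init_state = "on", t_final = 6000, sample_dt = 2,
                       burn_in = 0, label = "chain persistence, on state"),
    fig3c = run_config("chain-deterministic", I_ex_uM = 24,
                       init_state = "off", t_final = 2000, sample_dt = 2,
                       burn_in = 0,
                       interventions = list(
                         intervention_asymmetric_division(at = 4, ratio = 0.15,
                                                          follow = "smaller")),
                       label = "forced asymmetric division 0.15, off -> on"),
    fig3d = run_config("chain-deterministic", I_ex_uM = 24,
                       init_state = "on", t_final = 2000, sample_dt = 2,
                       burn_in = 0,
                       interventions = list(
                         intervention_delayed_division(at = 4, delay = 50)),
                       label = "forced 50-min division delay, on -> off"),
    fig4  = run_config("stochastic", I_ex_uM = 24, n_init = 1,
                       init_state = "off", N_cellsmax = 500, n_batches = 20,
                       t_end = 500, sample_dt = 10,
                       label = "stochastic population transient"),
    fig5a = run_config("stochastic", I_ex_uM = 10, n_init = 1,
                       init_state = "off", N_cellsmax = 500, n_batches = 20,
                       sample_times = 300, t_end = 300,
                       label = "NDF at 10 uM (with deterministic twin)"),
    fig5b = run_config("stochastic", I_ex_uM = 24, n_init = 1,
                       init_state = "off", N_cellsmax = 500, n_batches = 20,
                       sample_times = 300, t_end = 300,
                       label = "NDF at 24 uM (with deterministic twin)"),
    fig5c = run_config("stochastic", I_ex_uM = 50, n_init = 1,
                       init_state = "off", N_cellsmax = 500, n_batches = 20,
                       sample_times = 300, t_end = 300,
                       label = "NDF at 50 uM (with deterministic twin)"),
    fig6a = run_config("bifurcation", I_ex_grid_uM = seq(5, 60, by = 1),
                       label = "continuum bifurcation diagram"),
    fig6b = run_config("deterministic", I_ex_uM = 24, n_init = 20,
                       init_state = "off", N_cellsmax = 1e4,
                       sample_times = 300, t_end = 300,
                       label = "bimodal NDF with mode splitting"),
    fig7a = run_config("deterministic", I_ex_uM = 60, n_init = 20,
                       init_state = "off", N_cellsmax = 1e4, t_end = 400,
                       sample_dt = 5, label = "switch 0 -> 60 uM"),
    fig7b = run_config("deterministic", I_ex_uM = 0, n_init = 20,
                       init_state = "on", N_cellsmax = 1e4, t_end = 400,
                       sample_dt = 5, label = "switch 60 -> 0 uM"),
    fig7c = run_config("deterministic", I_ex_uM = 60, n_init = 20,
                       init_state = "off", N_cellsmax = 1e4, t_end = 800,
                       sample_dt = 5,
                       params = list(k_s0MY = 0.025, k_s1MY = 5e-4,
                                     lambda_MY = 0.001155),
                       label = "switch 0 -> 60 uM, slow lacY mRNA variant"),
    fig8a = run_config("chain-stochastic", I_ex_uM = 24, t_final = 1e5,
                       sample_dt = 10, burn_in = 500, N_cellsmax = 500,
                       n_batches = 20, t_end = 500,
                       label = "chain PDF vs population NDF"),
    fig8b = run_config("chain-stochastic", I_ex_uM = 24, t_final = 1e5,
                       sample_dt = 10, burn_in = 500, N_cellsmax = 500,
                       n_batches = 20, t_end = 250,
                       params = list(k_s1MY = 50, k_s0MY = 1, k_sY = 0.3),
                       label = "chain vs population, fast transcription variant")
  )
  if (is.null(name)) return(P)
  if (!name %in% names(P)) stop("unknown preset: ", name)
  P[[name]]
}

.cfg_params <- function(cfg) {
  ov <- cfg$params %||% list()
  ov$I_ex <- (cfg$I_ex_uM %||% 24) * 1000
  do.call(lac_params, ov)
}

.cfg_init <- function(cfg, params, mode) {
  attractor_state(cfg$init_state, params$I_ex, params, mode = mode)
}

#' Run a configured scenario and write its output tables
#'
#' Dispatches a [run_config()] to the matching engine and writes plain
#' tab-delimited tables (snapshots, mean timecourses, chain samples,
#' bifurcation branches or estimator values) plus a JSON manifest (resolved
#' configuration, seed, package version, wall-clock) to `out_dir`.
#'
#' @param cfg a `run_config` or preset name.
#' @param out_dir output directory (created if missing); `NULL` for none.
#' @return the computed result object, invisibly when writing files.
#' @export
run_scenario <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- list_presets(cfg)
  stopifnot(inherits(cfg, "run_config"))
  t_start <- Sys.time()
  set.seed(cfg$seed)
  params <- .cfg_params(cfg)
  mode <- cfg$mode

  result <- switch(mode,
    "stochastic" = ,
    "deterministic" = {
      init <- .cfg_init(cfg, params, mode)
      inits <- rep(list(init), cfg$n_init)
      st <- cfg$sample_times %||%
        seq(0, cfg$t_end, by = cfg$sample_dt %||% 10)
      if (cfg$n_batches > 1) {
        run_batches(cfg$n_batches, init = inits, t_end = cfg$t_end,
                    N_cellsmax = cfg$N_cellsmax, mode = mode,
                    sample_times = st, params = params)
      } else {
        simulate_population(inits, cfg$t_end, cfg$N_cellsmax, mode, st, params)
      }
    },
    "chain-stochastic" = ,
    "chain-deterministic" = {
      emode <- sub("^chain-", "", mode)
      init <- .cfg_init(cfg, params, emode)
      plan <- chain_plan(cfg$t_final, cfg$sample_dt %||% 10,
                         cfg$burn_in %||% 500)
      simulate_chain(init, plan, emode, params,
                     interventions = cfg$interventions %||% list())
    },
    "continuum" = {
      st <- cfg$sample_times %||% seq(0, cfg$t_end %||% 1000,
                                      by = cfg$sample_dt %||% 5)
      init0 <- attractor_state(cfg$init_state, params$I_ex, params,
                               mode = "deterministic")
      continuum_trajectory(st, params, estimate_A_over_V(params),
                           estimate_O_T(params))
    },
    "bifurcation" = {
      grid <- (cfg$I_ex_grid_uM %||% seq(5, 60, by = 1)) * 1000
      bifurcation_scan(grid, params)
    },
    "estimate" = {
      list(avg_A_over_V = estimate_A_over_V(params),
           avg_O_T = estimate_O_T(params))
    },
    "geometry-only" = {
      geometry_only_population(params,
                               t_end = cfg$t_end %||% 600,
                               N_cellsmax = cfg$N_cellsmax %||% 500,
                               n_batches = cfg$n_batches %||% 20)
    })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, nm) utils::write.table(
      df, file.path(out_dir, nm), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (inherits(result, "lac_population")) {
      wt(result$snapshots, "snapshots.tsv")
      wt(result$mean_timecourse, "mean_timecourse.tsv")
      wt(result$events, "events.tsv")
    } else if (inherits(result, "lac_chain")) {
      wt(result$samples, "chain_samples.tsv")
      wt(data.frame(division_min = result$division_times), "divisions.tsv")
    } else if (is.list(result) && !is.null(result$snapshots)) {
      wt(result$snapshots, "snapshots.tsv")
    } else if (is.data.frame(result)) {
      wt(result, "result.tsv")
    } else if (is.matrix(result)) {
      wt(as.data.frame(result), "result.tsv")
    } else if (is.list(result)) {
      est <- result[vapply(result, function(v)
        is.numeric(v) && length(v) == 1, logical(1))]
      if (length(est)) {
        wt(data.frame(quantity = names(est),
                      value = as.numeric(unlist(est))), "estimates.tsv")
      }
      if (!is.null(result$cells)) wt(result$cells, "cells.tsv")
    }
    manifest <- list(
      config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("lacpop")),
      wall_clock_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
    manifest$config$interventions <-
      if (!is.null(cfg$interventions)) lapply(cfg$interventions, unclass)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(result))
  }
  result
}
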
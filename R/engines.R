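# Single-cell engines. Two reaction treatments share one orchestration:
#  - stochastic: exact SSA over the 25 reactions with growing volume
#    (C++ kernel), duplication/division hazards in the total hazard;
#  - deterministic (hybrid): stiff mass-action ODEs integrated between
#    stochastic duplication/division events whose times are drawn exactly
#    from the closed-form power-law-hazard sampler (a piecewise
#    deterministic Markov process).
# Both engines follow one daughter after each division according to a
# caller-chosen policy; the population engine instead keeps every daughter.

# low-level binding to the C++ SSA kernel
.ssa_cell <- function(x0, V0, duplicated, t0, t_end, pv, sample_times,
                      refresh_dt = 0.5) {
  .Call("c_ssa_cell", as.numeric(x0), as.numeric(V0), as.logical(duplicated),
        as.numeric(t0), as.numeric(t_end), as.numeric(pv),
        as.numeric(sample_times), as.numeric(refresh_dt),
        PACKAGE = "lacpop")
}

.ode_parms <- function(params, mode, AoV_fixed = 0, mu = params$g,
                       V0_seg = 1, t0_seg = 0) {
  c(.param_vector(params), mode, AoV_fixed, mu, V0_seg, t0_seg)
}

# integrate the per-cell hybrid ODEs over [t_from, t_to] with volume growing
# from V0_seg at t_from; returns deSolve output matrix at grid + endpoints
.integrate_hybrid <- function(conc, t_from, t_to, V0_seg, params,
                              inner_times = numeric(0)) {
  times <- sort(unique(c(t_from, inner_times[inner_times > t_from &
                                             inner_times < t_to], t_to)))
  pv <- .ode_parms(params, mode = 1, mu = params$g,
                   V0_seg = V0_seg, t0_seg = t_from)
  out <- deSolve::lsoda(y = conc, times = times, func = "lac_derivs",
                        parms = pv, dllname = "lacpop",
                        initfunc = "lac_initmod",
                        rtol = 1e-8, atol = 1e-10, maxsteps = 1e5)
  if (attr(out, "istate")[1] < 0) {
    stop("stiff integration failure at t = ", utils::tail(times, 1),
         "; state: ", paste(signif(conc, 6), collapse = ", "))
  }
  y <- out[, -1, drop = FALSE]
  neg <- y < 0
  if (any(neg)) {
    if (min(y[neg]) < -1e-6) {
      .lacpop_env$clip_warnings <- .lacpop_env$clip_warnings + 1L
    }
    y[neg] <- 0
    out[, -1] <- y
  }
  out
}

.lacpop_env <- new.env(parent = emptyenv())
.lacpop_env$clip_warnings <- 0L

#' Count of negative-concentration clips in hybrid integrations
#'
#' The hybrid engine clips tiny negative concentrations produced by the
#' stiff integrator back to zero; clips beyond the integration tolerance
#' are counted here.
#' @return integer count since package load.
#' @export
integration_clip_count <- function() .lacpop_env$clip_warnings

# --- one cell from (t0, x, V0) until division or t_end ---------------------

# stochastic mode; returns list(divided, t_stop, V_stop, x, duplicated,
# t_dup, samples [n x 12], n_samples)
.cell_stochastic <- function(x, V0, duplicated, t0, t_end, params,
                             sample_times, refresh_dt = 0.5) {
  .ssa_cell(as.numeric(x), V0, duplicated, t0, t_end, .param_vector(params),
            as.numeric(sample_times), refresh_dt)
}

# hybrid mode; same contract. forced_division_delay overrides the sampled
# division waiting time (measured from the duplication event).
.cell_hybrid <- function(x, V0, duplicated, t0, t_end, params,
                         sample_times, forced_division_delay = NULL) {
  t_dup <- NA_real_
  if (!duplicated) {
    t_dup <- t0 + sample_event_time(V0, "duplication", params)
  }
  seg1_end <- if (!duplicated) min(t_dup, t_end) else t0
  samp <- matrix(numeric(0), ncol = 12)
  conc <- as.numeric(x)
  tcur <- t0

  if (seg1_end > tcur) {
    out <- .integrate_hybrid(conc, tcur, seg1_end, V0, params, sample_times)
    keep <- out[, 1] %in% sample_times
    if (any(keep)) {
      tt <- out[keep, 1]
      samp <- rbind(samp, cbind(tt, V0 * exp(params$g * (tt - t0)),
                                out[keep, -1, drop = FALSE]))
    }
    conc <- out[nrow(out), -1]
    tcur <- seg1_end
  }

  if (!duplicated && !is.na(t_dup) && t_dup >= t_end) {
    return(list(divided = FALSE, t_stop = t_end,
                V_stop = V0 * exp(params$g * (t_end - t0)), x = conc,
                duplicated = FALSE, t_dup = NA_real_, samples = samp))
  }

  # duplication jump: the new operator unit enters free
  if (!duplicated) {
    V_dup <- V0 * exp(params$g * (t_dup - t0))
    conc[4] <- conc[4] + 1 / molecules_per_nM(V_dup)
    duplicated <- TRUE
    tcur <- t_dup
  }
  V_cur <- V0 * exp(params$g * (tcur - t0))
  w_div <- if (is.null(forced_division_delay)) {
    sample_event_time(V_cur, "division", params)
  } else {
    forced_division_delay
  }
  t_div <- tcur + w_div
  seg2_end <- min(t_div, t_end)
  if (seg2_end > tcur) {
    out <- .integrate_hybrid(conc, tcur, seg2_end, V_cur, params, sample_times)
    keep <- out[, 1] %in% sample_times & out[, 1] > tcur
    if (any(keep)) {
      tt <- out[keep, 1]
      samp <- rbind(samp, cbind(tt, V0 * exp(params$g * (tt - t0)),
                                out[keep, -1, drop = FALSE]))
    }
    conc <- out[nrow(out), -1]
  }
  divided <- t_div <= t_end
  t_stop <- if (divided) t_div else t_end
  list(divided = divided, t_stop = t_stop,
       V_stop = V0 * exp(params$g * (t_stop - t0)), x = conc,
       duplicated = TRUE, t_dup = t_dup, samples = samp)
}

.run_cell <- function(mode, x, V0, duplicated, t0, t_end, params,
                      sample_times, refresh_dt = 0.5,
                      forced_division_delay = NULL) {
  if (mode == "stochastic") {
    res <- .cell_stochastic(x, V0, duplicated, t0, t_end, params,
                            sample_times, refresh_dt)
    n <- res$n_samples
    res$samples <- res$samples[seq_len(n), , drop = FALSE]
    res
  } else {
    .cell_hybrid(x, V0, duplicated, t0, t_end, params, sample_times,
                 forced_division_delay)
  }
}

# --- division interventions -------------------------------------------------

#' Forced-division interventions
#'
#' Construct interventions for the single-lineage engines that bias one
#' division event. `intervention_asymmetric_division()` forces the volume
#' fraction of daughter 1 at the `at`-th division to `ratio` (instead of a
#' Beta(q, q) draw) and then follows the daughter selected by `follow`
#' (default the smaller one). `intervention_delayed_division()` forces the
#' `at`-th division to occur exactly `delay` minutes after the preceding
#' DNA duplication (hybrid engine only). All other events are untouched.
#'
#' @param at division event index (1-based) the intervention applies to.
#' @param ratio forced daughter-1 volume fraction, in (0, 1).
#' @param follow which daughter to follow after the forced division:
#'   `"smaller"`, `"larger"`, `"d1"`, `"d2"` or `"policy"` (the engine's
#'   usual policy).
#' @param delay forced duplication-to-division delay, min (>= 0).
#' @return an object of class `lac_intervention`.
#' @export
intervention_asymmetric_division <- function(at, ratio, follow = "smaller") {
  if (!(ratio > 0 && ratio < 1)) stop("ratio must lie in (0, 1)")
  follow <- match.arg(follow, c("smaller", "larger", "d1", "d2", "policy"))
  structure(list(kind = "asymmetric_division", at = as.integer(at),
                 ratio = ratio, follow = follow),
            class = "lac_intervention")
}

#' @rdname intervention_asymmetric_division
#' @export
intervention_delayed_division <- function(at, delay) {
  if (delay < 0) stop("delay must be non-negative")
  structure(list(kind = "delayed_division", at = as.integer(at),
                 delay = delay),
            class = "lac_intervention")
}

.find_intervention <- function(interventions, kind, at) {
  for (iv in interventions) {
    if (iv$kind == kind && iv$at == at) return(iv)
  }
  NULL
}

# --- lineage orchestration --------------------------------------------------

#' Simulate one cell lineage through growth, reactions, duplication and division
#'
#' Runs a single cell forward in time; at each division one daughter is kept
#' according to `policy` and the simulation continues with it. The fully
#' stochastic engine (`simulate_cell_stochastic`) performs an exact SSA over
#' the 25-reaction network with the volume-dependent propensity prefactors
#' refreshed after every event and after every `refresh_dt` minutes of
#' silence; DNA-duplication and division hazards are part of the total
#' hazard. The hybrid engine (`simulate_cell_deterministic`) integrates the
#' stiff per-cell mass-action ODEs (dilution at rate g, surface-to-volume
#' ratio following the rod geometry) between duplication/division events
#' whose times are drawn exactly from the closed-form sampler.
#'
#' @param init a [cell_state()] in the matching mode.
#' @param t_end end of simulated time, min.
#' @param params a [lac_params()] object.
#' @param sample_times times (min) at which the state is recorded; default a
#'   1-min grid.
#' @param policy daughter-keeping policy: `"random"` (fair Bernoulli trial),
#'   `"first"`, `"smaller"` or `"larger"`.
#' @param interventions optional list of interventions built with
#'   [intervention_asymmetric_division()] / [intervention_delayed_division()].
#' @param refresh_dt silent-interval propensity refresh, min (stochastic
#'   engine only).
#' @return an object of class `lac_chain` with elements `samples` (data frame
#'   `time_min`, `V_fL`, the 10 species, `Y_total_nM`), `division_times`,
#'   `duplication_times`, `division_volumes`, `keep_choices`, `final`
#'   (the final [cell_state()]) and `mode`.
#' @export
simulate_cell_stochastic <- function(init, t_end, params,
                                     sample_times = NULL, policy = "random",
                                     interventions = list(),
                                     refresh_dt = 0.5) {
  .simulate_lineage(init, t_end, params, sample_times, "stochastic", policy,
                    interventions, refresh_dt)
}

#' @rdname simulate_cell_stochastic
#' @export
simulate_cell_deterministic <- function(init, t_end, params,
                                        sample_times = NULL,
                                        policy = "random",
                                        interventions = list()) {
  .simulate_lineage(init, t_end, params, sample_times, "deterministic",
                    policy, interventions)
}

.simulate_lineage <- function(init, t_end, params, sample_times, mode,
                              policy, interventions = list(),
                              refresh_dt = 0.5) {
  stopifnot(inherits(init, "cell_state"))
  if (init$mode != mode) stop("init state mode does not match the engine")
  if (t_end <= init$birth_time) stop("t_end must exceed the start time")
  policy <- match.arg(policy, c("random", "first", "smaller", "larger"))
  if (is.null(sample_times)) {
    sample_times <- seq(init$birth_time, t_end, by = 1)
  }
  sample_times <- sort(sample_times)

  for (iv in interventions) {
    if (iv$kind == "delayed_division" && mode != "deterministic") {
      stop("delayed-division interventions require the hybrid engine")
    }
  }

  cur_x <- init$x; cur_V <- init$V; cur_dup <- init$duplicated
  tcur <- init$birth_time
  st_remaining <- sample_times
  rows <- list()
  div_times <- numeric(0); dup_times <- numeric(0)
  div_volumes <- numeric(0); keeps <- integer(0)
  n_div <- 0L

  repeat {
    iv_delay <- .find_intervention(interventions, "delayed_division",
                                   n_div + 1L)
    st <- st_remaining[st_remaining >= tcur]
    res <- .run_cell(mode, cur_x, cur_V, cur_dup, tcur, t_end, params, st,
                     refresh_dt = refresh_dt,
                     forced_division_delay = iv_delay$delay)
    if (nrow(res$samples)) rows[[length(rows) + 1L]] <- res$samples
    if (!is.na(res$t_dup)) dup_times <- c(dup_times, res$t_dup)
    st_remaining <- st_remaining[st_remaining > res$t_stop]
    if (!res$divided) {
      final <- cell_state(if (mode == "stochastic") res$x else pmax(res$x, 0),
                          res$V_stop, res$duplicated, tcur,
                          init$lineage_id, mode)
      final$birth_time <- tcur
      break
    }
    n_div <- n_div + 1L
    div_times <- c(div_times, res$t_stop)
    div_volumes <- c(div_volumes, res$V_stop)
    mother <- cell_state(res$x, res$V_stop, TRUE, res$t_stop,
                         init$lineage_id, mode)
    iv_asym <- .find_intervention(interventions, "asymmetric_division", n_div)
    f_forced <- iv_asym$ratio
    part <- partition_cell(mother, params, f = f_forced, time = res$t_stop)
    follow <- if (!is.null(iv_asym) && iv_asym$follow != "policy") {
      iv_asym$follow
    } else {
      switch(policy,
             random  = if (stats::runif(1) < 0.5) "d1" else "d2",
             first   = "d1",
             smaller = if (part$d1$V <= part$d2$V) "d1" else "d2",
             larger  = if (part$d1$V >= part$d2$V) "d1" else "d2")
    }
    if (follow == "smaller") follow <- if (part$d1$V <= part$d2$V) "d1" else "d2"
    if (follow == "larger")  follow <- if (part$d1$V >= part$d2$V) "d1" else "d2"
    keeps <- c(keeps, if (follow == "d1") 1L else 2L)
    chosen <- part[[follow]]
    cur_x <- chosen$x; cur_V <- chosen$V; cur_dup <- FALSE
    tcur <- res$t_stop
    if (tcur >= t_end) {
      final <- chosen
      break
    }
  }

  samples <- .samples_to_df(rows, mode)
  structure(list(samples = samples, division_times = div_times,
                 duplication_times = dup_times,
                 division_volumes = div_volumes, keep_choices = keeps,
                 final = final, mode = mode, t_end = t_end),
            class = "lac_chain")
}

.samples_to_df <- function(rows, mode) {
  if (!length(rows)) {
    df <- as.data.frame(matrix(numeric(0), ncol = 13))
    names(df) <- c("time_min", "V_fL", species_names(), "Y_total_nM")
    return(df)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c("time_min", "V_fL", species_names())
  df <- as.data.frame(m)
  df$Y_total_nM <- if (mode == "stochastic") {
    (df$Y + df$YIex) / molecules_per_nM(df$V_fL)
  } else {
    df$Y + df$YIex
  }
  df
}

#' @export
print.lac_chain <- function(x, ...) {
  cat(sprintf("<lac_chain (%s reactions)> %d samples to t = %g min, %d divisions\n",
              x$mode, nrow(x$samples), x$t_end, length(x$division_times)))
  if (length(x$division_times) > 1) {
    iv <- diff(c(0, x$division_times))
    cat(sprintf("  mean interdivision time %.2f min\n", mean(iv)))
  }
  invisible(x)
}

#' @export
plot.lac_chain <- function(x, y, observable = "Y_total_nM", log = "", ...) {
  plot(x$samples$time_min, x$samples[[observable]], type = "l",
       xlab = "time (min)", ylab = observable, log = log, ...)
  invisible(x)
}
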
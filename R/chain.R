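# Cell chain: the history of a single cell through time. At every division
# one daughter is kept, chosen by a fair Bernoulli trial; for intensive
# observables (concentrations) the stationary chain PDF approximates the
# population NDF because mother and daughters share the same concentrations
# on average.

#' Sampling plan for a cell-chain simulation
#'
#' @param t_final total simulated time, min.
#' @param sample_dt periodic sampling interval, min.
#' @param burn_in initial transient discarded from the stationary sample
#'   set, min (default 500, about 17 generations).
#' @return object of class `chain_plan`.
#' @export
chain_plan <- function(t_final, sample_dt = 10, burn_in = 500) {
  stopifnot(sample_dt > 0, burn_in >= 0, burn_in < t_final)
  structure(list(t_final = t_final, sample_dt = sample_dt,
                 burn_in = burn_in),
            class = "chain_plan")
}

#' Simulate a cell chain and collect its stationary sample set
#'
#' Runs the chosen single-cell engine, keeping one daughter per division by
#' a fair Bernoulli trial, samples periodically in time and returns both
#' the full trajectory and the post-burn-in stationary samples of the total
#' LacY concentration.
#'
#' @param init a [cell_state()] in the matching mode.
#' @param plan a [chain_plan()].
#' @param mode `"stochastic"` or `"deterministic"` reaction dynamics.
#' @param params a [lac_params()] object.
#' @param ... further arguments passed to the engine
#'   (e.g. `interventions`, `refresh_dt`).
#' @return a `lac_chain` (see [simulate_cell_stochastic()]) with extra
#'   elements `stationary` (post-burn-in samples data frame) and `plan`.
#' @export
simulate_chain <- function(init, plan, mode = c("stochastic", "deterministic"),
                           params, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(plan, "chain_plan"))
  st <- seq(init$birth_time, plan$t_final, by = plan$sample_dt)
  chain <- if (mode == "stochastic") {
    simulate_cell_stochastic(init, plan$t_final, params,
                             sample_times = st, policy = "random", ...)
  } else {
    simulate_cell_deterministic(init, plan$t_final, params,
                                sample_times = st, policy = "random", ...)
  }
  chain$stationary <- chain$samples[chain$samples$time_min > plan$burn_in, ]
  chain$plan <- plan
  chain
}
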
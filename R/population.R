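# Cell-population Monte Carlo: every daughter is tracked; cells evolve
# independently between divisions (the only coupling is the division
# bookkeeping), so each cell is simulated to its own division event and
# divisions are processed in chronological order. Once the census reaches
# N_cellsmax the constant-number technique activates: every subsequent
# division is followed by removal of one uniformly chosen cell, keeping the
# census exactly at N_cellsmax without biasing distribution estimates.

#' Simulate a full cell population
#'
#' Starts from one or more initial cells and tracks every daughter through
#' growth, (stochastic or deterministic) reactions, stochastic DNA
#' duplication, division and partitioning. Each division replaces the mother
#' by two daughters; once the census reaches `N_cellsmax`, each subsequent
#' division is followed by uniform random removal of one cell (the
#' constant-number Monte Carlo technique).
#'
#' @param init a [cell_state()] or list of them (all in the same mode).
#' @param t_end end of simulated time, min.
#' @param N_cellsmax census cap for the constant-number technique.
#' @param mode `"stochastic"` or `"deterministic"` reaction dynamics.
#' @param sample_times times at which population snapshots are taken.
#' @param params a [lac_params()] object.
#' @param refresh_dt propensity refresh interval, min (stochastic mode).
#' @param batch_id identifier stamped on the snapshots.
#' @return object of class `lac_population`: `snapshots` (data frame with
#'   `time_min`, `cell_id`, `V_fL`, species columns, `Y_total_nM`),
#'   `mean_timecourse` (`time_min`, `mean_Y_total_nM`, `census`), `events`
#'   (division/duplication/removal log), `n_divisions`, `n_removals`.
#' @export
simulate_population <- function(init, t_end, N_cellsmax,
                                mode = c("stochastic", "deterministic"),
                                sample_times, params, refresh_dt = 0.5,
                                batch_id = 1L) {
  mode <- match.arg(mode)
  if (inherits(init, "cell_state")) init <- list(init)
  stopifnot(length(init) >= 1, N_cellsmax >= 1)
  for (cs in init) {
    if (!inherits(cs, "cell_state") || cs$mode != mode) {
      stop("all initial cells must be cell_state objects in mode ", mode)
    }
  }
  sample_times <- sort(sample_times)

  cap <- 4096L
  birth_time <- numeric(cap); divtime <- rep(Inf, cap)
  end_time <- numeric(cap); removed_time <- rep(Inf, cap)
  alive <- logical(cap); duplicated_at <- rep(NA_real_, cap)
  samples <- vector("list", cap)
  div_state <- vector("list", cap)
  n_cells <- 0L

  grow <- function() {
    cap2 <- 2L * cap
    length(birth_time) <<- cap2; length(divtime) <<- cap2
    length(end_time) <<- cap2; length(removed_time) <<- cap2
    length(alive) <<- cap2; length(duplicated_at) <<- cap2
    length(samples) <<- cap2; length(div_state) <<- cap2
    divtime[(cap + 1L):cap2] <<- Inf
    removed_time[(cap + 1L):cap2] <<- Inf
    alive[(cap + 1L):cap2] <<- FALSE
    cap <<- cap2
  }

  new_cell <- function(x, V0, dup, t0) {
    if (n_cells == cap) grow()
    n_cells <<- n_cells + 1L
    id <- n_cells
    st <- sample_times[sample_times >= t0 & sample_times <= t_end]
    res <- .run_cell(mode, x, V0, dup, t0, t_end, params, st,
                     refresh_dt = refresh_dt)
    birth_time[id] <<- t0
    divtime[id] <<- if (res$divided) res$t_stop else Inf
    end_time[id] <<- res$t_stop
    removed_time[id] <<- Inf
    alive[id] <<- TRUE
    duplicated_at[id] <<- res$t_dup
    samples[[id]] <<- res$samples
    div_state[[id]] <<- if (res$divided) list(x = res$x, V = res$V_stop) else NULL
    id
  }

  for (cs in init) new_cell(cs$x, cs$V, cs$duplicated, cs$birth_time)
  census <- length(init)
  n_div <- 0L; n_rem <- 0L
  removal_log <- numeric(0)

  repeat {
    id <- which.min(divtime[seq_len(n_cells)])
    Tdiv <- divtime[id]
    if (!is.finite(Tdiv) || Tdiv > t_end) break
    divtime[id] <- Inf
    alive[id] <- FALSE
    mother <- cell_state(if (mode == "stochastic") div_state[[id]]$x
                         else pmax(div_state[[id]]$x, 0),
                         div_state[[id]]$V, TRUE, Tdiv, id, mode)
    part <- partition_cell(mother, params, time = Tdiv)
    new_cell(part$d1$x, part$d1$V, FALSE, Tdiv)
    new_cell(part$d2$x, part$d2$V, FALSE, Tdiv)
    census <- census + 1L
    n_div <- n_div + 1L
    if (census > N_cellsmax) {
      living <- which(alive[seq_len(n_cells)])
      victim <- living[sample.int(length(living), 1L)]
      alive[victim] <- FALSE
      removed_time[victim] <- Tdiv
      divtime[victim] <- Inf
      census <- census - 1L
      n_rem <- n_rem + 1L
      removal_log <- c(removal_log, Tdiv)
    }
  }
  if (census < 1L) stop("empty population: every cell was removed")

  # assemble snapshots, dropping post-removal samples
  keep_rows <- vector("list", n_cells)
  for (id in seq_len(n_cells)) {
    m <- samples[[id]]
    if (is.null(m) || nrow(m) == 0) next
    ok <- m[, 1] < removed_time[id]
    if (!all(ok)) m <- m[ok, , drop = FALSE]
    if (nrow(m)) keep_rows[[id]] <- cbind(m, cell_id = id)
  }
  keep_rows <- keep_rows[!vapply(keep_rows, is.null, logical(1))]
  snap <- if (length(keep_rows)) {
    m <- do.call(rbind, keep_rows)
    colnames(m) <- c("time_min", "V_fL", species_names(), "cell_id")
    df <- as.data.frame(m)
    df$Y_total_nM <- if (mode == "stochastic") {
      (df$Y + df$YIex) / molecules_per_nM(df$V_fL)
    } else {
      df$Y + df$YIex
    }
    df$batch_id <- batch_id
    df[order(df$time_min, df$cell_id), ]
  } else {
    data.frame()
  }

  mtc <- if (nrow(snap)) {
    agg <- tapply(snap$Y_total_nM, snap$time_min, mean)
    cen <- tapply(snap$Y_total_nM, snap$time_min, length)
    data.frame(time_min = as.numeric(names(agg)),
               mean_Y_total_nM = as.numeric(agg),
               census = as.integer(cen))
  } else {
    data.frame()
  }

  divs <- which(!vapply(div_state, is.null, logical(1))[seq_len(n_cells)])
  events <- data.frame(
    cell_id = divs,
    birth_min = birth_time[divs],
    division_min = end_time[divs],
    duplication_min = duplicated_at[divs]
  )

  structure(list(snapshots = snap, mean_timecourse = mtc, events = events,
                 removals = removal_log, n_divisions = n_div,
                 n_removals = n_rem, final_census = census, mode = mode,
                 N_cellsmax = N_cellsmax, t_end = t_end,
                 batch_id = batch_id, n_cells_total = n_cells),
            class = "lac_population")
}

#' @export
print.lac_population <- function(x, ...) {
  cat(sprintf("<lac_population (%s reactions)> t_end = %g min, census %d (cap %d)\n",
              x$mode, x$t_end, x$final_census, x$N_cellsmax))
  cat(sprintf("  %d divisions, %d constant-number removals, %d cells tracked\n",
              x$n_divisions, x$n_removals, x$n_cells_total))
  invisible(x)
}

#' Run independent population batches and pool the snapshots
#'
#' Repeats [simulate_population()] `n_batches` times with independent seeds
#' drawn from the current RNG stream and concatenates the snapshots.
#'
#' @param n_batches number of independent batches.
#' @param ... arguments passed to [simulate_population()].
#' @return list with `snapshots` (pooled data frame), `batches` (list of
#'   `lac_population` objects).
#' @export
run_batches <- function(n_batches, ...) {
  stopifnot(n_batches >= 1)
  seeds <- sample.int(.Machine$integer.max, n_batches)
  batches <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    set.seed(seeds[b])
    batches[[b]] <- simulate_population(..., batch_id = b)
  }
  snaps <- do.call(rbind, lapply(batches, `[[`, "snapshots"))
  list(snapshots = snaps, batches = batches)
}

#' Geometry-only population averages of A/V and operator concentration
#'
#' Runs the population Monte Carlo with reactions disabled - each cell
#' carries only its volume and chromosome/duplication state - to
#' stationarity of the size distribution, and returns the population
#' averages of the surface-to-volume ratio A(V)/V and of the total operator
#' concentration (1 or 2 copies over the cell volume, in nM). Event times
#' use the exact closed-form sampler for the power-law hazards under
#' exponential growth; volume partitions by the symmetric Beta(q, q)
#' fraction and the constant-number technique caps the census.
#'
#' @param params a [lac_params()] object.
#' @param t_end simulated time, min (default 600, about 20 generations).
#' @param N_cellsmax census cap per batch.
#' @param n_batches number of independent batches pooled for the averages.
#' @param n_init initial cells per batch (newborn size `V_d_crit/2`).
#' @param sample_times snapshot times pooled into the averages (default:
#'   the single time `t_end`). Spreading the snapshots over one division
#'   cycle averages out any residual cell-cycle synchronization left over
#'   from the common newborn initial condition.
#' @return list with `avg_A_over_V` (1/um), `avg_O_T` (nM), `n_cells`,
#'   `cells` (pooled data frame: batch, time_min, V_fL, n_chromosomes) and
#'   the stationary-age analytic predictions `predicted` for reference.
#' @export
geometry_only_population <- function(params, t_end = 600, N_cellsmax = 500,
                                     n_batches = 20, n_init = 50,
                                     sample_times = t_end) {
  stopifnot(n_batches >= 1, N_cellsmax >= 1, all(sample_times <= t_end))
  pooled <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    pooled[[b]] <- .geometry_batch(params, t_end, N_cellsmax, n_init, b,
                                   sample_times)
  }
  cells <- do.call(rbind, pooled)
  AoV <- area_from_volume(cells$V_fL, params$R0) / cells$V_fL
  O_T <- cells$n_chromosomes / molecules_per_nM(cells$V_fL)
  list(avg_A_over_V = mean(AoV), avg_O_T = mean(O_T),
       n_cells = nrow(cells), cells = cells,
       predicted = predicted_population_averages(params))
}

# one geometry-only batch: event-driven, volumes and duplication flags only
.geometry_batch <- function(params, t_end, N_cellsmax, n_init, batch_id,
                            sample_times = t_end) {
  V0n <- params$V_d_crit / 2
  cap <- 2048L
  Vb <- numeric(cap); tb <- numeric(cap); tdup <- numeric(cap)
  tdiv <- rep(Inf, cap); tstop <- rep(Inf, cap)
  n <- 0L
  add <- function(V, t0) {
    if (n == cap) {
      cap2 <- 2L * cap
      length(Vb) <<- cap2; length(tb) <<- cap2; length(tdup) <<- cap2
      length(tdiv) <<- cap2; length(tstop) <<- cap2
      tdiv[(cap + 1L):cap2] <<- Inf; tstop[(cap + 1L):cap2] <<- Inf
      cap <<- cap2
    }
    n <<- n + 1L
    w_s <- sample_event_time(V, "duplication", params)
    V_s <- V * exp(params$g * w_s)
    w_d <- sample_event_time(V_s, "division", params)
    Vb[n] <<- V; tb[n] <<- t0
    tdup[n] <<- t0 + w_s
    tdiv[n] <<- t0 + w_s + w_d
    tstop[n] <<- Inf
    n
  }
  for (i in seq_len(n_init)) add(V0n, 0)
  census <- n_init
  pending <- tdiv            # division times of still-alive cells, Inf else
  repeat {
    id <- which.min(pending[seq_len(n)])
    Td <- pending[id]
    if (!is.finite(Td) || Td > t_end) break
    pending[id] <- Inf; tstop[id] <- Td
    Vm <- Vb[id] * exp(params$g * (Td - tb[id]))
    f <- stats::rbeta(1, params$q, params$q)
    add(f * Vm, Td); add(Vm - f * Vm, Td)
    pending[(n - 1L):n] <- tdiv[(n - 1L):n]
    census <- census + 1L
    if (census > N_cellsmax) {
      living <- which(is.finite(pending[seq_len(n)]))
      victim <- living[sample.int(length(living), 1L)]
      pending[victim] <- Inf; tstop[victim] <- Td
      census <- census - 1L
    }
  }
  rows <- lapply(sample_times, function(ts) {
    idx <- which(tb[seq_len(n)] <= ts & ts < pmin(tdiv[seq_len(n)],
                                                  tstop[seq_len(n)]))
    data.frame(batch = batch_id, time_min = ts,
               V_fL = Vb[idx] * exp(params$g * (ts - tb[idx])),
               n_chromosomes = ifelse(tdup[idx] <= ts, 2L, 1L))
  })
  do.call(rbind, rows)
}

#' Sharp-threshold analytic population averages
#'
#' Closed-form stationary-population averages of A/V and the operator
#' concentration in the idealized limit of deterministic duplication exactly
#' at `V_s_crit` and symmetric halving exactly at `V_d_crit`
#' (sharpness exponents and beta q to infinity). A balanced exponentially
#' growing population then has age density \eqn{2 g e^{-g a}} over one
#' 30-min cycle, giving
#' \deqn{\langle A/V\rangle = 2/R_0 + (4/3)\pi R_0^2 \cdot \tfrac{3}{2 V_{d}},\qquad
#'       \langle [O]_T\rangle \propto \frac{1}{V_0}\left(\tfrac12 + (V_0/V_s)^2\right)}
#' with newborn volume \eqn{V_0 = V_d/2}. Used as the numeric oracle for the
#' geometry-only population Monte Carlo.
#'
#' @param params a [lac_params()] object.
#' @return list `avg_A_over_V` (1/um), `avg_O_T` (nM).
#' @export
predicted_population_averages <- function(params) {
  V0 <- params$V_d_crit / 2
  inv_V <- (1 - 0.25) / V0                # population mean of 1/V
  AoV <- 2 / params$R0 + (4 / 3) * pi * params$R0^2 * inv_V
  nV <- (1 / V0) * (0.5 + (V0 / params$V_s_crit)^2)  # copies per fL
  list(avg_A_over_V = AoV, avg_O_T = nV / molecules_per_nM(1))
}
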
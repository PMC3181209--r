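# Structured continuum model: the whole population is lumped into one
# expanding biotic phase described by average intracellular concentrations.
# Reaction terms are the deterministic mass-action rates; growth appears as
# a dilution sink -mu [X] on every species except the operator-carrying
# ones, whose total concentration is a fixed cell characteristic <[O]_T>
# maintained by ongoing DNA duplication. The two lumped cell
# characteristics <A/V> and <[O]_T> are either estimated in closed form
# from the division-cycle geometry or measured from a population run.

#' Cycle-averaged surface-to-volume ratio of a growing rod cell
#'
#' A newborn cell of volume \eqn{V_{d,crit}/2} grows exponentially to
#' \eqn{V_{d,crit}} over one division cycle of length \eqn{\ln 2/g}. Since
#' the rod geometry gives \eqn{A/V = 2/R_0 + (4/3)\pi R_0^2 / V}, the time
#' average over the cycle has the closed form
#' \deqn{\langle A/V\rangle = \frac{2}{R_0} +
#'   \frac{(4/3)\pi R_0^2}{2\ln 2\; (V_{d,crit}/2)}.}
#'
#' @param params a [lac_params()] object (fields `R0`, `V_d_crit`, `g`).
#' @param method `"closed_form"` (default) or `"quadrature"` (adaptive
#'   numerical time average, used as an independent check).
#' @return average surface-to-volume ratio, \eqn{\mu m^{-1}}.
#' @examples
#' estimate_A_over_V(lac_params())  # ~5.64 1/um for the nominal geometry
#' @export
estimate_A_over_V <- function(params, method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  R0 <- params$R0; V0 <- params$V_d_crit / 2
  if (method == "closed_form") {
    return(2 / R0 + (4 / 3) * pi * R0^2 / (2 * log(2) * V0))
  }
  td <- log(2) / params$g
  f <- function(t) {
    V <- V0 * exp(params$g * t)
    area_from_volume(V, R0) / V
  }
  stats::integrate(f, 0, td, rel.tol = 1e-12)$value / td
}

#' Cycle-averaged total operator concentration
#'
#' Over one division cycle a newborn cell of volume \eqn{V_{d,crit}/2}
#' carries 1 operator copy until its volume reaches \eqn{V_{s,crit}} (DNA
#' duplication) and 2 copies until division at \eqn{V_{d,crit}}. The time
#' average of \eqn{n(t)/V(t)} under exponential growth reduces to
#' \deqn{\langle [O]_T\rangle = \frac{1}{V_{s,crit}\,\ln 2}\ \mathrm{copies/fL},}
#' independent of \eqn{V_{d,crit}}, converted to nM via Avogadro's number.
#'
#' @param params a [lac_params()] object; requires
#'   `V_d_crit/2 < V_s_crit < V_d_crit`.
#' @param method `"closed_form"` or `"quadrature"`.
#' @return average operator concentration, nM.
#' @examples
#' estimate_O_T(lac_params())  # ~2.40 nM for the nominal critical volumes
#' @export
estimate_O_T <- function(params, method = c("closed_form", "quadrature")) {
  method <- match.arg(method)
  V0 <- params$V_d_crit / 2; Vs <- params$V_s_crit
  if (!(V0 < Vs && Vs < params$V_d_crit)) {
    stop("requires V_d_crit/2 < V_s_crit < V_d_crit")
  }
  if (method == "closed_form") {
    return(1 / (Vs * log(2)) / molecules_per_nM(1))
  }
  g <- params$g; td <- log(2) / g
  ts <- log(Vs / V0) / g
  f <- function(t) {
    n <- ifelse(t < ts, 1, 2)
    n / (V0 * exp(g * t))
  }
  val <- (stats::integrate(f, 0, ts, rel.tol = 1e-12)$value +
          stats::integrate(f, ts, td, rel.tol = 1e-12)$value) / td
  val / molecules_per_nM(1)
}

#' Continuum-model right-hand side
#'
#' Time derivatives of the 10 average concentrations in the lumped biotic
#' phase: mass-action reaction rates at a fixed surface-to-volume ratio
#' `avg_A_over_V`, dilution at the average specific growth rate `mu` on all
#' species except the operator-carrying ones (`O`, `R2O`). The total
#' operator concentration is the conserved cell characteristic
#' `avg_O_T`; the free-operator concentration is `avg_O_T - [R2O]`.
#'
#' @param conc 10 concentrations (nM), ordered as [species_names()]; the
#'   `O` entry must equal `avg_O_T - R2O` (checked).
#' @param params a [lac_params()] object.
#' @param avg_A_over_V lumped surface-to-volume ratio, 1/um.
#' @param avg_O_T lumped total operator concentration, nM.
#' @param mu average specific growth rate, 1/min (defaults to `g`).
#' @return 10 derivatives, nM/min.
#' @export
continuum_rhs <- function(conc, params, avg_A_over_V, avg_O_T,
                          mu = params$g) {
  if (conc[5] > avg_O_T + 1e-9 * max(1, avg_O_T)) {
    stop("state error: [R2O] exceeds the total operator concentration")
  }
  ode_rhs(conc, params, A_over_V = avg_A_over_V, dilution_rate = mu,
          operator_dilution = FALSE)
}

# continuum state template with operator total OT and bound fraction phi
.continuum_init <- function(avg_O_T, high = FALSE) {
  x <- numeric(10)
  x[1] <- 0.474                       # MR near its decoupled steady state
  if (high) {
    x[4] <- avg_O_T * 0.95; x[5] <- avg_O_T * 0.05
    x[6] <- 1e6; x[8] <- 2.5; x[9] <- 300; x[10] <- 15
  } else {
    x[4] <- avg_O_T * 0.05; x[5] <- avg_O_T * 0.95
  }
  x
}

#' Integrate the structured continuum model
#'
#' @param times output times, min.
#' @param init initial concentrations (default: near-repressed state).
#' @inheritParams continuum_rhs
#' @return deSolve matrix (`time` plus the 10 species), with a
#'   `Y_total_nM` column appended.
#' @export
continuum_trajectory <- function(times, params, avg_A_over_V, avg_O_T,
                                 init = NULL, mu = params$g) {
  if (is.null(init)) init <- .continuum_init(avg_O_T)
  pv <- .ode_parms(params, mode = 0, AoV_fixed = avg_A_over_V, mu = mu)
  out <- deSolve::lsoda(y = init, times = times, func = "lac_derivs",
                        parms = pv, dllname = "lacpop",
                        initfunc = "lac_initmod",
                        rtol = 1e-10, atol = 1e-12, maxsteps = 1e5)
  if (attr(out, "istate")[1] < 0) stop("continuum integration failed")
  cbind(out, Y_total_nM = out[, 10] + out[, 11])
}

# The continuum RHS conserves the operator total [O] + [R2O] = <[O]_T>
# exactly, so the full 10-dim Jacobian is singular along that direction.
# Root solving and stability analysis therefore work in the 9-dim reduced
# space with [O] eliminated as <[O]_T> - [R2O].
.expand9 <- function(z, OT) {
  x <- numeric(10)
  x[c(1:3, 5:10)] <- z
  x[4] <- OT - z[3 + 1]          # z[4] is R2O in the reduced ordering
  x
}
.reduce10 <- function(x) x[c(1:3, 5:10)]

.rhs9 <- function(z, params, AoV, OT, mu) {
  x <- .expand9(z, OT)
  .reduce10(ode_rhs(x, params, AoV, mu, operator_dilution = FALSE))
}

.jac9 <- function(z, params, AoV, OT, mu) {
  f0 <- .rhs9(z, params, AoV, OT, mu)
  J <- matrix(0, 9, 9)
  h <- 1e-6 * pmax(abs(z), 1e-4)
  for (j in 1:9) {
    zp <- z; zp[j] <- zp[j] + h[j]
    J[, j] <- (.rhs9(zp, params, AoV, OT, mu) - f0) / h[j]
  }
  J
}

# damped Newton root in the reduced space; returns full 10-dim state or NULL
.newton_ss <- function(x0, params, AoV, OT, mu, tol = 1e-10, maxit = 200) {
  clamp <- function(z) {
    z <- pmax(z, 0)
    z[4] <- min(z[4], OT)        # keep R2O within the operator total
    z
  }
  z <- clamp(.reduce10(x0))
  scale <- pmax(abs(z), 1e-3)
  f <- function(z) .rhs9(z, params, AoV, OT, mu)
  for (it in seq_len(maxit)) {
    fz <- f(z)
    if (!all(is.finite(fz))) return(NULL)
    if (max(abs(fz / pmax(scale, abs(z)))) < tol) break
    J <- .jac9(z, params, AoV, OT, mu)
    step <- tryCatch(solve(J, -fz), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    n0 <- sum((fz / scale)^2)
    stalled <- FALSE
    repeat {
      zn <- clamp(z + lam * step)
      fn <- f(zn)
      if (all(is.finite(fn)) && sum((fn / scale)^2) < n0) break
      lam <- lam / 2
      if (lam < 1e-8) { stalled <- TRUE; break }
    }
    if (stalled) break            # at the float floor; final check decides
    z <- zn
  }
  fz <- f(z)
  if (max(abs(fz / pmax(scale, abs(z)))) > 1e-7) return(NULL)
  .expand9(z, OT)
}

#' Steady states of the structured continuum model
#'
#' Finds all steady states of the lumped model at the given extracellular
#' inducer level by (i) integrating to the attractors from repressed-like
#' and induced-like initial states, (ii) damped Newton polishing from those
#' attractors, from interpolated states between them and from any warm
#' starts supplied, then deduplicating and labelling stability by the sign
#' of the leading Jacobian eigenvalue (finite-difference Jacobian).
#'
#' @param I_ex extracellular inducer, nM.
#' @param params a [lac_params()] object (`I_ex` field is overridden).
#' @param avg_A_over_V,avg_O_T lumped cell characteristics (defaults: the
#'   closed-form cycle-average estimators).
#' @param mu average specific growth rate, 1/min.
#' @param warm_starts optional list of state vectors used as additional
#'   Newton starts (branch continuation).
#' @return data frame with columns `I_ex_nM`, `Y_total_nM`, `stable`,
#'   `leading_eigenvalue`, plus the full states in `attr(, "states")`
#'   (one row per steady state, ordered by `Y_total_nM`).
#' @export
continuum_steady_states <- function(I_ex, params,
                                    avg_A_over_V = estimate_A_over_V(params),
                                    avg_O_T = estimate_O_T(params),
                                    mu = params$g, warm_starts = list()) {
  params <- lac_params_update(params, I_ex = I_ex)
  OT <- avg_O_T
  # attractors by forward integration
  t_eq <- c(0, 4000)
  lo <- continuum_trajectory(t_eq, params, avg_A_over_V, OT,
                             init = .continuum_init(OT, FALSE), mu = mu)
  hi <- continuum_trajectory(t_eq, params, avg_A_over_V, OT,
                             init = .continuum_init(OT, TRUE), mu = mu)
  s_lo <- pmax(as.numeric(lo[nrow(lo), 2:11]), 0)
  s_hi <- pmax(as.numeric(hi[nrow(hi), 2:11]), 0)
  starts <- c(list(s_lo, s_hi), warm_starts)
  for (a in c(0.2, 0.35, 0.5, 0.65, 0.8)) {
    starts[[length(starts) + 1L]] <- a * s_lo + (1 - a) * s_hi
  }
  # geometric interpolation catches the saddle when branches are far apart
  if (abs(s_lo[9] - s_hi[9]) > 1) {
    for (a in c(0.3, 0.5, 0.7)) {
      starts[[length(starts) + 1L]] <-
        exp(a * log(pmax(s_lo, 1e-12)) + (1 - a) * log(pmax(s_hi, 1e-12)))
    }
  }
  sols <- list()
  for (x0 in starts) {
    s <- .newton_ss(x0, params, avg_A_over_V, OT, mu)
    if (is.null(s)) next
    dup <- FALSE
    for (ss in sols) {
      if (max(abs(s - ss) / pmax(abs(ss), 1e-3)) < 1e-5) { dup <- TRUE; break }
    }
    if (!dup) sols[[length(sols) + 1L]] <- s
  }
  if (!length(sols)) stop("no steady state found from any start")
  yt <- vapply(sols, function(s) s[9] + s[10], numeric(1))
  ord <- order(yt)
  sols <- sols[ord]; yt <- yt[ord]
  lead <- vapply(sols, function(s) {
    max(Re(eigen(.jac9(.reduce10(s), params, avg_A_over_V, OT, mu),
                 only.values = TRUE)$values))
  }, numeric(1))
  out <- data.frame(I_ex_nM = I_ex, Y_total_nM = yt,
                    stable = lead < 0, leading_eigenvalue = lead)
  attr(out, "states") <- do.call(rbind, sols)
  out
}

# update selected fields of an existing parameter object (re-validated)
#' @rdname lac_params
#' @param params an existing `lac_params` object to modify.
#' @export
lac_params_update <- function(params, ...) {
  stopifnot(inherits(params, "lac_params"))
  base <- unclass(params)
  base$ht_um <- NULL; base$doubling_time <- NULL
  do.call(lac_params, utils::modifyList(base, list(...)))
}

#' Bifurcation diagram of the lac operon switch
#'
#' Sweeps the extracellular inducer level over a grid and collects all
#' continuum steady states at each value, warm-starting the Newton solver
#' from the neighbouring grid point's branches in both sweep directions so
#' branches are followed through the folds. The S-shaped diagram of total
#' LacY concentration versus inducer exhibits a bistable window between the
#' two fold points.
#'
#' @param I_ex_grid monotone grid of extracellular inducer levels, nM.
#' @inheritParams continuum_steady_states
#' @return data frame `I_ex_nM`, `I_ex_uM`, `Y_total_nM`, `stable`; the
#'   attribute `"bistable_window"` holds the inducer range (nM) with 3
#'   coexisting states.
#' @export
bifurcation_scan <- function(I_ex_grid, params,
                             avg_A_over_V = estimate_A_over_V(params),
                             avg_O_T = estimate_O_T(params),
                             mu = params$g) {
  stopifnot(!is.unsorted(I_ex_grid))
  res <- vector("list", length(I_ex_grid))
  sweep_once <- function(grid_idx) {
    warm <- list()
    for (i in grid_idx) {
      ss <- tryCatch(
        continuum_steady_states(I_ex_grid[i], params, avg_A_over_V, avg_O_T,
                                mu, warm_starts = warm),
        error = function(e) NULL)
      if (is.null(ss)) next
      st <- attr(ss, "states")
      warm <- lapply(seq_len(nrow(st)), function(k) st[k, ])
      prev <- res[[i]]
      if (is.null(prev) || nrow(ss) > nrow(prev)) res[[i]] <<- ss
    }
  }
  sweep_once(seq_along(I_ex_grid))
  sweep_once(rev(seq_along(I_ex_grid)))
  out <- do.call(rbind, res)
  out$I_ex_uM <- out$I_ex_nM / 1000
  attr(out, "states") <- NULL
  n_states <- tapply(out$Y_total_nM, out$I_ex_nM, length)
  bist <- as.numeric(names(n_states))[n_states >= 3]
  attr(out, "bistable_window") <- if (length(bist)) range(bist) else NULL
  rownames(out) <- NULL
  out
}

#' Attractor states of the switch at a given inducer level
#'
#' Returns the repressed ("off") or induced ("on") stable steady state of
#' the continuum model, as concentrations, optionally converted to rounded
#' copy numbers for a stochastic-mode cell of volume `V`.
#'
#' @param which `"off"` or `"on"`.
#' @param I_ex extracellular inducer, nM.
#' @param params a [lac_params()] object.
#' @param V cell volume used for `"stochastic"` conversion, fL.
#' @param mode `"deterministic"` (nM concentrations) or `"stochastic"`
#'   (integer copies; the single operator unit is assigned to the dominant
#'   operator species).
#' @inheritParams continuum_steady_states
#' @return a [cell_state()] of volume `V` (newborn: not duplicated).
#' @export
attractor_state <- function(which = c("off", "on"), I_ex, params,
                            V = params$V_d_crit / 2,
                            mode = c("deterministic", "stochastic"),
                            avg_A_over_V = estimate_A_over_V(params),
                            avg_O_T = estimate_O_T(params)) {
  which <- match.arg(which)
  mode <- match.arg(mode)
  ss <- continuum_steady_states(I_ex, params, avg_A_over_V, avg_O_T)
  stable <- which(ss$stable)
  if (!length(stable)) stop("no stable steady state found")
  row <- if (which == "off") stable[1] else stable[length(stable)]
  conc <- attr(ss, "states")[row, ]
  if (mode == "deterministic") {
    # per-cell state: 1 operator copy in volume V, mother's bound fraction
    ot_cell <- 1 / molecules_per_nM(V)
    phi <- conc[5] / (conc[4] + conc[5])
    conc[4] <- (1 - phi) * ot_cell
    conc[5] <- phi * ot_cell
    cell_state(conc, V, FALSE, 0, 1L, "deterministic")
  } else {
    Om <- molecules_per_nM(V)
    x <- round(conc * Om)
    phi <- conc[5] / (conc[4] + conc[5])
    x[4] <- if (phi < 0.5) 1 else 0
    x[5] <- 1 - x[4]
    cell_state(x, V, FALSE, 0, 1L, "stochastic")
  }
}
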
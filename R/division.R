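# DNA-duplication and division hazards, exact event-time sampling under
# exponential volume growth, and partitioning of volume and molecular content
# at division.
#
# Hazard family: a(V) = g * n * (V / V_crit)^n. The sharpness exponent n
# concentrates event volumes near V_crit (large n), and under exponential
# growth V(t) = V0 e^{g t} the cumulative hazard has the closed form
# Lambda(t) = (V0/V_crit)^n (e^{n g t} - 1), which both integrates the
# stationary interdivision time to ln(2)/g and admits exact inverse-CDF
# sampling. Division is gated on completed DNA duplication so no daughter is
# ever born without a chromosome.

#' Volume-dependent DNA-duplication and division hazards
#'
#' `duplication_hazard()` returns \eqn{a_s(V) = g\,n_s (V/V_{s,crit})^{n_s}};
#' `division_hazard()` returns \eqn{a_d(V) = g\,n_d (V/V_{d,crit})^{n_d}} for
#' a cell that has completed DNA duplication and exactly 0 before duplication
#' (division is gated on the duplicated chromosome).
#'
#' @param V cell volume, fL (> 0).
#' @param params a [lac_params()] object (fields `g`, `n_s`, `V_s_crit`,
#'   `n_d`, `V_d_crit`).
#' @param duplicated logical; has the cell duplicated its DNA?
#' @return hazard rate, 1/min.
#' @examples
#' p <- lac_params()
#' duplication_hazard(p$V_s_crit, p)   # g * n_s ~ 0.578 /min at V_s_crit
#' division_hazard(2, p, duplicated = FALSE)  # 0: gated
#' @export
duplication_hazard <- function(V, params) {
  stopifnot(all(V > 0))
  params$g * params$n_s * (V / params$V_s_crit)^params$n_s
}

#' @rdname duplication_hazard
#' @export
division_hazard <- function(V, params, duplicated = TRUE) {
  stopifnot(all(V > 0))
  params$g * params$n_d * (V / params$V_d_crit)^params$n_d *
    as.numeric(duplicated)
}

#' Exact event-time sampling for power-law hazards under exponential growth
#'
#' For a cell of volume `V0` growing as \eqn{V(t) = V_0 e^{g t}}, the waiting
#' time to the next duplication (or division) event with hazard
#' \eqn{a(V) = g n (V/V_c)^n} has cumulative hazard
#' \eqn{\Lambda(t) = (V_0/V_c)^n (e^{n g t} - 1)} and is sampled exactly by
#' inverting \eqn{\Lambda(t) = -\ln u}:
#' \deqn{t = \frac{1}{n g}\ln\!\left(1 - \ln u \,(V_c/V_0)^n\right).}
#'
#' @param V0 volume at the start of the waiting interval, fL.
#' @param hazard_kind `"duplication"` or `"division"`.
#' @param params a [lac_params()] object.
#' @param u uniform(0,1) variate; defaults to a fresh draw from R's RNG.
#' @return waiting time, min.
#' @export
sample_event_time <- function(V0, hazard_kind = c("duplication", "division"),
                              params, u = stats::runif(1)) {
  hazard_kind <- match.arg(hazard_kind)
  stopifnot(V0 > 0, u > 0, u < 1)
  n <- if (hazard_kind == "duplication") params$n_s else params$n_d
  Vc <- if (hazard_kind == "duplication") params$V_s_crit else params$V_d_crit
  log1p(-log(u) * (Vc / V0)^n) / (n * params$g)
}

#' Construct a single-cell state
#'
#' @param x species state vector (copy numbers in stochastic mode, nM
#'   concentrations in deterministic mode), ordered as [species_names()].
#' @param V cell volume, fL.
#' @param duplicated has the chromosome been duplicated? In stochastic mode
#'   this must agree with the operator bookkeeping `O + R2O` (1 chromosome
#'   before duplication, 2 after).
#' @param birth_time cell birth time, min.
#' @param lineage_id identifier of the lineage.
#' @param mode `"stochastic"` (integer copies) or `"deterministic"` (nM).
#' @return object of class `cell_state`.
#' @export
cell_state <- function(x, V, duplicated = FALSE, birth_time = 0,
                       lineage_id = 1L, mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  stopifnot(length(x) == 10, V > 0)
  x <- unname(as.numeric(x))
  if (any(x < 0)) stop("species state must be non-negative")
  if (mode == "stochastic") {
    if (any(x != round(x))) stop("stochastic-mode state must be integer copy numbers")
    n_chrom <- x[4] + x[5]
    if (!(n_chrom %in% c(1, 2))) {
      stop("stochastic-mode state must carry 1 or 2 operator units (O + R2O)")
    }
    if (duplicated != (n_chrom == 2)) {
      stop("duplicated flag must match the operator unit count O + R2O")
    }
  }
  structure(list(x = x, V = V, duplicated = duplicated,
                 birth_time = birth_time, lineage_id = lineage_id,
                 mode = mode),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state (%s)> V = %.4g fL, duplicated = %s, born %.4g min\n",
              x$mode, x$V, x$duplicated, x$birth_time))
  v <- x$x; names(v) <- species_names()
  print(v)
  invisible(x)
}

#' Partition a mother cell into two daughters at division
#'
#' Volume splits by a symmetric Beta(q, q) fraction `f` (so daughters have
#' sizes `f V` and `(1-f) V`, equal in expectation, with coefficient of
#' variation \eqn{1/\sqrt{4(2q+1)}}, about 3.9 percent at q = 80).
#'
#' Stochastic mode: every non-chromosomal species partitions binomially with
#' success probability `f` (so expected daughter concentrations equal the
#' mother's), and the two chromosomal operator units - each carrying its own
#' repression state, free (`O`) or repressor-bound (`R2O`) - are split
#' exactly one per daughter, the assignment drawn hypergeometrically (1 of
#' the 2 units).
#'
#' Deterministic mode: partitioning is a Dirac delta in concentration space -
#' both daughters inherit the mother's concentrations; operator species are
#' recomputed from the integer copy bookkeeping (1 unit per daughter) over
#' each daughter volume, preserving the mother's bound fraction, so that all
#' concentrations are continuous across a symmetric division.
#'
#' Both daughters are born with `duplicated = FALSE`.
#'
#' @param mother a [cell_state()] with duplicated chromosomes.
#' @param params a [lac_params()] object (fields `q`, `R0`).
#' @param f optional fixed volume fraction for daughter 1 in (0, 1)
#'   (overrides the beta draw; used by the forced asymmetric-division
#'   intervention).
#' @param time division time stamped as the daughters' birth time, min.
#' @param bias optional biased-division hook: a pair `c(a, b)` draws the
#'   volume fraction from the symmetric mixture
#'   `0.5 Beta(a, b) + 0.5 Beta(b, a)` instead of `Beta(q, q)`,
#'   modelling consistently unequal division. Off (`NULL`) by default and
#'   not used by any shipped scenario.
#' @return list with `cell_state` daughters `d1`, `d2` and the volume
#'   fraction `f` used.
#' @export
partition_cell <- function(mother, params, f = NULL, time = NULL,
                           bias = NULL) {
  stopifnot(inherits(mother, "cell_state"))
  if (!mother$duplicated) {
    stop("gating violation: division requested before DNA duplication")
  }
  if (is.null(f)) {
    f <- if (is.null(bias)) {
      stats::rbeta(1, params$q, params$q)
    } else {
      stopifnot(length(bias) == 2, all(bias > 0))
      if (stats::runif(1) < 0.5) stats::rbeta(1, bias[1], bias[2])
      else stats::rbeta(1, bias[2], bias[1])
    }
  } else {
    if (!(f > 0 && f < 1)) stop("volume fraction must lie in (0, 1)")
  }
  if (is.null(time)) time <- mother$birth_time
  V1 <- f * mother$V
  V2 <- mother$V - V1
  x <- mother$x
  if (mother$mode == "stochastic") {
    # operator units: 2 chromosomes, each in state O (free) or R2O (bound);
    # exactly one unit per daughter, assignment hypergeometric (1 of 2)
    nO <- x[4]; nR2O <- x[5]
    stopifnot(nO + nR2O == 2)
    o1 <- stats::rhyper(1, m = nO, n = nR2O, k = 1)  # free units to daughter 1
    x1 <- x; x2 <- x
    idx_nonchrom <- c(1:3, 6:10)
    x1[idx_nonchrom] <- stats::rbinom(length(idx_nonchrom),
                                      size = as.integer(x[idx_nonchrom]),
                                      prob = f)
    x2[idx_nonchrom] <- x[idx_nonchrom] - x1[idx_nonchrom]
    x1[4] <- o1;     x1[5] <- 1 - o1
    x2[4] <- nO - o1; x2[5] <- nR2O - (1 - o1)
    d1 <- cell_state(x1, V1, FALSE, time, mother$lineage_id, "stochastic")
    d2 <- cell_state(x2, V2, FALSE, time, mother$lineage_id, "stochastic")
  } else {
    # Dirac-delta partitioning of concentrations; operator species recomputed
    # from 1 integer copy per daughter, preserving the mother's bound fraction
    ot_m <- x[4] + x[5]
    bound_frac <- if (ot_m > 0) x[5] / ot_m else 0
    mk <- function(Vd) {
      xd <- x
      ot_d <- 1 / molecules_per_nM(Vd)   # 1 operator copy in volume Vd, nM
      xd[4] <- (1 - bound_frac) * ot_d
      xd[5] <- bound_frac * ot_d
      xd
    }
    d1 <- cell_state(mk(V1), V1, FALSE, time, mother$lineage_id, "deterministic")
    d2 <- cell_state(mk(V2), V2, FALSE, time, mother$lineage_id, "deterministic")
  }
  list(d1 = d1, d2 = d2, f = f)
}
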
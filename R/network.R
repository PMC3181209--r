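# The artificial lac operon reaction network: 25 elementary reactions with
# stochastic propensity functions (copy-number state) and the matching 10
# mass-action rate equations (concentration state). Both views share one
# stoichiometry; the deterministic rates are the thermodynamic-limit image of
# the propensities.

#' Reaction scheme of the artificial lac operon network
#'
#' Returns the 25 elementary reactions of the switch: constitutive lacI
#' expression and dimerisation, operator repression by the LacI dimer and its
#' two inducer-mediated derepression routes, lacY transcription (free-operator
#' and leak), translation, carrier-mediated inducer uptake through the LacY
#' permease, passive membrane diffusion, and first-order decay of every
#' unstable species. The inducer (TMG) is non-metabolizable, so decay of the
#' inducer-repressor complex returns the inducer to the cytoplasm, and decay
#' of the permease-inducer complex returns it to the (unmodelled, constant)
#' extracellular pool.
#'
#' @return data.frame with columns `index`, `reactants`, `products`,
#'   `rate_constant`, `order` (reaction order descriptor used to build the
#'   propensity: `"zero"`, `"first"`, `"pair"` for 2X -> ..., `"hetero"` for
#'   X + Y -> ..., `"tri_pair"` for 2I + X -> ..., `"influx"`, `"efflux"`,
#'   `"pseudo_first"` for the I_ex-driven permease loading).
#' @export
reaction_table <- function() {
  rx <- list(
    list("0 -> MR",             "k_sMR",  "zero"),
    list("MR -> MR + R",        "k_sR",   "first"),
    list("2R -> R2",            "k_2R",   "pair"),
    list("R2 -> 2R",            "k_m2R",  "first"),
    list("R2 + O -> R2O",       "k_r",    "hetero"),
    list("R2O -> R2 + O",       "k_mr",   "first"),
    list("2I + R2O -> I2R2 + O","k_dr1",  "tri_pair"),
    list("I2R2 + O -> 2I + R2O","k_mdr2", "hetero"),
    list("2I + R2 -> I2R2",     "k_dr2",  "tri_pair"),
    list("I2R2 -> 2I + R2",     "k_mdr1", "first"),
    list("O -> O + MY",         "k_s1MY", "first"),
    list("R2O -> R2O + MY",     "k_s0MY", "first"),
    list("MY -> MY + Y",        "k_sY",   "first"),
    list("Y -> YIex",           "k_p",    "pseudo_first"),
    list("YIex -> Y",           "k_mp",   "first"),
    list("YIex -> Y + I",       "k_ft",   "first"),
    list("0 -> I",              "h_t",    "influx"),
    list("I -> 0",              "h_t",    "efflux"),
    list("MR -> 0",             "lambda_MR",   "first"),
    list("MY -> 0",             "lambda_MY",   "first"),
    list("R -> 0",              "lambda_R",    "first"),
    list("R2 -> 0",             "lambda_R2",   "first"),
    list("Y -> 0",              "lambda_Y",    "first"),
    list("YIex -> 0",           "lambda_YIex", "first"),
    list("I2R2 -> 2I",          "lambda_I2R2", "first")
  )
  eq <- vapply(rx, `[[`, "", 1L)
  sides <- strsplit(eq, " -> ", fixed = TRUE)
  data.frame(
    index = seq_along(rx),
    reactants = vapply(sides, `[[`, "", 1L),
    products = vapply(sides, `[[`, "", 2L),
    rate_constant = vapply(rx, `[[`, "", 2L),
    order = vapply(rx, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

#' Stoichiometry matrix of the lac operon network
#'
#' @return 10 x 25 integer matrix; column j is the state increment of
#'   reaction j of [reaction_table()], rows ordered as [species_names()].
#' @export
stoichiometry_matrix <- function() {
  sp <- species_names()
  S <- matrix(0L, nrow = 10, ncol = 25,
              dimnames = list(sp, paste0("r", 1:25)))
  add <- function(j, ...) {
    d <- c(...)
    S[names(d), j] <<- S[names(d), j] + as.integer(d)
  }
  add(1,  MR = 1)
  add(2,  R = 1)
  add(3,  R = -2, R2 = 1)
  add(4,  R = 2, R2 = -1)
  add(5,  R2 = -1, O = -1, R2O = 1)
  add(6,  R2 = 1, O = 1, R2O = -1)
  add(7,  I = -2, R2O = -1, I2R2 = 1, O = 1)
  add(8,  I = 2, R2O = 1, I2R2 = -1, O = -1)
  add(9,  I = -2, R2 = -1, I2R2 = 1)
  add(10, I = 2, R2 = 1, I2R2 = -1)
  add(11, MY = 1)
  add(12, MY = 1)
  add(13, Y = 1)
  add(14, Y = -1, YIex = 1)
  add(15, Y = 1, YIex = -1)
  add(16, Y = 1, I = 1, YIex = -1)
  add(17, I = 1)
  add(18, I = -1)
  add(19, MR = -1)
  add(20, MY = -1)
  add(21, R = -1)
  add(22, R2 = -1)
  add(23, Y = -1)
  add(24, YIex = -1)
  add(25, I = 2, I2R2 = -1)
  S
}

#' Stochastic propensity functions
#'
#' Evaluates the 25 reaction propensities (units 1/min) for a copy-number
#' state `x` in a cell of volume `V`. With \eqn{\Omega} the copy number of a
#' 1 nM concentration in volume `V` (see [molecules_per_nM()]): zeroth-order
#' reactions have \eqn{a = k\Omega}; first-order \eqn{a = kX}; heterodimeric
#' second-order \eqn{a = (k/\Omega) X_A X_B}; identical-pair second order
#' \eqn{a = (k/\Omega) X (X-1)}; the trimolecular derepression steps
#' \eqn{2I + B} have \eqn{a = (k/\Omega^2) I (I-1) X_B}. Passive transport
#' scales with the membrane area: influx \eqn{h_t (A/V) [I_{ex}] \Omega},
#' efflux \eqn{h_t (A/V) X_I}. Permease loading is pseudo-first-order in the
#' fixed extracellular inducer level, \eqn{a = k_p [I_{ex}] X_Y}.
#'
#' These conventions are chosen so that \eqn{a_j/\Omega} converges to the
#' deterministic mass-action rate (nM/min) of [ode_rhs()] as
#' \eqn{\Omega \to \infty} at fixed concentrations.
#'
#' @param x integer copy-number vector, ordered as [species_names()].
#' @param V cell volume, fL.
#' @param params a [lac_params()] object.
#' @return numeric vector of 25 non-negative propensities (1/min).
#' @export
propensities <- function(x, V, params) {
  stopifnot(length(x) == 10, V > 0)
  if (any(x < 0)) stop("state corruption: negative copy number")
  names(x) <- species_names()
  Om <- molecules_per_nM(V)
  AoV <- area_from_volume(V, params$R0) / V
  p <- params
  a <- c(
    p$k_sMR * Om,
    p$k_sR * x["MR"],
    (p$k_2R / Om) * x["R"] * (x["R"] - 1),
    p$k_m2R * x["R2"],
    (p$k_r / Om) * x["R2"] * x["O"],
    p$k_mr * x["R2O"],
    (p$k_dr1 / Om^2) * x["I"] * (x["I"] - 1) * x["R2O"],
    (p$k_mdr2 / Om) * x["I2R2"] * x["O"],
    (p$k_dr2 / Om^2) * x["I"] * (x["I"] - 1) * x["R2"],
    p$k_mdr1 * x["I2R2"],
    p$k_s1MY * x["O"],
    p$k_s0MY * x["R2O"],
    p$k_sY * x["MY"],
    p$k_p * p$I_ex * x["Y"],
    p$k_mp * x["YIex"],
    p$k_ft * x["YIex"],
    p$ht_um * AoV * p$I_ex * Om,
    p$ht_um * AoV * x["I"],
    p$lambda_MR * x["MR"],
    p$lambda_MY * x["MY"],
    p$lambda_R * x["R"],
    p$lambda_R2 * x["R2"],
    p$lambda_Y * x["Y"],
    p$lambda_YIex * x["YIex"],
    p$lambda_I2R2 * x["I2R2"]
  )
  unname(a)
}

#' Deterministic reaction rate equations
#'
#' Time derivatives (nM/min) of the 10 species concentrations under
#' mass-action kinetics of the 25-reaction scheme, plus a first-order
#' dilution sink \eqn{-\mu [X]} from exponential cell growth. In the
#' structured continuum model the operator-carrying species `O` and `R2O`
#' are exempt from dilution (`operator_dilution = FALSE`) because DNA
#' duplication continuously regenerates the operator; in the per-cell hybrid
#' engine dilution applies to all species and the operator amounts are
#' restored by discrete duplication/division jumps
#' (`operator_dilution = TRUE`).
#'
#' @param conc concentration vector (nM), ordered as [species_names()].
#' @param params a [lac_params()] object.
#' @param A_over_V membrane area per volume, \eqn{\mu m^{-1}}.
#' @param dilution_rate growth dilution rate \eqn{\mu}, 1/min.
#' @param operator_dilution logical; apply dilution to `O` and `R2O`?
#' @return numeric vector of 10 derivatives, nM/min.
#' @export
ode_rhs <- function(conc, params, A_over_V, dilution_rate = params$g,
                    operator_dilution = TRUE) {
  stopifnot(length(conc) == 10, dilution_rate >= 0)
  names(conc) <- species_names()
  cc <- conc; p <- params
  v_dim  <- p$k_2R * cc["R"]^2 - p$k_m2R * cc["R2"]
  v_rep  <- p$k_r * cc["R2"] * cc["O"] - p$k_mr * cc["R2O"]
  v_dr1  <- p$k_dr1 * cc["I"]^2 * cc["R2O"] - p$k_mdr2 * cc["I2R2"] * cc["O"]
  v_dr2  <- p$k_dr2 * cc["I"]^2 * cc["R2"] - p$k_mdr1 * cc["I2R2"]
  v_load <- p$k_p * p$I_ex * cc["Y"] - p$k_mp * cc["YIex"]
  v_ft   <- p$k_ft * cc["YIex"]
  v_pass <- p$ht_um * A_over_V * (p$I_ex - cc["I"])
  mu <- dilution_rate
  mu_op <- if (operator_dilution) mu else 0
  d <- c(
    MR   = p$k_sMR - p$lambda_MR * cc["MR"] - mu * cc["MR"],
    R    = p$k_sR * cc["MR"] - 2 * v_dim - p$lambda_R * cc["R"] - mu * cc["R"],
    R2   = v_dim - v_rep - v_dr2 - p$lambda_R2 * cc["R2"] - mu * cc["R2"],
    O    = -v_rep + v_dr1 - mu_op * cc["O"],
    R2O  = v_rep - v_dr1 - mu_op * cc["R2O"],
    I    = -2 * v_dr1 - 2 * v_dr2 + v_ft + v_pass +
           2 * p$lambda_I2R2 * cc["I2R2"] - mu * cc["I"],
    I2R2 = v_dr1 + v_dr2 - p$lambda_I2R2 * cc["I2R2"] - mu * cc["I2R2"],
    MY   = p$k_s1MY * cc["O"] + p$k_s0MY * cc["R2O"] -
           p$lambda_MY * cc["MY"] - mu * cc["MY"],
    Y    = p$k_sY * cc["MY"] - v_load + v_ft - p$lambda_Y * cc["Y"] -
           mu * cc["Y"],
    YIex = v_load - v_ft - p$lambda_YIex * cc["YIex"] - mu * cc["YIex"]
  )
  names(d) <- species_names()
  d
}
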
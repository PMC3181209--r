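# Parameter handling: kinetic constants of the artificial lac operon network,
# physiological (growth/duplication/division) constants and cell geometry.
# Defaults are the nominal parameter set of the model; rate constants are in
# nM and minutes, volumes in fL (1e-15 L), lengths in um.

.param_defaults <- function() {
  list(
    # transcription / translation / dimerisation
    k_sMR  = 0.23,   # nM/min, constitutive lacI transcription
    k_sR   = 15,     # 1/min, LacI monomer translation
    k_2R   = 50,     # 1/(nM min), LacI dimerisation
    k_m2R  = 1e-3,   # 1/min, dimer dissociation
    # operator (re)pression
    k_r    = 960,    # 1/(nM min), repressor-operator association
    k_mr   = 2.4,    # 1/min, repressor-operator dissociation
    k_dr1  = 3e-7,   # 1/(nM^2 min), inducer strips repressor off operator
    k_mdr1 = 12,     # 1/min, I2R2 -> 2I + R2
    k_dr2  = 3e-7,   # 1/(nM^2 min), inducer sequesters free repressor dimer
    k_mdr2 = 4.8e3,  # 1/(nM min), I2R2 + O -> 2I + R2O
    # lacY expression
    k_s1MY = 0.5,    # 1/min, transcription from free operator
    k_s0MY = 0.01,   # 1/min, leak transcription from repressed operator
    k_sY   = 30,     # 1/min, LacY translation
    # inducer transport
    k_p    = 0.12,   # 1/(nM min), LacY-inducer association (periplasmic side)
    k_mp   = 0.1,    # 1/min, LacY-inducer dissociation
    k_ft   = 6e4,    # 1/min, facilitated translocation YIex -> Y + I
    h_t    = 1.55e-6, # dm/min, passive membrane permeability (as tabulated)
    # first-order decay
    lambda_MR   = 0.462,
    lambda_MY   = 0.462,
    lambda_R    = 0.2,
    lambda_R2   = 0.2,
    lambda_Y    = 0.2,
    lambda_YIex = 0.2,
    lambda_I2R2 = 0.2,
    # environment
    I_ex = 0,        # nM, extracellular TMG (reservoir, not a dynamic species)
    O_T_per_chromosome = 1,  # operator copies per chromosome
    # physiology: growth, DNA duplication, division, partitioning
    g        = 0.0231,  # 1/min, specific growth rate (doubling time ln2/g ~ 30 min)
    n_d      = 25,      # division hazard sharpness exponent
    V_d_crit = 1.5,     # fL, critical volume for division
    q        = 80,      # symmetric beta sharpness for volume partitioning
    n_s      = 25,      # DNA duplication hazard sharpness exponent
    V_s_crit = 1.0,     # fL, critical volume for DNA duplication
    # geometry
    R0 = 0.4            # um, cell radius
  )
}

# aliases accepted in parameter files / override lists (tabulated symbols)
.param_aliases <- c(
  "k_-2R" = "k_m2R", "k_-r" = "k_mr", "k_-dr1" = "k_mdr1",
  "k_-dr2" = "k_mdr2", "k_-p" = "k_mp",
  "λ_MR" = "lambda_MR", "λ_MY" = "lambda_MY",
  "λ_R" = "lambda_R", "λ_R2" = "lambda_R2",
  "λ_Y" = "lambda_Y", "λ_YIex" = "lambda_YIex",
  "λ_I2R2" = "lambda_I2R2",
  "R_0" = "R0", "V_d,crit" = "V_d_crit", "V_s,crit" = "V_s_crit"
)

.canonical_names <- function(nm) {
  hit <- match(nm, names(.param_aliases))
  nm[!is.na(hit)] <- .param_aliases[hit[!is.na(hit)]]
  nm
}

#' Model parameters for the artificial lac operon simulators
#'
#' Builds the full parameter set used by every engine in the package:
#' the kinetic constants of the 25-reaction lac operon scheme, the
#' physiological constants governing exponential growth, DNA duplication,
#' division and partitioning, and the cell geometry. Defaults are the
#' nominal parameter set; any subset can be overridden by name.
#' Reverse-rate symbols may be written either ASCII-safe (`k_m2R`) or as
#' tabulated (`` `k_-2R` ``); decay constants either `lambda_MY` or
#' `λ_MY`. Unknown names are rejected.
#'
#' Units: rate constants in nM and minutes; `h_t` in dm/min as tabulated
#' (converted internally to \eqn{\mu m}/min once, field `ht_um`);
#' `I_ex` in nM; volumes in fL; `R0` in \eqn{\mu m}.
#'
#' @param ... named parameter overrides (see Details in the package vignette).
#' @param file optional path to a YAML/flat key-value parameter file whose
#'   entries are applied before the `...` overrides.
#' @return an object of class `lac_params`: a named list of parameters with
#'   derived fields `ht_um` (permeability in \eqn{\mu m}/min) and
#'   `doubling_time` (\eqn{\ln 2 / g}, min).
#' @examples
#' p <- lac_params(I_ex = 24e3)  # 24 uM extracellular TMG
#' p$doubling_time               # ~30 min
#' @export
lac_params <- function(..., file = NULL) {
  p <- .param_defaults()
  ov <- list(...)
  if (!is.null(file)) ov <- c(read_param_file(file), ov)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == "")) {
      stop("all parameter overrides must be named")
    }
    names(ov) <- .canonical_names(names(ov))
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    for (nm in names(ov)) {
      v <- ov[[nm]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
        stop("parameter '", nm, "' must be a single finite number")
      }
      p[[nm]] <- as.numeric(v)
    }
  }
  validate_lac_params(p)
  p$ht_um <- p$h_t * 1e5          # 1 dm = 1e5 um
  p$doubling_time <- log(2) / p$g
  class(p) <- "lac_params"
  p
}

validate_lac_params <- function(p) {
  rate_names <- setdiff(names(.param_defaults()),
                        c("g", "n_d", "V_d_crit", "q", "n_s", "V_s_crit", "R0"))
  for (nm in rate_names) {
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be non-negative")
  }
  if (p$g <= 0) stop("growth rate g must be positive")
  if (p$n_d < 1 || p$n_s < 1) stop("sharpness exponents n_d, n_s must be >= 1")
  if (p$q <= 0) stop("beta sharpness q must be positive")
  if (!(p$V_s_crit > 0 && p$V_d_crit > p$V_s_crit)) {
    stop("critical volumes must satisfy 0 < V_s_crit < V_d_crit")
  }
  if (p$R0 <= 0) stop("cell radius R0 must be positive")
  if (p$O_T_per_chromosome != 1) {
    stop("only one operator per chromosome is supported")
  }
  invisible(p)
}

#' Read a flat parameter file
#'
#' Accepts a YAML mapping (or the equivalent flat `key: value` text file)
#' whose keys are parameter symbols, e.g. `k_sMR`, `` k_-2R ``,
#' `λ_I2R2`, `g`, `V_d_crit`. Unknown keys are rejected by
#' [lac_params()].
#'
#' @param file path to the parameter file.
#' @return named list of numeric values (not yet validated).
#' @export
read_param_file <- function(file) {
  vals <- yaml::read_yaml(file)
  if (!is.list(vals)) stop("parameter file must be a key-value mapping")
  vals
}

#' @export
print.lac_params <- function(x, ...) {
  cat("Artificial lac operon model parameters\n")
  cat(sprintf("  I_ex = %g nM,  growth g = %g /min (doubling %.2f min)\n",
              x$I_ex, x$g, x$doubling_time))
  cat(sprintf("  duplication: n_s = %g at V_s_crit = %g fL;  division: n_d = %g at V_d_crit = %g fL;  beta q = %g\n",
              x$n_s, x$V_s_crit, x$n_d, x$V_d_crit, x$q))
  cat(sprintf("  geometry: R0 = %g um\n", x$R0))
  kin <- setdiff(names(unclass(x)),
                 c("I_ex", "g", "n_s", "V_s_crit", "n_d", "V_d_crit", "q",
                   "R0", "ht_um", "doubling_time"))
  cat("  kinetic constants: ", paste0(kin, collapse = ", "), "\n")
  invisible(x)
}

# fixed parameter-vector layout shared with the C/C++ kernels
.PV_NAMES <- c("k_sMR", "k_sR", "k_2R", "k_m2R", "k_r", "k_mr",
               "k_dr1", "k_mdr1", "k_dr2", "k_mdr2",
               "k_s1MY", "k_s0MY", "k_sY", "k_p", "k_mp", "k_ft",
               "ht_um", "lambda_MR", "lambda_MY", "lambda_R", "lambda_R2",
               "lambda_Y", "lambda_YIex", "lambda_I2R2",
               "I_ex", "g", "n_d", "V_d_crit", "q", "n_s", "V_s_crit", "R0")

.param_vector <- function(p) {
  stopifnot(inherits(p, "lac_params"))
  vapply(.PV_NAMES, function(nm) p[[nm]], numeric(1))
}

#' Species names of the lac operon state vector
#'
#' Fixed ordering used by every engine: lacI mRNA (`MR`), LacI monomer (`R`)
#' and dimer (`R2`), free (`O`) and repressed (`R2O`) operator, intracellular
#' inducer (`I`), inducer-repressor complex (`I2R2`), lacY mRNA (`MY`), LacY
#' permease (`Y`) and permease-inducer complex (`YIex`).
#'
#' @return character vector of length 10.
#' @export
species_names <- function() {
  c("MR", "R", "R2", "O", "R2O", "I", "I2R2", "MY", "Y", "YIex")
}
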
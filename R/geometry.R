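#' Rod-shaped cell geometry
#'
#' An *E. coli* cell is modelled as a cylinder of radius `R0` with two
#' hemispherical caps, so a cell of overall length `L` has volume
#' \deqn{V = \pi R_0^2 (L - 2R_0) + \tfrac{4}{3}\pi R_0^3}
#' and, inverting for the membrane area at given volume,
#' \deqn{A(V) = \frac{2}{R_0}\left(V - \tfrac{4}{3}\pi R_0^3\right) + 4\pi R_0^2.}
#' The radius is treated as constant through the cell cycle (its observed
#' change is below ~8 percent per cycle); all growth is elongation.
#' Volumes are in fL (1 fL = 1 \eqn{\mu m^3}), lengths in \eqn{\mu m},
#' areas in \eqn{\mu m^2}.
#'
#' @param L cell length, \eqn{\mu m}; must satisfy `L >= 2 * R0`.
#' @param V cell volume, fL; must be at least the volume of the all-caps
#'   sphere, \eqn{(4/3)\pi R_0^3}.
#' @param R0 cell radius, \eqn{\mu m}.
#' @return `volume_from_length()`: volume in fL. `area_from_volume()`:
#'   membrane area in \eqn{\mu m^2}.
#' @examples
#' volume_from_length(2.3, 0.4)  # ~1.0 fL, a representative E. coli
#' area_from_volume(volume_from_length(2.3, 0.4), 0.4)  # ~5.8 um^2
#' @export
volume_from_length <- function(L, R0) {
  stopifnot(is.numeric(L), is.numeric(R0), R0 > 0)
  if (any(L < 2 * R0)) {
    stop("invalid geometry: length L must be at least 2*R0 (sphere limit)")
  }
  pi * R0^2 * (L - 2 * R0) + (4 / 3) * pi * R0^3
}

#' @rdname volume_from_length
#' @export
area_from_volume <- function(V, R0) {
  stopifnot(is.numeric(V), is.numeric(R0), R0 > 0)
  vmin <- (4 / 3) * pi * R0^3
  if (any(V < vmin - 1e-12)) {
    stop("invalid geometry: volume below the all-caps sphere minimum (4/3)*pi*R0^3")
  }
  (2 / R0) * (V - vmin) + 4 * pi * R0^2
}

#' Avogadro's number (molecules per mole)
#' @keywords internal
.N_AVOGADRO <- 6.02214076e23

#' Copy-number scale of a 1 nM concentration
#'
#' Returns \eqn{\Omega}, the number of molecules that corresponds to a 1 nM
#' concentration in a cell of volume `V` fL:
#' \eqn{\Omega = N_A \cdot V \cdot 10^{-15}\,\mathrm{L} \cdot 10^{-9}\,\mathrm{mol/L}}.
#' Conversely one molecule in volume `V` is a concentration of \eqn{1/\Omega} nM.
#' Used to convert between the copy-number state of the stochastic engine and
#' the nM units of the rate constants.
#'
#' @param V cell volume, fL (> 0).
#' @return dimensionless scale \eqn{\Omega} (molecules per nM).
#' @examples
#' molecules_per_nM(1)      # ~0.602: one molecule in 1 fL is ~1.66 nM
#' 1 / molecules_per_nM(1)  # nM concentration of a single molecule
#' @export
molecules_per_nM <- function(V) {
  stopifnot(is.numeric(V), all(V > 0))
  .N_AVOGADRO * V * 1e-15 * 1e-9
}
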
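# Polymer elasticity of dsDNA and ssDNA, plus bead-fluctuation force
# calibration. All lengths in nm, forces in pN, energies in pN*nm.

#' Boltzmann constant in pN nm / K
#' @noRd
.kB <- 0.0138065

#' Thermal energy context
#'
#' @param temperature absolute temperature in Kelvin.
#' @return An object of class `thermal_context` with field `kBT` (pN nm).
#' @examples
#' thermal_context(296)$kBT  # ~4.09 pN nm at room temperature
#' @export
thermal_context <- function(temperature = 296) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  structure(list(temperature = temperature, kBT = .kB * temperature),
            class = "thermal_context")
}

#' Elastic parameters of double-stranded DNA
#'
#' Parameters of the extensible worm-like chain used to convert bead-height
#' changes into base pairs at a given force.
#'
#' @param persistence_length WLC persistence length in nm.
#' @param contour_rise crystallographic rise per base pair in nm/bp
#'   (must not exceed 0.4 nm/bp).
#' @param stretch_modulus enthalpic stretch modulus in pN.
#' @param temperature absolute temperature in K.
#' @return An object of class `duplex_elasticity`.
#' @export
duplex_elasticity <- function(persistence_length = 50,
                              contour_rise = 0.34,
                              stretch_modulus = 1000,
                              temperature = 296) {
  vals <- c(persistence_length, contour_rise, stretch_modulus, temperature)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all duplex elasticity parameters must be finite and strictly positive")
  if (contour_rise > 0.4)
    stop("contour_rise must be <= 0.4 nm/bp")
  structure(list(persistence_length = persistence_length,
                 contour_rise = contour_rise,
                 stretch_modulus = stretch_modulus,
                 temperature = temperature),
            class = "duplex_elasticity")
}

#' Elastic parameters of single-stranded DNA (freely-jointed chain)
#'
#' Defaults place the ssDNA/dsDNA extension-per-residue crossover at
#' ~5.9 pN, so that ssDNA is longer than duplex above ~6 pN and shorter
#' below ~5 pN, the regime boundary relevant to canonical unwinding
#' geometries.
#'
#' @param kuhn_length Kuhn segment length in nm.
#' @param contour_per_nt contour length per nucleotide in nm/nt.
#' @return An object of class `ssdna_elasticity`.
#' @export
ssdna_elasticity <- function(kuhn_length = 1.5, contour_per_nt = 0.57) {
  vals <- c(kuhn_length, contour_per_nt)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("ssDNA elasticity parameters must be finite and strictly positive")
  structure(list(kuhn_length = kuhn_length, contour_per_nt = contour_per_nt),
            class = "ssdna_elasticity")
}

.check_force <- function(force) {
  if (!is.numeric(force) || any(!is.finite(force)) || any(force < 0))
    stop("force must be finite and non-negative (pN)")
}

#' Fractional extension of dsDNA under force (extensible Marko-Siggia)
#'
#' Solves the extensible Marko-Siggia interpolation
#' \deqn{F = (k_BT/P)\,[1/(4(1-x/L_c+F/S)^2) - 1/4 + x/L_c - F/S]}
#' for the fractional extension x/Lc by bracketed root finding.
#'
#' @param force applied force in pN (scalar or vector, >= 0).
#' @param e a [duplex_elasticity()] object.
#' @return fractional extension x/Lc, dimensionless, in [0, 1.05].
#' @export
duplex_fractional_extension <- function(force, e = duplex_elasticity()) {
  .check_force(force)
  stopifnot(inherits(e, "duplex_elasticity"))
  kBT <- .kB * e$temperature
  P <- e$persistence_length
  S <- e$stretch_modulus
  vapply(force, function(f) {
    if (f == 0) return(0)
    # substitute u = x/Lc - F/S: classic Marko-Siggia in u, monotone on [0,1)
    g <- function(u) (kBT / P) * (1 / (4 * (1 - u)^2) - 0.25 + u) - f
    lo <- 0; hi <- 1 - 1e-12
    if (g(lo) > 0 || g(hi) < 0)
      stop("failed to bracket the Marko-Siggia root at force ", f, " pN")
    u <- stats::uniroot(g, c(lo, hi), tol = 1e-9)$root
    frac <- u + f / S
    if (frac < 0 || frac > 1.05)
      stop("fractional extension ", frac, " outside [0, 1.05]; ",
           "check elasticity parameters")
    frac
  }, numeric(1))
}

#' Rise per base pair of dsDNA at a given force
#'
#' The single bp <-> nm conversion constant used throughout the trace
#' analysis: contour rise scaled by the WLC fractional extension.
#'
#' @inheritParams duplex_fractional_extension
#' @return extension per base pair in nm/bp.
#' @export
duplex_rise_per_bp <- function(force, e = duplex_elasticity()) {
  e$contour_rise * duplex_fractional_extension(force, e)
}

#' Extension per nucleotide of ssDNA under force (freely-jointed chain)
#'
#' FJC expression `contour_per_nt * (coth(F b / kBT) - kBT / (F b))` with
#' Kuhn length b. Monotone increasing in force; 0 at zero force;
#' approaches `contour_per_nt` at high force.
#'
#' @param force applied force in pN (>= 0).
#' @param e an [ssdna_elasticity()] object.
#' @param t a [thermal_context()].
#' @return extension per nucleotide in nm/nt.
#' @export
ssdna_extension_per_nt <- function(force, e = ssdna_elasticity(),
                                   t = thermal_context()) {
  .check_force(force)
  stopifnot(inherits(e, "ssdna_elasticity"), inherits(t, "thermal_context"))
  x <- force * e$kuhn_length / t$kBT
  out <- ifelse(x == 0, 0, e$contour_per_nt * (1 / tanh(x) - 1 / x))
  unname(out)
}

#' Force from lateral bead fluctuations (equipartition estimator)
#'
#' Brownian-motion force calibration of a tethered bead:
#' \deqn{F = k_BT \cdot \langle z \rangle / \langle \delta x^2 \rangle}
#'
#' @param lateral_variance variance of the lateral bead coordinate in nm^2.
#' @param tether_extension mean tether extension in nm.
#' @param t a [thermal_context()].
#' @return estimated force in pN.
#' @examples
#' force_from_fluctuations(1092, 2130, thermal_context(296))  # ~8 pN
#' @export
force_from_fluctuations <- function(lateral_variance, tether_extension,
                                    t = thermal_context()) {
  stopifnot(inherits(t, "thermal_context"))
  if (!is.numeric(lateral_variance) || !is.finite(lateral_variance) ||
      lateral_variance <= 0)
    stop("lateral_variance must be strictly positive (zero variance implies infinite force)")
  if (!is.numeric(tether_extension) || !is.finite(tether_extension) ||
      tether_extension <= 0)
    stop("tether_extension must be strictly positive")
  t$kBT * tether_extension / lateral_variance
}

#' Simulate lateral bead fluctuations at a known force
#'
#' Generates independent Gaussian lateral displacements with the
#' equipartition variance kBT * extension / force, for validating the
#' force calibration.
#'
#' @param force applied force in pN (> 0).
#' @param extension tether extension in nm.
#' @param duration length of the record in s.
#' @param sampling_rate camera rate in Hz.
#' @param t a [thermal_context()].
#' @param seed integer seed.
#' @return numeric vector of lateral positions in nm.
#' @export
simulate_bead_fluctuations <- function(force, extension, duration = 60,
                                       sampling_rate = 60,
                                       t = thermal_context(), seed = 1L) {
  .check_force(force)
  stopifnot(force > 0, extension > 0, duration > 0)
  set.seed(as.integer(seed))
  n <- floor(duration * sampling_rate)
  stats::rnorm(n, 0, sqrt(t$kBT * extension / force))
}
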
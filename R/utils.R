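## Physical constants (kJ/mol, nm, ps, Da, e units).

.kB <- 0.008314462618      # kJ/mol/K
.coulomb <- 138.935458     # kJ nm / mol / e^2 (1/(4 pi eps0) in these units)
.avogadro <- 6.02214076e23

#' Evaluate an expression under a private RNG stream
#'
#' Seeds R's RNG with \code{seed}, runs \code{expr}, and restores the
#' caller's RNG state afterwards, so generators never leak global RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Temperature-dependent dielectric constant of water
#'
#' Empirical polynomial fit to the static dielectric constant of liquid
#' water; about 78.4 at 298.15 K.
#'
#' @param temperature temperature in K.
#' @return dimensionless relative permittivity.
#' @export
waterDielectric <- function(temperature) {
  T <- temperature
  5321 / T + 233.76 - 0.9297 * T + 1.417e-3 * T^2 - 8.292e-7 * T^3
}

#' Inverse Debye screening length
#'
#' Computes kappa (nm^-1) for a 1:1 electrolyte of the given ionic strength
#' at the given temperature, using the Bjerrum length in water (or a fixed
#' dielectric when supplied).
#'
#' @param ionicStrength ionic strength in M (mol/L), >= 0.
#' @param temperature temperature in K.
#' @param dielectric optional fixed relative permittivity; default is the
#'   temperature-dependent water value.
#' @return kappa in nm^-1.
#' @export
debyeKappa <- function(ionicStrength, temperature = 298.15,
                       dielectric = NULL) {
  if (ionicStrength < 0) stop("ionic strength must be non-negative")
  epsr <- if (is.null(dielectric)) waterDielectric(temperature) else dielectric
  kT <- .kB * temperature
  lB <- .coulomb / (epsr * kT)              # Bjerrum length, nm
  nIon <- ionicStrength * .avogadro * 1e-24 # number density, nm^-3 per M
  sqrt(8 * pi * lB * nIon)
}

## Squared Euclidean distances from one point to rows of a matrix.
.distToPoint <- function(coords, point) {
  sqrt(colSums((t(coords) - point)^2))
}

.rowNorms <- function(m) sqrt(rowSums(m * m))

## Mass-weighted center of mass of a coordinate block.
.centerOfMass <- function(coords, masses) {
  colSums(coords * masses) / sum(masses)
}

.newTrajectory <- function(coords, times, dt, replica = 1L,
                           velocities = NULL) {
  new("Trajectory", coords = coords, times = as.numeric(times),
      dt = as.numeric(dt), replica = as.integer(replica),
      velocities = velocities)
}
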
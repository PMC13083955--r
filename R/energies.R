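#' Hydropathy-scaled short-range pair energy (Ashbaugh-Hatch form)
#'
#' With \eqn{L(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}, returns
#' \eqn{L(r) + (1-\lambda)\epsilon} for \eqn{r \le 2^{1/6}\sigma} and
#' \eqn{\lambda L(r)} beyond, truncated to zero past the short-range
#' cutoff.  Both branches evaluate to \eqn{-\lambda\epsilon} at the
#' potential minimum \eqn{r = 2^{1/6}\sigma}, so the function is continuous
#' there for every parameter combination.
#'
#' @param r pair distance (nm), > 0; vectorized.
#' @param sigma pair size parameter (nm).
#' @param lambda pair stickiness in [0, 1].
#' @param epsilon energy scale (kJ/mol); default 0.8368 (0.2 kcal/mol).
#' @param cutoff short-range cutoff (nm); default 2.0.
#' @return energy in kJ/mol (vectorized over \code{r}).
#' @examples
#' ahEnergy(2^(1/6) * 0.6, sigma = 0.6, lambda = 0.5)  # -0.5 * 0.8368
#' @export
ahEnergy <- function(r, sigma, lambda, epsilon = 0.8368, cutoff = 2.0) {
  if (any(r <= 0)) stop("pair distance r must be positive")
  sr6 <- (sigma / r)^6
  lj <- 4 * epsilon * (sr6^2 - sr6)
  rmin <- 2^(1 / 6) * sigma
  e <- ifelse(r <= rmin, lj + (1 - lambda) * epsilon, lambda * lj)
  e[r > cutoff] <- 0
  e
}

#' Debye-Hueckel screened electrostatic pair energy
#'
#' Returns \eqn{B(\epsilon_r) q_i q_j \exp(-\kappa r)/r} with the Coulomb
#' constant \eqn{B = 138.935/\epsilon_r} kJ nm/mol/e^2, the inverse Debye
#' length \eqn{\kappa} computed from the ionic strength and temperature,
#' and \eqn{\epsilon_r} from the temperature-dependent water dielectric
#' unless a fixed value is supplied.  Zero beyond the electrostatic cutoff.
#'
#' @param r pair distance (nm), > 0; vectorized.
#' @param qi,qj charges (elementary charges).
#' @param ionicStrength ionic strength (M), >= 0.
#' @param temperature temperature (K).
#' @param dielectric optional fixed relative permittivity.
#' @param cutoff electrostatic cutoff (nm); default 4.0.
#' @return energy in kJ/mol (vectorized over \code{r}).
#' @examples
#' dhEnergy(1, 1, 1, ionicStrength = 0, dielectric = 80)  # 138.935/80
#' @export
dhEnergy <- function(r, qi, qj, ionicStrength = 0.22, temperature = 298.15,
                     dielectric = NULL, cutoff = 4.0) {
  if (any(r <= 0)) stop("pair distance r must be positive")
  if (ionicStrength < 0) stop("ionic strength must be non-negative")
  epsr <- if (is.null(dielectric)) waterDielectric(temperature) else dielectric
  kappa <- debyeKappa(ionicStrength, temperature, dielectric = epsr)
  e <- .coulomb / epsr * qi * qj * exp(-kappa * r) / r
  e[r > cutoff] <- 0
  e
}
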
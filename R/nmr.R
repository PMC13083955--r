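#' Create a peak list
#'
#' Per-residue 2D amide peak positions and intensities.  Peak
#' disappearance is an explicit absent state (row missing or
#' \code{present = FALSE}), never a zero intensity.
#'
#' @param residue integer residue indices (unique).
#' @param H proton chemical shifts (ppm).
#' @param N nitrogen chemical shifts (ppm).
#' @param intensity peak intensities (>= 0); default 1.
#' @param present logical presence flags; default TRUE.
#' @return a data.frame of class \code{peakList}.
#' @export
peakList <- function(residue, H, N, intensity = rep(1, length(residue)),
                     present = rep(TRUE, length(residue))) {
  if (anyDuplicated(residue)) stop("residue indices must be unique")
  if (any(intensity[present] < 0))
    stop("intensities must be non-negative where present")
  out <- data.frame(residue = as.integer(residue), H = H, N = N,
                    intensity = intensity, present = present)
  class(out) <- c("peakList", "data.frame")
  out
}

#' Chemical-shift perturbation between two peak lists
#'
#' Weighted combined amide shift difference
#' \eqn{\Delta\delta = \sqrt{(\Delta\delta_H)^2 +
#' (\Delta\delta_N / w)^2}} with nitrogen weight \eqn{w} (default 5).
#' Residues present in only one list are returned with \code{NA} and
#' flagged absent.
#'
#' @param reference,perturbed peak lists (see \code{\link{peakList}}).
#' @param nitrogenWeight nitrogen scaling divisor; default 5.
#' @return data.frame with columns \code{residue}, \code{csp} (ppm),
#'   \code{absent}.
#' @export
csp <- function(reference, perturbed, nitrogenWeight = 5) {
  allRes <- sort(union(reference$residue, perturbed$residue))
  refPresent <- reference$residue[reference$present]
  perPresent <- perturbed$residue[perturbed$present]
  shared <- intersect(refPresent, perPresent)
  if (!length(shared))
    stop("no residues shared between the two peak lists")
  out <- data.frame(residue = allRes, csp = NA_real_,
                    absent = !(allRes %in% shared))
  iR <- match(shared, reference$residue)
  iP <- match(shared, perturbed$residue)
  dH <- perturbed$H[iP] - reference$H[iR]
  dN <- perturbed$N[iP] - reference$N[iR]
  out$csp[match(shared, allRes)] <- sqrt(dH^2 + (dN / nitrogenWeight)^2)
  out
}

#' Concentration-normalized intensity ratios
#'
#' Per-residue I/I0 between a test and a reference peak list; when
#' \code{normalize} is on, each intensity is first divided by its sample
#' concentration so lists recorded at different concentrations compare
#' fairly.  Residues with no observable test peak are flagged absent (not
#' zero); zero reference intensities are flagged per residue.
#'
#' @param reference reference peak list, at concentration \code{c0}.
#' @param test test peak list, at concentration \code{conc}.
#' @param c0,conc sample concentrations (same units, > 0).
#' @param normalize divide intensities by concentration; default TRUE.
#' @return data.frame with columns \code{residue}, \code{ratio},
#'   \code{absent}, \code{zeroReference}.
#' @export
intensityRatio <- function(reference, test, c0 = 1, conc = 1,
                           normalize = TRUE) {
  if (c0 <= 0 || conc <= 0) stop("concentrations must be positive")
  allRes <- sort(reference$residue[reference$present])
  out <- data.frame(residue = allRes, ratio = NA_real_,
                    absent = TRUE, zeroReference = FALSE)
  iR <- match(allRes, reference$residue)
  iT <- match(allRes, test$residue)
  hasTest <- !is.na(iT) & test$present[pmax(iT, 1)] & !is.na(iT)
  hasTest[is.na(hasTest)] <- FALSE
  out$absent <- !hasTest
  refI <- reference$intensity[iR]
  testI <- ifelse(hasTest, test$intensity[iT], NA_real_)
  if (normalize) {
    refI <- refI / c0
    testI <- testI / conc
  }
  zero <- hasTest & refI == 0
  out$zeroReference <- zero
  ok <- hasTest & !zero
  out$ratio[ok] <- testI[ok] / refI[ok]
  out
}

#' Secondary chemical shifts from Calpha/Cbeta assignments
#'
#' \eqn{\Delta\delta(C_\alpha - C_\beta) = (\delta C_{\alpha,obs} -
#' \delta C_{\alpha,rc}) - (\delta C_{\beta,obs} - \delta C_{\beta,rc})}
#' per residue; positive values indicate alpha-helical and negative values
#' beta-strand propensity.  Residues lacking a Cbeta observation (glycine)
#' are computed from the Calpha term alone and flagged.
#'
#' @param assignments data.frame with columns \code{residue},
#'   \code{caObs}, \code{cbObs}, \code{caRc}, \code{cbRc}; \code{cbObs}
#'   and \code{cbRc} may be NA (glycine).
#' @return data.frame with columns \code{residue}, \code{secondaryShift}
#'   (ppm), \code{caOnly}, \code{missingRandomCoil}.
#' @export
secondaryShift <- function(assignments) {
  a <- as.data.frame(assignments)
  need <- c("residue", "caObs", "cbObs", "caRc", "cbRc")
  if (!all(need %in% names(a)))
    stop("assignments must have columns ", paste(need, collapse = ", "))
  missRc <- is.na(a$caRc) | (!is.na(a$cbObs) & is.na(a$cbRc))
  caOnly <- is.na(a$cbObs) & !missRc
  val <- (a$caObs - a$caRc) - ifelse(is.na(a$cbObs), 0, a$cbObs - a$cbRc)
  val[missRc] <- NA_real_
  data.frame(residue = a$residue, secondaryShift = val,
             caOnly = caOnly, missingRandomCoil = missRc)
}

#' Create a relaxation series
#'
#' @param delays relaxation delays (s); duplicates are kept as independent
#'   observations.
#' @param intensities peak heights.
#' @param noise spectral noise estimate (for Monte Carlo errors).
#' @return a \code{\link{RelaxationSeries}}.
#' @export
relaxationSeries <- function(delays, intensities, noise = 0) {
  new("RelaxationSeries", delays = as.numeric(delays),
      intensities = as.numeric(intensities), noise = noise)
}

#' Fit a mono-exponential relaxation decay
#'
#' Untransformed non-linear least squares fit of
#' \eqn{I(t) = I_0 e^{-R t}} (so noise stays additive), with the starting
#' guess from a two-point log slope.  The rate uncertainty is the standard
#' deviation of rates refit on \code{mcTrials} replicas of the data
#' perturbed with Gaussian noise at the stored spectral noise level.
#'
#' @param series a \code{\link{RelaxationSeries}}.
#' @param mcTrials Monte Carlo trials for the rate SD; default 500.
#' @param seed integer seed for the Monte Carlo noise stream.
#' @return list with \code{rate} (s^-1), \code{amplitude}, \code{rateSD}
#'   (0 when the stored noise is 0), \code{converged}.
#' @export
fitMonoexponential <- function(series, mcTrials = 500, seed = 1) {
  stopifnot(is(series, "RelaxationSeries"))
  t <- series@delays; I <- series@intensities
  if (I[which.min(t)] <= 0)
    stop("intensity at the smallest delay must be positive")

  fitOnce <- function(y) {
    ## two-point log-slope initial guess on the positive extremes
    ord <- order(t)
    pos <- ord[y[ord] > 0]
    if (length(pos) >= 2) {
      i1 <- pos[1]; i2 <- pos[length(pos)]
      r0 <- (log(y[i1]) - log(y[i2])) / (t[i2] - t[i1])
    } else r0 <- 1
    if (!is.finite(r0) || r0 <= 0) r0 <- 1 / max(t)
    a0 <- y[which.min(t)] * exp(r0 * min(t))
    df <- data.frame(t = t, y = y)
    fit <- tryCatch(
      stats::nls(y ~ a * exp(-r * t), data = df,
                 start = list(a = a0, r = r0),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(-r * t), data = df,
                          start = list(a = a0, r = r0),
                          control = minpack.lm::nls.lm.control(
                            maxiter = 200)),
        error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    stats::coef(fit)
  }

  cf <- fitOnce(I)
  if (is.null(cf))
    return(list(rate = NA_real_, amplitude = NA_real_, rateSD = NA_real_,
                converged = FALSE))

  rateSD <- 0
  if (series@noise > 0 && mcTrials > 0) {
    rates <- withSeed(seed, {
      vapply(seq_len(mcTrials), function(k) {
        yk <- I + stats::rnorm(length(I), 0, series@noise)
        ck <- fitOnce(yk)
        if (is.null(ck)) NA_real_ else ck[["r"]]
      }, numeric(1))
    })
    rateSD <- stats::sd(rates, na.rm = TRUE)
  }
  list(rate = as.numeric(cf[["r"]]), amplitude = as.numeric(cf[["a"]]),
       rateSD = rateSD, converged = TRUE)
}

#' Steady-state heteronuclear NOE with propagated uncertainty
#'
#' Per-residue ratio of saturated to reference peak heights,
#' \eqn{I_{sat}/I_{ref}}, with the propagated error
#' \eqn{|value| \sqrt{(\sigma_{sat}/I_{sat})^2 +
#' (\sigma_{ref}/I_{ref})^2}} from the two spectral noise levels.
#'
#' @param saturated,reference peak lists (see \code{\link{peakList}}).
#' @param noiseSat,noiseRef spectral noise of the two experiments.
#' @return data.frame with columns \code{residue}, \code{noe},
#'   \code{error}, \code{zeroReference}.
#' @export
hetNOE <- function(saturated, reference, noiseSat = 0, noiseRef = 0) {
  shared <- intersect(saturated$residue[saturated$present],
                      reference$residue[reference$present])
  if (!length(shared)) stop("no residues shared between the experiments")
  iS <- match(shared, saturated$residue)
  iR <- match(shared, reference$residue)
  Isat <- saturated$intensity[iS]
  Iref <- reference$intensity[iR]
  zero <- Iref == 0
  value <- ifelse(zero, NA_real_, Isat / Iref)
  err <- ifelse(zero | Isat == 0,
                ifelse(zero, NA_real_,
                       abs(noiseSat / Iref)),  # value 0: only sat term
                abs(value) * sqrt((noiseSat / Isat)^2 +
                                  (noiseRef / Iref)^2))
  data.frame(residue = shared, noe = value, error = err,
             zeroReference = zero)
}
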
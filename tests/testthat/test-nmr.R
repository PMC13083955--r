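test_that("chemical-shift perturbations follow the weighted combination", {
  ref <- peakList(1:4, H = c(8.0, 8.1, 8.2, 8.3),
                  N = c(115, 118, 121, 124))
  per <- peakList(1:4, H = c(8.0, 8.1, 8.3, 8.3),
                  N = c(115, 119, 121, 124.5))
  out <- csp(ref, per)
  expect_equal(out$csp[1], 0)
  expect_equal(out$csp[2], 0.2)                  # N-only: 1/5
  expect_equal(out$csp[3], 0.1)                  # H-only
  expect_equal(out$csp[4], 0.1)                  # 0.5 ppm N / 5
  ## equal contributions add in quadrature: sqrt(2) * 0.1
  per2 <- peakList(1, H = 8.1, N = 115.5)
  expect_equal(csp(peakList(1, H = 8.0, N = 115), per2)$csp,
               sqrt(0.1^2 + 0.1^2))
})

test_that("CSP is symmetric under swapping the two peak lists", {
  set.seed(8)
  ref <- peakList(1:10, H = rnorm(10, 8), N = rnorm(10, 118))
  per <- peakList(1:10, H = rnorm(10, 8), N = rnorm(10, 118))
  expect_equal(csp(ref, per)$csp, csp(per, ref)$csp)
})

test_that("CSP flags residues missing from either list", {
  ref <- peakList(1:3, H = rep(8, 3), N = rep(118, 3))
  per <- peakList(2:4, H = rep(8, 3), N = rep(118, 3))
  out <- csp(ref, per)
  expect_equal(out$residue, 1:4)
  expect_equal(out$absent, c(TRUE, FALSE, FALSE, TRUE))
  noShare <- peakList(7:8, H = rep(8, 2), N = rep(118, 2))
  expect_error(csp(ref, noShare), "shared")
})

test_that("intensity ratios normalize for concentration and flag absences", {
  ref <- peakList(1:3, H = rep(8, 3), N = rep(118, 3),
                  intensity = c(100, 100, 100))
  same <- csp  # silence lints: unused
  test1 <- peakList(1:3, H = rep(8, 3), N = rep(118, 3),
                    intensity = c(100, 100, 100))
  out <- intensityRatio(ref, test1, c0 = 50, conc = 50)
  expect_equal(out$ratio, c(1, 1, 1))

  ## 800 at 400 uM vs 100 at 50 uM: ratio 1 after normalization
  test2 <- peakList(1, H = 8, N = 118, intensity = 800)
  out2 <- intensityRatio(ref, test2, c0 = 50, conc = 400)
  expect_equal(out2$ratio[1], 1)
  expect_true(all(out2$absent[2:3]))
  expect_true(all(is.na(out2$ratio[2:3])))

  refZero <- peakList(1, H = 8, N = 118, intensity = 0)
  out3 <- intensityRatio(refZero, test2)
  expect_true(out3$zeroReference[1])
  expect_true(is.na(out3$ratio[1]))
  expect_error(intensityRatio(ref, test1, c0 = 0), "positive")
})

test_that("secondary shifts combine Calpha and Cbeta deviations", {
  a <- data.frame(residue = 1:3,
                  caObs = c(58, 56, 45.2), cbObs = c(32, 33, NA),
                  caRc = c(56, 56, 45.0), cbRc = c(33, 33, NA))
  out <- secondaryShift(a)
  expect_equal(out$secondaryShift[1], 3)     # (58-56) - (32-33)
  expect_equal(out$secondaryShift[2], 0)     # observed == random coil
  expect_equal(out$secondaryShift[3], 0.2)   # glycine: Calpha term only
  expect_true(out$caOnly[3])
  expect_false(any(out$caOnly[1:2]))

  b <- a; b$caRc[2] <- NA
  out2 <- secondaryShift(b)
  expect_true(out2$missingRandomCoil[2])
  expect_true(is.na(out2$secondaryShift[2]))
})

test_that("mono-exponential fits recover noiseless parameters to machine precision", {
  s <- makeRelaxationSeries(2.0, 100, c(0.004, 0.6, 1.0))
  fit <- fitMonoexponential(s)
  expect_true(fit$converged)
  expect_equal(fit$rate, 2.0, tolerance = 1e-8)
  expect_equal(fit$amplitude, 100, tolerance = 1e-8)
  expect_equal(fit$rateSD, 0)
})

test_that("Monte Carlo rate errors cover the truth and scale with noise", {
  delays <- rep(c(0.004, 0.6, 1.0), each = 2)
  s <- makeRelaxationSeries(2.0, 100, delays, noiseSD = 1.0, seed = 5)
  fit <- fitMonoexponential(s, mcTrials = 300, seed = 6)
  expect_lt(abs(fit$rate - 2.0), 3 * fit$rateSD)
  ## SD proportional to the noise level
  s2 <- makeRelaxationSeries(2.0, 100, delays, noiseSD = 2.0, seed = 5)
  fit2 <- fitMonoexponential(s2, mcTrials = 300, seed = 6)
  expect_equal(fit2$rateSD / fit$rateSD, 2, tolerance = 0.3)
})

test_that("degenerate relaxation inputs are rejected", {
  expect_error(makeRelaxationSeries(2, 100, c(0.5, 0.5)), "distinct")
  expect_error(relaxationSeries(0.5, 10), "distinct")
  s <- makeRelaxationSeries(2, 100, c(0.004, 1.0))
  s@intensities[1] <- -5
  expect_error(fitMonoexponential(s), "positive")
})

test_that("hetNOE values and propagated errors match hand evaluation", {
  sat <- peakList(1:3, H = rep(8, 3), N = rep(118, 3),
                  intensity = c(100, 50, 0))
  ref <- peakList(1:3, H = rep(8, 3), N = rep(118, 3),
                  intensity = c(100, 100, 100))
  out <- hetNOE(sat, ref, noiseSat = 0, noiseRef = 0)
  expect_equal(out$noe, c(1, 0.5, 0))
  expect_equal(out$error[1], 0)

  out2 <- hetNOE(sat, ref, noiseSat = 1, noiseRef = 1)
  ## 0.5 * sqrt((1/50)^2 + (1/100)^2) = 0.01118
  expect_equal(out2$error[2], 0.5 * sqrt((1 / 50)^2 + (1 / 100)^2),
               tolerance = 1e-9)
  expect_equal(out2$error[2], 0.01118, tolerance = 1e-4)

  refZero <- peakList(1, H = 8, N = 118, intensity = 0)
  satOne <- peakList(1, H = 8, N = 118, intensity = 10)
  out3 <- hetNOE(satOne, refZero)
  expect_true(out3$zeroReference[1])
})

test_that("hetNOE error formula agrees with finite-difference propagation", {
  ## numerical propagation: sigma_f^2 = (df/dIsat sSat)^2 + (df/dIref sRef)^2
  cases <- expand.grid(Isat = c(20, 50, 120), Iref = c(40, 100, 300))
  for (k in seq_len(nrow(cases))) {
    Is <- cases$Isat[k]; Ir <- cases$Iref[k]
    sSat <- 1; sRef <- 1.5
    h <- 1e-5
    dfs <- ((Is + h) / Ir - (Is - h) / Ir) / (2 * h)
    dfr <- (Is / (Ir + h) - Is / (Ir - h)) / (2 * h)
    num <- sqrt((dfs * sSat)^2 + (dfr * sRef)^2)
    out <- hetNOE(peakList(1, 8, 118, Is), peakList(1, 8, 118, Ir),
                  noiseSat = sSat, noiseRef = sRef)
    expect_equal(out$error, num, tolerance = 0.01)
  }
})
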
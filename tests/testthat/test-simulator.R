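quickConfig <- function(duration, equilibration = 0, saveInterval = 1,
                        friction = 0.01, replicas = 1) {
  simulationConfig(duration = duration, equilibration = equilibration,
                   saveInterval = saveInterval, friction = friction,
                   replicas = replicas)
}

test_that("zero integration steps return only the initial coordinates", {
  top <- toyChainTopology(10)
  cfg <- quickConfig(duration = 1e-9, equilibration = 0)
  tr <- runLangevin(top, cfg, seed = 1,
                    initialCoords = referenceCoords(top))
  expect_equal(nFrames(tr), 1)
  expect_equal(frameCoords(tr, 1), referenceCoords(top),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("identical (topology, config, seed) reproduce the trajectory exactly", {
  top <- toyChainTopology(15)
  cfg <- quickConfig(duration = 0.05)
  a <- runLangevin(top, cfg, seed = 123)
  b <- runLangevin(top, cfg, seed = 123)
  expect_identical(a@coords, b@coords)
  c <- runLangevin(top, cfg, seed = 124)
  expect_false(identical(a@coords, c@coords))
})

test_that("frame count follows the closed form, including the full protocol", {
  ## printed full protocol: 70 ns, 3.5 ns discard, 0.5 ps saves
  expect_equal(productionFrameCount(70, 3.5, 0.5), 133000L)
  expect_equal(productionFrameCount(1, 0.25, 1), 750L)
  expect_error(productionFrameCount(1, 1, 1), "smaller")

  top <- toyChainTopology(8)
  cfg <- quickConfig(duration = 0.2, equilibration = 0.05, saveInterval = 1)
  tr <- runLangevin(top, cfg, seed = 5)
  trimmed <- trimEquilibration(tr, 0.05)
  expect_equal(nFrames(trimmed), productionFrameCount(0.2, 0.05, 1))
  expect_equal(unique(round(diff(frameTimes(trimmed)), 9)), tr@dt)
})

test_that("trimming with zero cut is the identity and full cut errors", {
  top <- toyChainTopology(8)
  tr <- runLangevin(top, quickConfig(duration = 0.05), seed = 2)
  expect_identical(trimEquilibration(tr, 0), tr)
  expect_error(trimEquilibration(tr, 0.05), "smaller")
  expect_error(trimEquilibration(tr, 1), "smaller")
})

test_that("kinetic temperature obeys equipartition scaling laws", {
  n <- 20; nf <- 30
  masses <- rep(100, n)
  vel <- array(0, dim = c(n, 3, nf))
  expect_equal(kineticTemperature(vel, masses)$temperature, 0)
  set.seed(9)
  ## velocities drawn at 300 K: sqrt(kT/m) with kT = kB * 300
  s <- sqrt(0.008314462618 * 300 / 100)
  vel[] <- rnorm(n * 3 * nf, 0, s)
  t1 <- kineticTemperature(vel, masses)$temperature
  t4 <- kineticTemperature(vel * 2, masses)$temperature
  expect_equal(t4, 4 * t1, tolerance = 1e-12)
  expect_equal(t1, 300, tolerance = 0.1 * 300)
  expect_error(kineticTemperature(vel[, , 1, drop = FALSE][, , integer(0),
                                                           drop = FALSE],
                                  masses), "beads x 3 x frames|samples")
})

test_that("thermostat holds a toy chain at the target temperature", {
  top <- toyChainTopology(30)
  ## stronger friction decorrelates the kinetic-energy blocks
  cfg <- quickConfig(duration = 0.6, equilibration = 0.2,
                     saveInterval = 0.5, friction = 0.1)
  tr <- runLangevin(top, cfg, seed = 31, saveVelocities = TRUE)
  kt <- kineticTemperature(trimEquilibration(tr, 0.2), beadMasses(top))
  expect_lt(abs(kt$temperature - 298.15), 3 * kt$se)
})

test_that("free-bead diffusion matches the Einstein relation", {
  ## two non-bonded, non-interacting beads; D = kT / (m gamma)
  ref <- rbind(c(0, 0, 0), c(50, 0, 0))
  top <- buildTopology("GG", referenceCoords = ref, bondK = 0,
                       includeTermini = FALSE)
  gamma <- 0.05
  kT <- 0.008314462618 * 298.15
  D <- kT / (beadMasses(top)[1] * gamma)
  cfg <- quickConfig(duration = 0.5, saveInterval = 1, friction = gamma)
  slopes <- vapply(1:8, function(r) {
    tr <- runLangevin(top, cfg, seed = 600 + r, warmupSteps = 0)
    disp <- sapply(seq_len(nFrames(tr)), function(f)
      sum((frameCoords(tr, f)[1, ] - ref[1, ])^2))
    t <- frameTimes(tr)
    win <- t >= 100
    unname(coef(lm(disp[win] ~ t[win]))[2]) / 6
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - D), 3 * se)
})

test_that("bond lengths sample the harmonic Boltzmann distribution", {
  ## dimer with only the bond term; oracle: quadrature over
  ## r^2 exp(-beta k (r - r0)^2 / 2)
  ref <- rbind(c(0, 0, 0), c(0.38, 0, 0))
  top <- buildTopology("GG", referenceCoords = ref, includeTermini = FALSE)
  kT <- 0.008314462618 * 298.15
  k <- 8033; r0 <- 0.38
  w <- function(r) r^2 * exp(-k * (r - r0)^2 / (2 * kT))
  Z <- integrate(w, 0.2, 0.6)$value
  meanR <- integrate(function(r) r * w(r), 0.2, 0.6)$value / Z

  cfg <- quickConfig(duration = 2, equilibration = 0.2, saveInterval = 0.5,
                     friction = 0.1)
  tr <- trimEquilibration(runLangevin(top, cfg, seed = 77), 0.2)
  bl <- sapply(seq_len(nFrames(tr)), function(f) {
    fc <- frameCoords(tr, f); sqrt(sum((fc[1, ] - fc[2, ])^2))
  })
  blocks <- vapply(split(bl, cut(seq_along(bl), 10, labels = FALSE)),
                   mean, numeric(1))
  se <- sd(blocks) / sqrt(10)
  expect_lt(abs(mean(bl) - meanR), 3 * se + 1e-4)
})

test_that("elastic restraints keep folded-domain geometry near the reference", {
  top <- twoDomainTopology()
  cfg <- quickConfig(duration = 0.5, equilibration = 0.1, saveInterval = 1)
  tr <- trimEquilibration(runLangevin(top, cfg, seed = 41), 0.1)
  rp <- restraintPairs(top)
  drift <- sapply(seq_len(nFrames(tr)), function(f) {
    fc <- frameCoords(tr, f)
    d <- sqrt(rowSums((fc[rp$i, ] - fc[rp$j, ])^2))
    sqrt(mean((d - rp$r0)^2))
  })
  expect_lt(max(drift), 0.15)
  ## stationary: late-half drift no worse than twice the early half
  half <- length(drift) %/% 2
  expect_lt(mean(drift[(half + 1):length(drift)]),
            2 * mean(drift[1:half]) + 0.02)
})
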
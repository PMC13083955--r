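test_that("toy groove systems are deterministic and geometrically sound", {
  a <- makeToyGrooveSystem(8, 8, 6.0, seed = 1)
  b <- makeToyGrooveSystem(8, 8, 6.0, seed = 1)
  expect_identical(a@coords, b@coords)
  c <- makeToyGrooveSystem(8, 8, 6.0, seed = 2)
  expect_false(identical(a@coords, c@coords))

  ## interior and exterior partition the beads
  g <- a@groove
  expect_setequal(c(grooveInterior(g), grooveExterior(g)),
                  seq_len(nrow(a@coords)))
  expect_length(intersect(grooveInterior(g), grooveExterior(g)), 0)

  ## the arc centroid lies closer to the center than the furthest interior
  ## bead (so a probe there passes the first test)
  center <- grooveCenter(a@coords, grooveInterior(g))
  rInt <- sqrt(colSums((t(a@coords[grooveInterior(g), ]) - center)^2))
  expect_lt(0, max(rInt))  # non-degenerate
  expect_true(all(classifyFrame(rbind(a@coords, center), g,
                                nrow(a@coords) + 1L)))

  expect_error(makeToyGrooveSystem(3, 8, 6.0, seed = 1), "nInterior")
  expect_error(makeToyGrooveSystem(8, 8, -1, seed = 1), "positive")
})

test_that("planted trajectories honor their occupancy targets", {
  sys <- makeToyGrooveSystem(8, 8, 6.0, seed = 1)
  all1 <- makePlantedOccupancyTrajectory(sys, 2, 1.0, 100, seed = 4)
  expect_true(all(all1$truth))
  all0 <- makePlantedOccupancyTrajectory(sys, 2, 0.0, 100, seed = 4)
  expect_false(any(all0$truth))

  mid <- makePlantedOccupancyTrajectory(sys, 1, 0.25, 10000, seed = 7)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(mean(mid$truth) - 0.25), 3 * se)

  ## same seed reproduces both coordinates and truth
  mid2 <- makePlantedOccupancyTrajectory(sys, 1, 0.25, 10000, seed = 7)
  expect_identical(mid$truth, mid2$truth)
  expect_identical(mid$trajectory@coords, mid2$trajectory@coords)

  expect_error(makePlantedOccupancyTrajectory(sys, 1, 1.5, 10, seed = 1),
               "\\[0, 1\\]")
  expect_error(makePlantedOccupancyTrajectory(sys, 1, 0.5, 0, seed = 1),
               ">= 1")
})

test_that("relaxation generator is the exact closed form plus seeded noise", {
  s <- makeRelaxationSeries(2.0, 100, c(0.004, 0.6, 1.0))
  expect_equal(s@intensities, 100 * exp(-2 * c(0.004, 0.6, 1.0)),
               tolerance = 1e-12)
  ## hand values: 99.20..., 30.12..., 13.53...
  expect_equal(round(s@intensities, 2), c(99.20, 30.12, 13.53))

  withZero <- makeRelaxationSeries(2.0, 100, c(0, 0.5))
  expect_equal(withZero@intensities[1], 100)

  n1 <- makeRelaxationSeries(2, 100, c(0.1, 0.5), noiseSD = 1, seed = 9)
  n2 <- makeRelaxationSeries(2, 100, c(0.1, 0.5), noiseSD = 1, seed = 9)
  expect_identical(n1@intensities, n2@intensities)
  expect_false(identical(n1@intensities,
                         100 * exp(-2 * c(0.1, 0.5))))
})

test_that("Guinier generator is the exact closed form with linear ln I in q^2", {
  q <- seq(0.002, 0.034, by = 0.002)
  p <- makeGuinierProfile(38, 100, q)
  expect_equal(p@I, 100 * exp(-q^2 * 38^2 / 3), tolerance = 1e-12)
  ## ln I exactly linear in q^2
  fit <- lm(log(p@I) ~ I(q^2))
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-10)
  expect_equal(guinierFit(p)$rg, 38, tolerance = 1e-9)

  n1 <- makeGuinierProfile(38, 100, q, noiseSD = 0.3, seed = 2)
  n2 <- makeGuinierProfile(38, 100, q, noiseSD = 0.3, seed = 2)
  expect_identical(n1@I, n2@I)
  expect_error(makeGuinierProfile(38, 100, c(0.02, 0.01)), "increasing")
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(500)
  before <- .Random.seed
  invisible(makeToyGrooveSystem(8, 8, 6.0, seed = 1))
  invisible(makeRelaxationSeries(2, 100, c(0.1, 0.5), noiseSD = 1,
                                 seed = 3))
  invisible(makeGuinierProfile(38, 100, c(0.01, 0.02), noiseSD = 1,
                               seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("the synthetic multidomain chain has the annotated architecture", {
  seq <- syntheticMultidomainSequence()
  expect_equal(nchar(seq), 373)
  doms <- syntheticDomainTable()
  expect_equal(doms$start, c(1L, 147L, 327L))
  expect_equal(doms$end, c(75L, 223L, 373L))
  regions <- syntheticHelixRegions()
  expect_equal(regions$name, c("TH1", "TH2", "TH3"))

  ref <- syntheticReferenceCoords()
  expect_true(all(is.finite(ref$coords)))
  expect_equal(nrow(ref$coords), 373)
  ## groove indices lie inside the groove-bearing domain
  expect_true(all(grooveInterior(ref$groove) %in% 147:223))
  expect_true(all(grooveExterior(ref$groove) %in% 147:223))
  ## chain continuity: consecutive beads near the bond length everywhere
  ## (the two groove-sheet junctions may reach ~2.5x the bond length;
  ## the soft-core warmup relaxes them before production)
  d <- sqrt(rowSums((ref$coords[-1, ] - ref$coords[-373, ])^2))
  expect_lt(max(d), 1.0)
  expect_gt(min(d), 0.28)
  expect_lt(mean(d > 0.5), 0.02)
  ## bound pose docks the first and last domains close together
  comDist <- function(co) {
    a <- colMeans(co[1:75, ]); b <- colMeans(co[327:373, ])
    sqrt(sum((a - b)^2))
  }
  expect_lt(comDist(ref$boundCoords), 3)
  expect_gt(comDist(ref$coords), 5)
})
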
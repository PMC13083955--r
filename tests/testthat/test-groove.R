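test_that("groove center is the mean of interior positions", {
  coords <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 3, 1))
  expect_equal(grooveCenter(coords, 1:2), c(0, 0, 0))
  expect_equal(grooveCenter(coords, 3), c(0, 3, 1))
  expect_error(grooveCenter(coords, integer()), "non-empty")
  sys <- makeToyGrooveSystem(10, 6, 8, seed = 3)
  expect_equal(grooveCenter(sys@coords, grooveInterior(sys@groove)),
               colMeans(sys@coords[grooveInterior(sys@groove), ]))
})

test_that("a candidate at the groove center is occupied; a far one is not", {
  sys <- makeToyGrooveSystem(8, 8, 6.0, seed = 1)
  g <- sys@groove
  center <- grooveCenter(sys@coords, grooveInterior(g))
  rMax <- max(sqrt(colSums((t(sys@coords[grooveInterior(g), ]) - center)^2)))
  coords <- rbind(sys@coords, center, center + c(3 * rMax, 0, 0))
  flags <- classifyFrame(coords, g, c(17L, 18L))
  expect_true(flags[1])
  expect_false(flags[2])
})

test_that("classification agrees with the brute-force oracle and is rigid-motion invariant", {
  set.seed(202)
  sys <- makeToyGrooveSystem(10, 8, 7.0, seed = 11)
  g <- sys@groove
  nCand <- 500
  span <- 3 * sys@radius
  cand <- matrix(runif(3 * nCand, -span, span), ncol = 3)
  coords <- rbind(sys@coords, cand)
  candIdx <- nrow(sys@coords) + seq_len(nCand)
  flags <- classifyFrame(coords, g, candIdx)
  oracle <- bruteClassify(coords, grooveInterior(g), grooveExterior(g),
                          g@threshold, candIdx)
  expect_identical(flags, oracle)
  expect_gt(sum(flags), 0)
  expect_lt(sum(flags), nCand)
  ## all criteria are distance/axis-relative: invariant under rigid motion
  moved <- randomRigidMotion(coords)
  expect_identical(classifyFrame(moved, g, candIdx), flags)
})

test_that("degenerate interior sets are rejected", {
  expect_error(grooveDefinition(1:3, 4:6), "at least 4")
  sys <- makeToyGrooveSystem(8, 8, 6.0, seed = 1)
  g <- sys@groove
  g@interior <- g@interior[1:3]
  expect_error(classifyFrame(sys@coords, g, 10L), "at least 4")
})

test_that("occupancy profiles recover planted targets", {
  sys <- makeToyGrooveSystem(8, 8, 6.0, seed = 1)

  full <- makePlantedOccupancyTrajectory(sys, nProbes = 2,
                                         targetOccupancy = 1, nFrames = 100,
                                         seed = 2)
  p1 <- occupancyProfile(full$trajectory, full$groove, full$probeResidues)
  expect_equal(p1@probability, c(1, 1))

  none <- makePlantedOccupancyTrajectory(sys, nProbes = 2,
                                         targetOccupancy = 0, nFrames = 100,
                                         seed = 2)
  p0 <- occupancyProfile(none$trajectory, none$groove, none$probeResidues)
  expect_equal(p0@probability, c(0, 0))

  mid <- makePlantedOccupancyTrajectory(sys, nProbes = 1,
                                        targetOccupancy = 0.25,
                                        nFrames = 10000, seed = 7)
  pm <- occupancyProfile(mid$trajectory, mid$groove, mid$probeResidues)
  ## classification must equal the planted truth frame by frame, so the
  ## profile is the binomial truth fraction
  expect_equal(pm@probability, mean(mid$truth))
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(pm@probability - 0.25), 3 * se)
})

test_that("replica averaging gives the mean and population spread", {
  sys <- makeToyGrooveSystem(8, 8, 6.0, seed = 1)
  r1 <- makePlantedOccupancyTrajectory(sys, 1, 0.2, 4000, seed = 21)
  r2 <- makePlantedOccupancyTrajectory(sys, 1, 0.4, 4000, seed = 22)
  prof <- occupancyProfile(list(r1$trajectory, r2$trajectory), sys@groove,
                           r1$probeResidues)
  expect_equal(prof@nReplicas, 2L)
  expect_equal(prof@probability, 0.3, tolerance = 0.05)
  expect_equal(prof@spread, sd(c(mean(r1$truth), mean(r2$truth))),
               tolerance = 1e-9)
})

test_that("excess occupancy handles ratios, identity and zero baselines", {
  mk <- function(p) new("OccupancyProfile", residues = 1:4,
                        probability = p, spread = rep(0, 4),
                        nFrames = 100L, nReplicas = 1L)
  obs <- mk(c(0.30, 0.10, 0, 0.05))
  base <- mk(c(0.002, 0.10, 0, 0))
  ex <- excessOccupancy(obs, base)
  expect_equal(ex@enrichment[1], 150)
  expect_equal(ex@enrichment[2], 1)
  expect_equal(ex@status, c("ok", "ok", "undefined", "infinite"))

  ## identity: X / X = 1 wherever X > 0
  same <- excessOccupancy(obs, obs)
  expect_equal(same@enrichment[same@status == "ok"], c(1, 1, 1))

  other <- mk(c(0.1, 0.1, 0.1, 0.1))
  other@residues <- 2:5
  expect_error(excessOccupancy(obs, other), "different residue sets")
})

test_that("region means average only defined residues", {
  ex <- new("ExcessProfile", residues = 1:10,
            enrichment = c(rep(150, 4), rep(100, 3), rep(200, 2), NA),
            status = c(rep("ok", 9), "undefined"))
  regions <- data.frame(name = c("A", "B", "C"),
                        start = c(1, 5, 9), end = c(4, 9, 10))
  out <- regionEnrichment(ex, regions)
  expect_equal(unname(out["A"]), 150)
  expect_equal(unname(out["B"]), mean(c(100, 100, 100, 200, 200)))
  expect_equal(unname(out["C"]), 200)  # the undefined residue is excluded

  allUndef <- new("ExcessProfile", residues = 1:2,
                  enrichment = c(NA_real_, NA_real_),
                  status = c("undefined", "undefined"))
  expect_warning(out2 <- regionEnrichment(
    allUndef, data.frame(name = "Z", start = 1, end = 2)), "no defined")
  expect_true(is.na(out2[["Z"]]))
  expect_error(regionEnrichment(ex, data.frame(name = "X", start = 8,
                                               end = 12)), "beyond")
})

test_that("groove definitions round-trip through YAML", {
  g <- grooveDefinition(1:6, 7:10, threshold = 0.8)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(interior = grooveInterior(g),
                        exterior = grooveExterior(g),
                        threshold = 0.8), path)
  g2 <- readGrooveDefinition(path)
  expect_identical(grooveInterior(g2), grooveInterior(g))
  expect_identical(grooveExterior(g2), grooveExterior(g))
  expect_equal(g2@threshold, 0.8)
})

test_that("interior proposal helper returns concave-face domain residues", {
  ## evaluated on the synthetic groove-bearing domain it is meant for
  ref <- syntheticReferenceCoords()
  prop <- proposeGrooveInterior(ref$coords, 147:223)
  expect_true(all(prop %in% 147:223))
  expect_true(length(prop) >= 4)
  ## proposals are strongly enriched for the constructed interior beads
  expect_gt(mean(prop %in% grooveInterior(ref$groove)), 0.7)
  expect_gt(mean(grooveInterior(ref$groove) %in% prop), 0.7)
})
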
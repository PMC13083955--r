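test_that("square-of-beads example yields exactly the non-bonded close pairs", {
  ## 4 beads on a 0.5 nm square: 6 pairs within 0.9 nm, minus 3 consecutive
  ## (bonded) pairs leaves restraints (1,3), (2,4) and the 1-4 diagonal
  ## at 0.5*sqrt(2) < 0.9
  ref <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0.5, 0.5, 0), c(0, 0.5, 0))
  doms <- data.frame(name = "D", start = 1L, end = 4L, group = "D")
  top <- buildTopology("GGGG", referenceCoords = ref, domains = doms)
  rp <- restraintPairs(top)
  expect_equal(nrow(rp), 3)
  expect_equal(as.matrix(rp[, 1:2]),
               matrix(c(1L, 1L, 2L, 3L, 4L, 4L), 3, 2,
                      dimnames = list(NULL, c("i", "j"))))
  expect_equal(rp$r0, c(sqrt(0.5), 0.5, sqrt(0.5)), tolerance = 1e-12)
})

test_that("restraint enumeration matches the brute-force oracle", {
  set.seed(71)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    coords <- matrix(runif(3 * n, 0, 1.6), ncol = 3)
    s1 <- sample(5:(n %/% 2), 1)
    doms <- data.frame(name = c("A", "B"),
                       start = c(1L, as.integer(s1 + 3)),
                       end = c(as.integer(s1), as.integer(n)),
                       group = c("A", "B"))
    top <- buildTopology(rep("G", n), referenceCoords = coords,
                         domains = doms)
    group <- rep(NA_character_, n)
    group[1:s1] <- "A"; group[(s1 + 3):n] <- "B"
    oracle <- bruteRestraints(coords, group, 0.9)
    rp <- restraintPairs(top)
    expect_equal(unname(as.matrix(rp[, 1:2])), unname(oracle$pairs))
    expect_equal(rp$r0, oracle$r0, tolerance = 1e-12)
  }
})

test_that("no domains or a zero cutoff produce no restraints", {
  ref <- matrix(runif(60), ncol = 3)
  top <- buildTopology(rep("A", 20), referenceCoords = ref)
  expect_equal(nrow(restraintPairs(top)), 0)
  doms <- data.frame(name = "D", start = 1L, end = 20L, group = "D")
  top0 <- buildTopology(rep("A", 20), referenceCoords = ref,
                        domains = doms, enmCutoff = 0)
  expect_equal(nrow(restraintPairs(top0)), 0)
})

test_that("invalid domains and coordinates are rejected", {
  ref <- matrix(0.38 * (1:10), ncol = 3, nrow = 10)
  expect_error(
    buildTopology(rep("A", 10), referenceCoords = ref,
                  domains = data.frame(name = "D", start = 5L, end = 12L)),
    "exceeds sequence")
  refBad <- ref; refBad[3, 2] <- NaN
  expect_error(buildTopology(rep("A", 10), referenceCoords = refBad),
               "non-finite")
  expect_error(
    buildTopology(rep("A", 10), referenceCoords = ref,
                  domains = data.frame(name = c("X", "Y"),
                                       start = c(1L, 4L), end = c(5L, 8L))),
    "overlap")
})

test_that("excluded-volume variant zeroes stickiness and charge, keeps topology", {
  top <- twoDomainTopology()
  ev <- excludedVolumeVariant(top)
  expect_equal(max(beadLambdas(ev)), 0)
  expect_equal(sum(abs(beadCharges(ev))), 0)
  expect_identical(restraintPairs(ev), restraintPairs(top))
  expect_identical(ev@bonds, top@bonds)
  ## idempotence
  expect_identical(excludedVolumeVariant(ev), ev)
  ## optional retention of electrostatics
  evq <- excludedVolumeVariant(top, keepCharges = TRUE)
  expect_identical(beadCharges(evq), beadCharges(top))
})

test_that("bound-complex variant adds only inter-group contact restraints", {
  top <- twoDomainTopology()

  ## pose with the domains still far apart: nothing changes
  far <- referenceCoords(top)
  same <- boundComplexVariant(top, c("D1", "D2"), far)
  expect_identical(restraintPairs(same), restraintPairs(top))

  ## docked pose: second domain translated into contact
  bound <- far
  bound[21:30, ] <- sweep(far[21:30, ], 2, c(-4.3, 0.4, 0), "+")
  bc <- boundComplexVariant(top, c("D1", "D2"), bound)
  rp <- restraintPairs(bc)
  ## all original (intra-group) restraints are retained
  expect_true(nrow(merge(restraintPairs(top), rp)) ==
              nrow(restraintPairs(top)))
  ## added pairs match a brute-force enumeration of inter-group contacts
  added <- rp[!paste(rp$i, rp$j) %in%
                paste(restraintPairs(top)$i, restraintPairs(top)$j), ]
  group <- rep(NA_character_, 30)
  group[1:10] <- "D1"; group[21:30] <- "D2"
  ## enumerate as if merged into one group, then keep cross-group pairs
  merged <- group; merged[!is.na(merged)] <- "M"
  oracle <- bruteRestraints(bound, merged, 0.9)
  inter <- oracle$pairs[group[oracle$pairs[, 1]] !=
                        group[oracle$pairs[, 2]], , drop = FALSE]
  addedM <- unname(as.matrix(added[, 1:2]))
  addedM <- addedM[order(addedM[, 1], addedM[, 2]), , drop = FALSE]
  expect_equal(addedM, unname(inter))
  expect_gt(nrow(added), 0)

  ## merged beads must all have coordinates
  incomplete <- bound; incomplete[25, ] <- NA
  expect_error(boundComplexVariant(top, c("D1", "D2"), incomplete),
               "missing coordinates")
})

test_that("buried-residue stickiness rescaling only touches buried domain beads", {
  top <- twoDomainTopology()
  ref <- referenceCoords(top)
  scaled <- buildTopology(chainSequence(top), referenceCoords = ref,
                          domains = domainTable(top),
                          buriedLambdaScale = 0.5, buriedMinNeighbors = 5)
  changed <- which(beadLambdas(scaled) != beadLambdas(top))
  group <- rep(NA_character_, 30)
  group[1:10] <- "D1"; group[21:30] <- "D2"
  expect_true(all(!is.na(group[changed])))
  expect_equal(beadLambdas(scaled)[changed],
               beadLambdas(top)[changed] * 0.5)
})
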
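## Independent oracles used across the suite.  These are deliberately
## written as plain loops over the definitions, separate from the package
## implementations they check.

## Brute-force groove classifier: the three geometric tests, looped.
bruteClassify <- function(coords, interior, exterior, threshold,
                          candidates) {
  nI <- length(interior)
  center <- c(0, 0, 0)
  for (i in interior) center <- center + coords[i, ]
  center <- center / nI

  rMax <- 0
  for (i in interior) {
    d <- sqrt(sum((coords[i, ] - center)^2))
    if (d > rMax) rMax <- d
  }

  ## covariance of the interior group about the center, by summation
  C <- matrix(0, 3, 3)
  for (i in interior) {
    v <- coords[i, ] - center
    C <- C + outer(v, v)
  }
  C <- C / nI
  axis <- eigen(C, symmetric = TRUE)$vectors[, 1]

  perpDist <- function(p) {
    v <- p - center
    along <- sum(v * axis)
    sqrt(max(sum(v^2) - along^2, 0))
  }
  envelope <- 0
  for (i in interior) {
    pd <- perpDist(coords[i, ])
    if (pd > envelope) envelope <- pd
  }

  out <- logical(length(candidates))
  for (k in seq_along(candidates)) {
    p <- coords[candidates[k], ]
    t1 <- sqrt(sum((p - center)^2)) < rMax
    dI <- Inf; for (i in interior) dI <- min(dI, sqrt(sum((p - coords[i, ])^2)))
    dE <- Inf; for (e in exterior) dE <- min(dE, sqrt(sum((p - coords[e, ])^2)))
    t2 <- dI < dE
    t3 <- perpDist(p) <= threshold * envelope
    out[k] <- t1 && t2 && t3
  }
  out
}

## Brute-force elastic-network enumeration: all pairs, looped.
bruteRestraints <- function(coords, group, cutoff) {
  n <- nrow(coords)
  pairs <- NULL
  r0 <- numeric()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i < 2) next
      if (is.na(group[i]) || is.na(group[j])) next
      if (group[i] != group[j]) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d < cutoff) {
        pairs <- rbind(pairs, c(i, j))
        r0 <- c(r0, d)
      }
    }
  }
  if (is.null(pairs)) pairs <- matrix(integer(), 0, 2)
  o <- if (nrow(pairs)) order(pairs[, 1], pairs[, 2]) else integer()
  list(pairs = pairs[o, , drop = FALSE], r0 = r0[o])
}

## Definition-based Rg summation, looped.
bruteRg <- function(coords, masses) {
  M <- sum(masses)
  com <- c(0, 0, 0)
  for (i in seq_len(nrow(coords))) com <- com + masses[i] * coords[i, ]
  com <- com / M
  s <- 0
  for (i in seq_len(nrow(coords))) s <- s + masses[i] * sum((coords[i, ] - com)^2)
  10 * sqrt(s / M)
}

## Random rigid-body motion (rotation + translation) of a frame.
randomRigidMotion <- function(coords) {
  ang <- stats::runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]),
                 0, 0, 0, 1), 3, 3, byrow = TRUE)
  shift <- stats::runif(3, -5, 5)
  sweep(coords %*% (Rx %*% Ry %*% Rz), 2, shift, "+")
}

## Small interacting test chain: sticky/charged mixed sequence on a
## straight reference, no folded domains.
toyChainTopology <- function(n = 40, pattern = c("L", "F", "G", "S", "E", "K")) {
  seqv <- rep(pattern, length.out = n)
  ref <- cbind(0.38 * seq_len(n), 0, 0)
  buildTopology(seqv, referenceCoords = ref)
}

## Two compact 10-bead serpentine domains joined by a 10-bead linker;
## the reference keeps the domains far apart and every consecutive bead
## near the bond length.
twoDomainTopology <- function() {
  snake <- function(x0, y0) {
    rbind(cbind(x0 + 0.38 * (0:4), y0, 0),
          cbind(x0 + 0.38 * (4:0), y0 + 0.38, 0))
  }
  ref <- rbind(snake(0, 0),
               cbind(0.38 * (1:10), 0.76, 0),
               snake(4.18, 0.76))
  doms <- data.frame(name = c("D1", "D2"), start = c(1L, 21L),
                     end = c(10L, 30L), group = c("D1", "D2"))
  buildTopology(rep(c("A", "S"), 15), referenceCoords = ref,
                domains = doms)
}
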
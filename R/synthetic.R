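## Synthetic benchmark generators.  Every generator draws from a private
## RNG stream (withSeed) and states its closed form; noiseless outputs are
## exact evaluations of those forms.

#' Build a rigid toy groove system
#'
#' Interior beads are placed on the concave face of a hemicylinder of the
#' given radius (evenly spaced over the half-arc and along the cylinder
#' axis); exterior beads sit on the convex back side at a larger radius.
#' The geometry is rigid, deterministic for a fixed seed (the seed only
#' jitters bead spacing slightly to avoid degenerate symmetric
#' configurations), and gives an unambiguous interior/exterior ground
#' truth with a well-defined principal axis along the cylinder.
#'
#' @param nInterior number of interior beads (>= 4).
#' @param nExterior number of exterior beads (>= 1).
#' @param grooveRadius groove radius in Angstrom (> 0).
#' @param seed integer seed.
#' @param jitter small positional jitter SD in Angstrom; default 0.05.
#' @return a \code{\link{ToyGrooveSystem}} (coordinates stored in nm).
#' @export
makeToyGrooveSystem <- function(nInterior, nExterior, grooveRadius, seed,
                                jitter = 0.05) {
  if (nInterior < 4)
    stop("nInterior must be >= 4 (principal axis undefined below that)")
  if (nExterior < 1) stop("nExterior must be >= 1")
  if (grooveRadius <= 0) stop("grooveRadius must be positive")
  R <- grooveRadius / 10  # A -> nm
  jit <- jitter / 10
  withSeed(seed, {
    ## interior: concave face, angles spanning the half-arc on the -x side,
    ## spread along the cylinder (z) axis
    ang <- seq(pi / 2, 3 * pi / 2, length.out = nInterior)
    zInt <- seq(-R, R, length.out = nInterior)
    interior <- cbind(R * cos(ang), R * sin(ang), zInt) +
      matrix(stats::rnorm(3 * nInterior, 0, jit), ncol = 3)
    ## exterior: convex back side (+x), larger radius
    angE <- seq(-pi / 3, pi / 3, length.out = nExterior)
    zExt <- seq(-R, R, length.out = nExterior)
    exterior <- cbind(1.5 * R * cos(angE), 1.5 * R * sin(angE), zExt) +
      matrix(stats::rnorm(3 * nExterior, 0, jit), ncol = 3)
    coords <- rbind(interior, exterior)
    groove <- grooveDefinition(seq_len(nInterior),
                               nInterior + seq_len(nExterior))
    new("ToyGrooveSystem", groove = groove, coords = coords, radius = R)
  })
}

#' Planted-occupancy trajectory over a toy groove
#'
#' Appends probe beads to the rigid groove geometry.  In each frame, each
#' probe sits at the groove centroid with probability
#' \code{targetOccupancy} and otherwise at three times the
#' furthest-interior radius from the centroid (guaranteed to fail the
#' first classification test).  The per-(probe, frame) ground-truth flags
#' are returned alongside, making the empirical truth fraction a binomial
#' draw around the target.
#'
#' @param system a \code{\link{ToyGrooveSystem}}.
#' @param nProbes number of probe beads to append; default 1.
#' @param targetOccupancy planted occupancy probability in [0, 1].
#' @param nFrames number of frames (>= 1).
#' @param seed integer seed.
#' @return list with \code{trajectory} (a \code{\link{Trajectory}} over
#'   groove beads + probes), \code{truth} (nFrames x nProbes logical
#'   matrix), \code{probeResidues} (their bead indices) and
#'   \code{groove}.
#' @export
makePlantedOccupancyTrajectory <- function(system, nProbes = 1,
                                           targetOccupancy, nFrames,
                                           seed) {
  stopifnot(is(system, "ToyGrooveSystem"))
  if (targetOccupancy < 0 || targetOccupancy > 1)
    stop("targetOccupancy must lie in [0, 1]")
  if (nFrames < 1) stop("nFrames must be >= 1")
  base <- system@coords
  nBase <- nrow(base)
  groove <- system@groove
  center <- grooveCenter(base, grooveInterior(groove))
  rMax <- max(.distToPoint(base[grooveInterior(groove), , drop = FALSE],
                           center))
  outside <- center + c(3 * rMax, 0, 0) * 1.0001

  withSeed(seed, {
    truth <- matrix(stats::runif(nFrames * nProbes) < targetOccupancy,
                    nFrames, nProbes)
    coords <- array(0, dim = c(nBase + nProbes, 3, nFrames))
    for (f in seq_len(nFrames)) {
      fr <- base
      for (p in seq_len(nProbes)) {
        pos <- if (truth[f, p]) center else outside
        fr <- rbind(fr, pos)
      }
      coords[, , f] <- fr
    }
    list(trajectory = .newTrajectory(coords, times = seq_len(nFrames),
                                     dt = 1, replica = 1L),
         truth = truth,
         probeResidues = nBase + seq_len(nProbes),
         groove = groove)
  })
}

#' Synthetic mono-exponential relaxation series
#'
#' Intensities are exact evaluations of
#' \eqn{A e^{-R t}} plus Gaussian noise of the given SD; the noise level
#' is stored in the series for downstream Monte Carlo error estimation.
#'
#' @param rate decay rate (s^-1), > 0.
#' @param amplitude amplitude at t = 0.
#' @param delays delay times (s), >= 2 distinct values; duplicates allowed.
#' @param noiseSD Gaussian noise SD; default 0.
#' @param seed integer seed (used only when noiseSD > 0).
#' @return a \code{\link{RelaxationSeries}}.
#' @export
makeRelaxationSeries <- function(rate, amplitude, delays, noiseSD = 0,
                                 seed = 1) {
  if (rate <= 0) stop("rate must be positive")
  if (length(unique(delays)) < 2)
    stop("at least 2 distinct delays are required")
  clean <- amplitude * exp(-rate * delays)
  noisy <- if (noiseSD > 0)
    withSeed(seed, clean + stats::rnorm(length(delays), 0, noiseSD))
  else clean
  relaxationSeries(delays, noisy, noise = noiseSD)
}

#' Synthetic ideal Guinier scattering profile
#'
#' \eqn{I(q) = I_0 \exp(-q^2 R_g^2 / 3)} evaluated on the given q grid,
#' plus optional Gaussian noise; the sigma column is populated with the
#' noise SD.
#'
#' @param rg radius of gyration (Angstrom), > 0.
#' @param i0 forward intensity.
#' @param qGrid strictly increasing positive q values (A^-1).
#' @param noiseSD Gaussian noise SD on I; default 0.
#' @param seed integer seed (used only when noiseSD > 0).
#' @return a \code{\link{ScatteringProfile}}.
#' @export
makeGuinierProfile <- function(rg, i0, qGrid, noiseSD = 0, seed = 1) {
  if (rg <= 0) stop("rg must be positive")
  if (any(qGrid <= 0) || (length(qGrid) > 1 && any(diff(qGrid) <= 0)))
    stop("qGrid must be strictly increasing and positive")
  clean <- i0 * exp(-qGrid^2 * rg^2 / 3)
  I <- if (noiseSD > 0)
    withSeed(seed, clean + stats::rnorm(length(qGrid), 0, noiseSD))
  else clean
  scatteringProfile(qGrid, I, sigma = rep(noiseSD, length(qGrid)))
}

#' Synthetic multidomain test sequence
#'
#' A deterministic 373-residue stand-in for a UBL-IDR-STI1-IDR-UBA
#' architecture, used because the package ships no sequence of record:
#' folded domains (1-75, 147-223, 327-373) with mixed folded-domain
#' composition, disordered linkers rich in G/S/E/K/P/Q/N/T, and three
#' amphipathic transient-helix segments at 114-134, 279-291 and 303-313
#' whose hydrophobic faces give them an affinity for the sticky groove
#' face of the central domain.  The middle of the central domain
#' (residues 169-203, which form the groove's concave face in the
#' synthetic reference structure) is strongly hydrophobic; the convex
#' back is polar.  This is a synthetic construct, not a natural protein
#' sequence.
#'
#' @return character string of 373 one-letter codes.
#' @export
syntheticMultidomainSequence <- function() {
  rep_to <- function(pattern, n) {
    s <- strsplit(pattern, "")[[1]]
    paste(rep(s, length.out = n), collapse = "")
  }
  ubl <- rep_to("MKVTLKDAQSVELTIKASDTVAELKEQLASV", 75)       # 1-75
  linker1a <- rep_to("SGQEQKPTNSEGQSTPEKQGSNDQTGSEPQKSTGNEQS", 38) # 76-113
  th1 <- rep_to("LLEKALSIAEKLLQSAIDLFE", 21)                  # 114-134
  linker1b <- rep_to("SGQEKPTNSEGQ", 12)                      # 135-146
  sti1BackA <- rep_to("EKQSNEQKSTEQNKSEQTKSNE", 22)            # 147-168
  sti1Groove <- rep_to("LMALFIAVLMILAFLVAMILAFLIMVLAFILMALF", 35) # 169-203
  sti1BackB <- rep_to("QSTKEQNSKEQTSKENQEKQ", 20)              # 204-223
  linker2a <- rep_to("SGQEQKPTNSEGQSTPEKQGSNDQTGSEPQKSTGNEQSSGQEQKPTNSEGQSTPE",
                     55)                                      # 224-278
  th2 <- rep_to("FLQKALEIAEKLF", 13)                          # 279-291
  linker2b <- rep_to("SGQEKPTNSEG", 11)                       # 292-302
  th3 <- rep_to("MLLSKAIELAF", 11)                            # 303-313
  linker2c <- rep_to("SGQEKPTNSEGQP", 13)                     # 314-326
  uba <- rep_to("MSEQDIQRLVSMGFDPSKAVEALRISGGDLNTAVEYLLSGDSEHHA", 47) # 327-373
  seq <- paste0(ubl, linker1a, th1, linker1b, sti1BackA, sti1Groove,
                sti1BackB, linker2a, th2, linker2b, th3, linker2c, uba)
  stopifnot(nchar(seq) == 373)
  seq
}

#' Default domain annotation for the synthetic multidomain chain
#'
#' @return data.frame with columns \code{name}, \code{start}, \code{end},
#'   \code{group}.
#' @export
syntheticDomainTable <- function() {
  data.frame(name = c("UBL", "STI1", "UBA"),
             start = c(1L, 147L, 327L),
             end = c(75L, 223L, 373L),
             group = c("UBL", "STI1", "UBA"))
}

#' Transient-helix region table for the synthetic multidomain chain
#'
#' @return data.frame with columns \code{name}, \code{start}, \code{end}.
#' @export
syntheticHelixRegions <- function() {
  data.frame(name = c("TH1", "TH2", "TH3"),
             start = c(114L, 279L, 303L),
             end = c(134L, 291L, 313L))
}

## ---- synthetic reference geometry --------------------------------------

## Compact solenoid fold for a generic domain: consecutive beads exactly
## `spacing` apart winding around a cylinder, turns stacked at `pitch`.
## Continuous by construction (no chain jumps); perTurn 12 at pitch 0.42
## keeps the aspect ratio near globular for 40-80 residue domains.
.domainSpiral <- function(n, spacing = 0.38, perTurn = 12, pitch = 0.42) {
  h <- pitch / perTurn
  chord <- sqrt(spacing^2 - h^2)
  R <- chord / (2 * sin(pi / perTurn))
  i <- seq_len(n) - 1
  ang <- i * 2 * pi / perTurn
  cbind(R * cos(ang), R * sin(ang), i * h - n * h / 2)
}

## Deterministic steric relaxation of an assembled reference layout:
## pushes non-bonded pairs apart to at least minDist and pulls bonds back
## toward bondTarget.  Folded domains respond rigidly (per-iteration
## displacements on domain beads are averaged into a rigid translation),
## so their internal geometry — and hence the restraint network derived
## from it — is preserved exactly.  Pairs inside one domain are exempt
## from the clash term.  Purely geometric (no RNG).
.relaxGeometry <- function(coords, minDist = 0.5, bondTarget = 0.38,
                           iters = 600, tolBond = 0.08, group = NULL) {
  n <- nrow(coords)
  if (is.null(group)) group <- rep(NA_character_, n)
  domainIdx <- split(seq_len(n), group)
  for (it in seq_len(iters)) {
    disp <- matrix(0, n, 3)
    D <- as.matrix(stats::dist(coords))
    close <- which(D < minDist & upper.tri(D), arr.ind = TRUE)
    close <- close[abs(close[, 1] - close[, 2]) >= 2, , drop = FALSE]
    if (nrow(close)) {
      sameDomain <- !is.na(group[close[, 1]]) &
        !is.na(group[close[, 2]]) &
        group[close[, 1]] == group[close[, 2]]
      close <- close[!sameDomain, , drop = FALSE]
    }
    if (nrow(close)) {
      for (k in seq_len(nrow(close))) {
        i <- close[k, 1]; j <- close[k, 2]
        v <- coords[i, ] - coords[j, ]
        d <- sqrt(sum(v^2))
        u <- if (d > 1e-8) v / d else c(1, 0, 0)
        push <- 0.6 * (minDist - d) / 2
        disp[i, ] <- disp[i, ] + u * push
        disp[j, ] <- disp[j, ] - u * push
      }
    }
    bd <- coords[-1, , drop = FALSE] - coords[-n, , drop = FALSE]
    bl <- sqrt(rowSums(bd^2))
    stretch <- which(abs(bl - bondTarget) > tolBond)
    for (i in stretch) {
      u <- bd[i, ] / bl[i]
      corr <- 0.5 * (bl[i] - bondTarget) / 2
      disp[i, ] <- disp[i, ] + u * corr
      disp[i + 1, ] <- disp[i + 1, ] - u * corr
    }
    if (max(abs(disp)) < 1e-12) break
    ## folded domains stay frozen: their placement is by construction and
    ## their internal geometry defines the restraint network; clashes are
    ## resolved by moving linker beads only
    for (idx in domainIdx) disp[idx, ] <- 0
    coords <- coords + disp
  }
  coords
}

## Hemicylindrical groove fold: an inner (concave, groove-lining) arc sheet
## backed by an outer arc sheet.  Returns coords plus the inner/outer index
## split so the groove definition is known by construction.
.grooveDomainCoords <- function(n, rInner = 0.8, rOuter = 1.3,
                                spacing = 0.38) {
  nInner <- ceiling(n * 0.45)
  nOuter <- n - nInner
  build <- function(m, r, rowsTopDown = FALSE, firstRowReversed = FALSE,
                    perRow = NULL) {
    arcLen <- pi * r
    if (is.null(perRow)) perRow <- max(4, floor(arcLen / spacing) + 1)
    rows <- ceiling(m / perRow)
    rowSeq <- seq_len(rows)
    if (rowsTopDown) rowSeq <- rev(rowSeq)
    out <- matrix(0, m, 3)
    k <- 1
    for (ri in seq_along(rowSeq)) {
      z <- (rowSeq[ri] - (rows + 1) / 2) * spacing
      ang <- seq(pi / 2, 3 * pi / 2, length.out = perRow)
      reversed <- xor(ri %% 2 == 0, firstRowReversed)
      if (reversed) ang <- rev(ang)      # snake for chain continuity
      for (a in ang) {
        if (k > m) break
        out[k, ] <- c(r * cos(a), r * sin(a), z)
        k <- k + 1
      }
    }
    out
  }
  ## path order: first half of the outer (convex back) sheet, then the
  ## inner (groove) sheet, then the rest of the outer sheet.  Both chain
  ## termini thereby sit on the exposed back of the domain, so the
  ## flanking linkers never have to thread into the groove mouth.
  ## split the outer sheet at a row boundary so the inner sheet bridges
  ## from the top of the lower half to the bottom of the upper half
  perRowOut <- max(4, floor(pi * rOuter / spacing) + 1)
  rowsOut <- ceiling(nOuter / perRowOut)
  nOutA <- min(nOuter - 1, (rowsOut %/% 2) * perRowOut)
  nOutB <- nOuter - nOutA
  fullOuter <- build(nOuter, rOuter)           # one snake, bottom to top
  outA <- fullOuter[seq_len(nOutA), , drop = FALSE]
  outB <- fullOuter[nOutA + seq_len(nOutB), , drop = FALSE]
  ## orient the inner sheet and the second outer half to minimize the two
  ## chain jumps (outerA -> inner and inner -> outerB) jointly
  ## an even number of inner rows lets the inner sheet enter and exit on
  ## the same arc side, keeping both junctions short
  pIn <- max(4, floor(pi * rInner / spacing) + 1)
  rIn <- ceiling(nInner / pIn)
  if (rIn %% 2 == 1) pIn <- ceiling(nInner / (rIn + 1))
  inner <- NULL; outBBest <- NULL; bestD <- Inf
  for (td in c(FALSE, TRUE)) {
    for (fr in c(FALSE, TRUE)) {
      cand <- build(nInner, rInner, td, fr, perRow = pIn)
      for (flip in c(FALSE, TRUE)) {
        ob <- if (flip) outB[nOutB:1, , drop = FALSE] else outB
        d <- sum((outA[nOutA, ] - cand[1, ])^2) +
          sum((cand[nInner, ] - ob[1, ])^2)
        if (d < bestD) { bestD <- d; inner <- cand; outBBest <- ob }
      }
    }
  }
  outB <- outBBest
  list(coords = rbind(outA, inner, outB),
       innerIdx = nOutA + seq_len(nInner),
       outerIdx = c(seq_len(nOutA), nOutA + nInner + seq_len(nOutB)))
}

## Tapered helical-coil linker path between two anchor points: the coil
## radius follows R_max sin(pi t) so the path leaves both anchors along
## the axis (no wrap-around near the flanking domains) and bulges
## mid-linker, where there is free space.  R_max is solved so the total
## arc length matches the chain contour (spacing per bond).
.linkerCoil <- function(from, to, n, spacing = 0.38) {
  axis <- to - from
  L <- sqrt(sum(axis^2))
  u <- axis / L
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  a <- L / (n + 1)                       # axial advance per bead
  m <- max(8, ceiling(1.2 / a))          # beads per turn: pitch >= ~1.2 nm
  phi <- 2 * pi / m
  place <- function(Rmax) {
    t <- seq_len(n) / (n + 1)
    R <- Rmax * sin(pi * t)
    ang <- seq_len(n) * phi
    sweep(outer(a * seq_len(n), u) +
            outer(R * cos(ang), e1) + outer(R * sin(ang), e2),
          2, from, "+")
  }
  pathLen <- function(Rmax) {
    pts <- rbind(from, place(Rmax), to)
    sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                        pts[-nrow(pts), , drop = FALSE])^2)))
  }
  target <- spacing * (n + 1)
  Rmax <- 0
  if (pathLen(0) < target) {
    hi <- 1
    while (pathLen(hi) < target && hi < 64) hi <- hi * 2
    Rmax <- stats::uniroot(function(r) pathLen(r) - target, c(0, hi),
                           tol = 1e-6)$root
  }
  place(Rmax)
}

## Linker route between two domain anchors with short radial stalks at
## both ends: the chain leaves each domain along the outward normal of
## its anchor bead (clear of the domain body) before coiling across.
.linkerPath <- function(fromAnchor, toAnchor, n, fromCenter, toCenter,
                        spacing = 0.38, nStalk = 3) {
  if (n <= 2 * nStalk + 6)
    return(.linkerCoil(fromAnchor, toAnchor, n, spacing))
  unitv <- function(v) v / sqrt(sum(v^2))
  outF <- unitv(fromAnchor - fromCenter)
  outT <- unitv(toAnchor - toCenter)
  stalkF <- t(vapply(seq_len(nStalk), function(k)
    fromAnchor + spacing * k * outF, numeric(3)))
  stalkT <- t(vapply(seq_len(nStalk), function(k)
    toAnchor + spacing * k * outT, numeric(3)))
  mid <- .linkerCoil(stalkF[nStalk, ], stalkT[nStalk, ], n - 2 * nStalk,
                     spacing)
  rbind(stalkF, mid, stalkT[nStalk:1, , drop = FALSE])
}

#' Synthetic reference coordinates for a multidomain chain
#'
#' Builds a full-chain reference conformation: compact spiral folds for
#' the terminal domains, a hemicylindrical groove-bearing fold for the
#' central domain, and helical-coil linkers with constant inter-bead
#' spacing connecting them.  The groove's concave-face bead indices are
#' returned so a \code{\link{GrooveDefinition}} is known by construction.
#' Geometry is deterministic.  This is a synthetic stand-in for a
#' predicted or experimental reference structure.
#'
#' @param domains domain table (name, start, end, group); default
#'   \code{\link{syntheticDomainTable}}.
#' @param n total chain length; default 373.
#' @param grooveDomain name of the groove-bearing domain; default "STI1".
#' @param separation center-to-center placement distance between
#'   consecutive domain anchors (nm); default 6.
#' @return list with \code{coords} (n x 3 matrix, nm), \code{groove}
#'   (a \code{\link{GrooveDefinition}} in chain numbering), and
#'   \code{boundCoords} (an alternative pose in which the first and last
#'   domains are docked in contact, for bound-complex variants).
#' @export
syntheticReferenceCoords <- function(domains = syntheticDomainTable(),
                                     n = 373, grooveDomain = "STI1",
                                     separation = 6) {
  coords <- matrix(NA_real_, n, 3)
  grooveIdx <- NULL
  ## lay domains left to right along x
  nd <- nrow(domains)
  centers <- lapply(seq_len(nd), function(i) c((i - 1) * separation, 0, 0))
  for (i in seq_len(nd)) {
    span <- domains$start[i]:domains$end[i]
    if (domains$name[i] == grooveDomain) {
      g <- .grooveDomainCoords(length(span))
      dc <- g$coords
      grooveIdx <- list(interior = span[g$innerIdx],
                        exterior = span[g$outerIdx])
    } else {
      dc <- .domainSpiral(length(span))
    }
    coords[span, ] <- sweep(dc, 2, centers[[i]], "+")
  }
  ## linkers between consecutive domains (and free tails, if any)
  domCenter <- function(i) colMeans(coords[domains$start[i]:domains$end[i],
                                           , drop = FALSE])
  for (i in seq_len(nd - 1)) {
    from <- domains$end[i] + 1L
    to <- domains$start[i + 1] - 1L
    if (from > to) next
    coords[from:to, ] <- .linkerPath(coords[domains$end[i], ],
                                     coords[domains$start[i + 1], ],
                                     to - from + 1L,
                                     domCenter(i), domCenter(i + 1))
  }
  if (domains$start[1] > 1) {
    pre <- seq_len(domains$start[1] - 1)
    base <- coords[domains$start[1], ]
    coords[pre, ] <- t(vapply(rev(seq_along(pre)), function(k)
      base + c(-0.38 * k, 0.25, 0), numeric(3)))
  }
  if (domains$end[nd] < n) {
    post <- (domains$end[nd] + 1):n
    base <- coords[domains$end[nd], ]
    coords[post, ] <- t(vapply(seq_along(post), function(k)
      base + c(0.38 * k, 0.25, 0), numeric(3)))
  }

  ## bound pose: dock the last domain against the first (rigid translation)
  ## and re-route the linker leading into it to the docked anchor
  boundCoords <- coords
  first <- domains$start[1]:domains$end[1]
  last <- domains$start[nd]:domains$end[nd]
  comF <- colMeans(coords[first, ])
  comL <- colMeans(coords[last, ])
  target <- comF + c(0, 2.0, 0)   # docked ~2 nm from the first domain's com
  boundCoords[last, ] <- sweep(coords[last, , drop = FALSE], 2,
                               target - comL, "+")
  if (nd > 1) {
    from <- domains$end[nd - 1] + 1L
    to <- domains$start[nd] - 1L
    if (from <= to) {
      cF <- colMeans(boundCoords[domains$start[nd - 1]:domains$end[nd - 1],
                                 , drop = FALSE])
      cT <- colMeans(boundCoords[domains$start[nd]:domains$end[nd],
                                 , drop = FALSE])
      boundCoords[from:to, ] <- .linkerPath(
        boundCoords[domains$end[nd - 1], ],
        boundCoords[domains$start[nd], ], to - from + 1L, cF, cT)
    }
  }
  if (domains$end[nd] < n) {
    post <- (domains$end[nd] + 1):n
    base <- boundCoords[domains$end[nd], ]
    boundCoords[post, ] <- t(vapply(seq_along(post), function(k)
      base + c(0.38 * k, 0.25, 0), numeric(3)))
  }

  group <- rep(NA_character_, n)
  for (i in seq_len(nd))
    group[domains$start[i]:domains$end[i]] <- as.character(domains$group[i])
  coords <- .relaxGeometry(coords, group = group)
  boundCoords <- .relaxGeometry(boundCoords, group = group)
  groove <- if (!is.null(grooveIdx))
    grooveDefinition(grooveIdx$interior, grooveIdx$exterior) else NULL
  list(coords = coords, groove = groove, boundCoords = boundCoords)
}
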
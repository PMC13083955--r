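#' Mass-weighted radius of gyration of one frame
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}}, reported
#' in Angstrom (coordinates are in nm internally; conversion happens only
#' at this reporting boundary).
#'
#' @param coords frame coordinates (beads x 3, nm).
#' @param masses bead masses (Da).
#' @return Rg in Angstrom.
#' @export
radiusOfGyration <- function(coords, masses) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("at least 2 beads required")
  if (length(masses) != nrow(coords)) stop("one mass per bead required")
  if (sum(masses) <= 0) stop("total mass must be positive")
  com <- .centerOfMass(coords, masses)
  rel <- sweep(coords, 2, com)
  10 * sqrt(sum(masses * rowSums(rel^2)) / sum(masses))
}

#' Radius-of-gyration ensemble summary across replicas
#'
#' Per-frame Rg series for every replica, per-replica means, the grand
#' mean with its standard error across replicas, and a pooled normalized
#' histogram of the Rg distribution.
#'
#' @param trajectories a \code{\link{Trajectory}} or list of them.
#' @param masses bead masses (Da).
#' @param breaks histogram break specification (passed to \code{hist}).
#' @return an \code{\link{RgSummary}} (Angstrom).
#' @export
rgSummary <- function(trajectories, masses, breaks = 50) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  if (length(trajectories) < 1) stop("at least one replica required")
  perFrame <- lapply(trajectories, function(tr) {
    nf <- nFrames(tr)
    if (nf == 0) stop("empty replica trajectory")
    vapply(seq_len(nf),
           function(f) radiusOfGyration(frameCoords(tr, f), masses),
           numeric(1))
  })
  replicaMeans <- vapply(perFrame, mean, numeric(1))
  grand <- mean(replicaMeans)
  sem <- if (length(replicaMeans) > 1)
    stats::sd(replicaMeans) / sqrt(length(replicaMeans)) else 0
  pooled <- unlist(perFrame)
  h <- if (length(unique(pooled)) > 1)
    graphics::hist(pooled, breaks = breaks, plot = FALSE)
  else list(mids = unique(pooled), density = Inf)
  new("RgSummary", perFrame = perFrame, replicaMeans = replicaMeans,
      mean = grand, sem = sem,
      histogram = list(mids = h$mids, density = h$density))
}

#' Effective concentration of one tethered domain at another
#'
#' Builds the distribution of center-of-mass distances between two residue
#' spans over all frames and converts the probability of finding the
#' domains at contact range into a concentration: the fraction of frames
#' with distance inside the spherical shell (contactDistance +/-
#' shellWidth/2) divided by the shell volume (4 pi d^2 w) times Avogadro's
#' number.  Reported in micromolar, with a standard error across replicas.
#'
#' @param trajectories a \code{\link{Trajectory}} or list of them.
#' @param masses bead masses (Da) for center-of-mass weighting.
#' @param groupA,groupB disjoint integer residue index vectors.
#' @param contactDistance shell center (nm).
#' @param shellWidth shell width (nm); default 0.2.
#' @return list with \code{concentration} (uM), \code{sem} (uM),
#'   \code{perReplica} (uM), \code{fractionInShell} and \code{emptyShell}
#'   flag (TRUE when no frame falls inside the shell).
#' @export
effectiveConcentration <- function(trajectories, masses, groupA, groupB,
                                   contactDistance, shellWidth = 0.2) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  if (length(intersect(groupA, groupB)))
    stop("groupA and groupB must be disjoint")
  if (contactDistance <= 0) stop("contactDistance must be positive")
  if (shellWidth <= 0) stop("shellWidth must be positive")
  lo <- contactDistance - shellWidth / 2
  hi <- contactDistance + shellWidth / 2
  shellVolNm3 <- 4 * pi * contactDistance^2 * shellWidth
  ## 1 molecule per nm^3 corresponds to 1/(N_A * 1e-24) mol/L
  molarPerNm3 <- 1e24 / .avogadro

  perReplica <- vapply(trajectories, function(tr) {
    nf <- nFrames(tr)
    d <- vapply(seq_len(nf), function(f) {
      fc <- frameCoords(tr, f)
      a <- .centerOfMass(fc[groupA, , drop = FALSE], masses[groupA])
      b <- .centerOfMass(fc[groupB, , drop = FALSE], masses[groupB])
      sqrt(sum((a - b)^2))
    }, numeric(1))
    mean(d > lo & d <= hi)
  }, numeric(1))

  concs <- perReplica / shellVolNm3 * molarPerNm3 * 1e6  # uM
  empty <- all(perReplica == 0)
  if (empty)
    warning("no frames inside the contact shell; effective concentration 0")
  list(concentration = mean(concs),
       sem = if (length(concs) > 1) stats::sd(concs) / sqrt(length(concs))
             else 0,
       perReplica = concs,
       fractionInShell = mean(perReplica),
       emptyShell = empty)
}

#' Create a scattering profile
#'
#' @param q scattering vector (A^-1), strictly increasing and positive.
#' @param I intensities (arbitrary units).
#' @param sigma intensity uncertainties; default zero.
#' @return a \code{\link{ScatteringProfile}}.
#' @export
scatteringProfile <- function(q, I, sigma = numeric(length(q))) {
  new("ScatteringProfile", q = as.numeric(q), I = as.numeric(I),
      sigma = as.numeric(sigma))
}

#' Read a 3-column scattering profile
#'
#' Whitespace-delimited (q, I, sigma I) with '#' comment lines; the common
#' small-angle scattering repository dialect.
#'
#' @param path file path.
#' @return a \code{\link{ScatteringProfile}}.
#' @export
readScatteringProfile <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("q", "I", "sigma"), fill = TRUE)
  tab <- tab[stats::complete.cases(tab[, 1:2]), ]
  tab$sigma[is.na(tab$sigma)] <- 0
  keep <- tab$q > 0
  scatteringProfile(tab$q[keep], tab$I[keep], tab$sigma[keep])
}

#' Guinier fit of a scattering profile
#'
#' Linear fit of \eqn{\ln I} against \eqn{q^2} over the largest low-q
#' window satisfying \eqn{q R_g \le qRgMax}, iterated to self-consistency
#' (the fitted Rg redefines the window until it stabilizes, at most 20
#' rounds, ties resolved toward the smaller window).  The slope gives
#' \eqn{R_g = \sqrt{-3 \times slope}}.
#'
#' @param profile a \code{\link{ScatteringProfile}} (q in A^-1).
#' @param qRgMax Guinier-validity limit; default 1.3.
#' @param minPoints minimum points in the fit window; default 5.
#' @return list with \code{rg} (Angstrom), \code{rgSE}, \code{i0},
#'   \code{window} (index range used), \code{qRgMax} achieved and
#'   \code{residuals}.
#' @export
guinierFit <- function(profile, qRgMax = 1.3, minPoints = 5) {
  stopifnot(is(profile, "ScatteringProfile"))
  q <- profile@q; I <- profile@I
  pos <- I > 0
  if (sum(pos) < minPoints)
    stop("not enough positive intensities for a Guinier fit")
  q <- q[pos]; I <- I[pos]
  x <- q^2; y <- log(I)

  fitWindow <- function(m) stats::lm(y[1:m] ~ x[1:m])
  m <- length(q)
  for (iter in 1:20) {
    fit <- fitWindow(m)
    slope <- stats::coef(fit)[2]
    if (slope >= 0)
      stop("non-decaying profile: Guinier slope is non-negative")
    rg <- sqrt(-3 * slope)
    mNew <- max(minPoints, sum(q * rg <= qRgMax))
    if (mNew >= m) break      # ties and growth resolve to the smaller window
    m <- mNew
  }
  fit <- fitWindow(m)
  slope <- stats::coef(fit)[2]
  if (slope >= 0)
    stop("non-decaying profile: Guinier slope is non-negative")
  rg <- as.numeric(sqrt(-3 * slope))
  slopeSE <- suppressWarnings(summary(fit)$coefficients[2, 2])
  list(rg = rg,
       rgSE = as.numeric(3 * slopeSE / (2 * rg)),
       i0 = as.numeric(exp(stats::coef(fit)[1])),
       window = c(1L, m),
       qRgMax = max(q[1:m]) * rg,
       residuals = stats::residuals(fit))
}
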
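#' Create a groove definition
#'
#' @param interior interior residue indices (>= 4).
#' @param exterior exterior residue indices (disjoint from interior).
#' @param threshold axis-alignment scale for the principal-axis test;
#'   default 1 (candidates must stay within the interior group's own
#'   radial envelope around the dominant axis).
#' @return a \code{\link{GrooveDefinition}}.
#' @export
grooveDefinition <- function(interior, exterior, threshold = 1.0) {
  new("GrooveDefinition", interior = as.integer(interior),
      exterior = as.integer(exterior), threshold = threshold)
}

#' Read a groove definition from a YAML file
#'
#' The file must contain keys \code{interior} and \code{exterior}
#' (residue index lists) and may contain \code{threshold}.
#'
#' @param path YAML file path.
#' @return a \code{\link{GrooveDefinition}}.
#' @export
readGrooveDefinition <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$interior) || is.null(spec$exterior))
    stop("groove file must define 'interior' and 'exterior'")
  grooveDefinition(unlist(spec$interior), unlist(spec$exterior),
                   if (is.null(spec$threshold)) 1.0 else spec$threshold)
}

#' Center of the groove in one frame
#'
#' The arithmetic mean of the interior residue positions, recomputed per
#' frame.
#'
#' @param coords frame coordinates (beads x 3).
#' @param interior interior residue indices.
#' @return numeric length-3 center position.
#' @export
grooveCenter <- function(coords, interior) {
  if (length(interior) < 1) stop("interior residue set must be non-empty")
  colMeans(coords[interior, , drop = FALSE])
}

#' Classify groove occupancy of candidate residues in one frame
#'
#' A candidate is occupied iff all three geometric tests pass:
#' \enumerate{
#'   \item it is strictly closer to the groove center (mean of interior
#'     positions) than the furthest interior residue is;
#'   \item its minimum distance to any interior residue is strictly
#'     smaller than its minimum distance to any exterior residue;
#'   \item its perpendicular distance to the dominant principal axis of
#'     the interior group (the line through the groove center along the
#'     leading eigenvector of the interior covariance) is at most the
#'     interior group's own maximum perpendicular distance scaled by the
#'     groove's alignment threshold.  This accounts for the groove's
#'     curvature: candidates must lie along the groove, not off-axis.
#' }
#'
#' @param coords frame coordinates (beads x 3, covering interior, exterior
#'   and candidate indices).
#' @param groove a \code{\link{GrooveDefinition}}.
#' @param candidates candidate residue indices.
#' @return logical vector, one occupancy flag per candidate.
#' @export
classifyFrame <- function(coords, groove, candidates) {
  stopifnot(is(groove, "GrooveDefinition"))
  interior <- groove@interior
  exterior <- groove@exterior
  if (length(interior) < 4)
    stop("at least 4 interior residues required (degenerate covariance)")
  maxIdx <- max(interior, exterior, candidates)
  if (maxIdx > nrow(coords))
    stop("coordinates missing for residue index ", maxIdx)

  intC <- coords[interior, , drop = FALSE]
  extC <- coords[exterior, , drop = FALSE]
  candC <- coords[candidates, , drop = FALSE]

  center <- colMeans(intC)
  rInterior <- .distToPoint(intC, center)
  rMax <- max(rInterior)

  ## step 1: closer to the center than the furthest interior residue
  dCenter <- .distToPoint(candC, center)
  pass1 <- dCenter < rMax

  ## step 2: closer to an interior than to an exterior residue
  dInt <- apply(candC, 1, function(p) min(.distToPoint(intC, p)))
  dExt <- apply(candC, 1, function(p) min(.distToPoint(extC, p)))
  pass2 <- dInt < dExt

  ## step 3: principal-axis (curvature) criterion
  centered <- sweep(intC, 2, center)
  ev <- eigen(crossprod(centered) / nrow(centered), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  perp <- function(pts) {
    rel <- sweep(pts, 2, center)
    along <- rel %*% axis
    sqrt(pmax(rowSums(rel^2) - as.numeric(along)^2, 0))
  }
  envelope <- max(perp(intC))
  pass3 <- perp(candC) <= groove@threshold * envelope

  as.logical(pass1 & pass2 & pass3)
}

#' Per-residue groove occupancy across replica trajectories
#'
#' For each trajectory, the per-residue occupancy is the fraction of frames
#' in which \code{\link{classifyFrame}} marks the residue occupied; the
#' profile is the mean over replicas with the across-replica standard
#' deviation as the spread.
#'
#' @param trajectories a \code{\link{Trajectory}} or list of them (replicas).
#' @param groove a \code{\link{GrooveDefinition}}.
#' @param residues candidate residue indices.
#' @return an \code{\link{OccupancyProfile}}.
#' @export
occupancyProfile <- function(trajectories, groove, residues) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  if (length(trajectories) < 1) stop("at least one trajectory required")
  residues <- as.integer(residues)
  nb <- unique(vapply(trajectories, nBeads, integer(1)))
  if (length(nb) != 1)
    stop("trajectories have inconsistent bead counts")
  perReplica <- vapply(trajectories, function(tr) {
    nf <- nFrames(tr)
    if (nf == 0) stop("empty trajectory")
    hits <- matrix(FALSE, nf, length(residues))
    for (f in seq_len(nf))
      hits[f, ] <- classifyFrame(frameCoords(tr, f), groove, residues)
    colMeans(hits)
  }, numeric(length(residues)))
  perReplica <- matrix(perReplica, nrow = length(residues))
  prob <- rowMeans(perReplica)
  spread <- if (ncol(perReplica) > 1) apply(perReplica, 1, stats::sd)
            else numeric(length(residues))
  new("OccupancyProfile", residues = residues, probability = prob,
      spread = spread,
      nFrames = vapply(trajectories, nFrames, integer(1)),
      nReplicas = length(trajectories))
}

#' Excess occupancy over an excluded-volume baseline
#'
#' Per-residue ratio of observed to baseline occupancy.  Where the baseline
#' is zero the ratio is flagged: \code{"undefined"} if the observed
#' probability is also zero, \code{"infinite"} otherwise.  No pseudo-count
#' is applied.
#'
#' @param observed an \code{\link{OccupancyProfile}} from the interacting
#'   simulations.
#' @param baseline an \code{\link{OccupancyProfile}} from the
#'   excluded-volume simulations, over the identical residue set.
#' @return an \code{\link{ExcessProfile}}.
#' @export
excessOccupancy <- function(observed, baseline) {
  stopifnot(is(observed, "OccupancyProfile"),
            is(baseline, "OccupancyProfile"))
  if (!identical(observed@residues, baseline@residues))
    stop("observed and baseline profiles cover different residue sets")
  k <- length(observed@residues)
  enrichment <- rep(NA_real_, k)
  status <- rep("ok", k)
  zeroB <- baseline@probability == 0
  status[zeroB & observed@probability == 0] <- "undefined"
  status[zeroB & observed@probability > 0] <- "infinite"
  ok <- !zeroB
  enrichment[ok] <- observed@probability[ok] / baseline@probability[ok]
  new("ExcessProfile", residues = observed@residues,
      enrichment = enrichment, status = status)
}

#' Mean fold enrichment over named residue regions
#'
#' Arithmetic mean of the defined per-residue enrichments within each span;
#' spans with no defined residue are flagged \code{NA} with a warning.
#'
#' @param excess an \code{\link{ExcessProfile}}.
#' @param regions data.frame with columns \code{name}, \code{start},
#'   \code{end} (1-based inclusive residue spans).
#' @return named numeric vector of per-region mean enrichments.
#' @export
regionEnrichment <- function(excess, regions) {
  stopifnot(is(excess, "ExcessProfile"))
  regions <- as.data.frame(regions)
  if (!all(c("name", "start", "end") %in% names(regions)))
    stop("regions must have columns name, start, end")
  out <- stats::setNames(rep(NA_real_, nrow(regions)),
                         as.character(regions$name))
  for (i in seq_len(nrow(regions))) {
    span <- regions$start[i]:regions$end[i]
    if (!all(span %in% excess@residues))
      stop("region ", regions$name[i], " extends beyond the profile range")
    sel <- excess@residues %in% span & excess@status == "ok"
    if (!any(sel)) {
      warning("region ", regions$name[i], " has no defined enrichment")
      next
    }
    out[i] <- mean(excess@enrichment[sel])
  }
  out
}

#' Propose interior residues for a groove-bearing domain (advisory)
#'
#' Heuristic helper: fits the center of curvature of the domain surface
#' (linear least-squares sphere fit) and proposes as groove-lining the
#' residues whose distance to that center is below the median — concave
#' groove-face beads hug the center of curvature, back-side beads stand
#' off it.  The output is advisory; an explicit interior/exterior list
#' remains the source of truth.
#'
#' @param coords reference coordinates (beads x 3, nm).
#' @param span integer residue indices of the domain.
#' @return integer vector of proposed interior residue indices.
#' @export
proposeGrooveInterior <- function(coords, span) {
  dc <- coords[span, , drop = FALSE]
  ## algebraic sphere fit: |p|^2 = 2 p . c + (r^2 - |c|^2)
  A <- cbind(2 * dc, 1)
  b <- rowSums(dc^2)
  center <- qr.solve(A, b)[1:3]
  d <- .distToPoint(dc, center)
  span[d < stats::median(d)]
}
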
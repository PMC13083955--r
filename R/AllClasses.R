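#' @import methods
NULL

## Internal unit conventions: length nm, time ps, energy kJ/mol, mass Da,
## charge elementary charges.  1 kJ/mol == 1 Da nm^2 ps^-2, so kB below makes
## masses, velocities and temperatures mutually consistent.
## Radii of gyration are converted to Angstrom only at reporting boundaries.

#' Chain topology for a one-bead-per-residue coarse-grained chain
#'
#' A \code{ChainTopology} holds everything the simulator needs about a single
#' chain: the amino-acid sequence, per-bead interaction parameters
#' (stickiness lambda, size sigma, charge, mass), harmonic backbone bonds
#' between consecutive beads, elastic-network restraints that keep folded
#' domains rigid, the domain annotations that generated those restraints, and
#' the reference coordinates (nm) the restraint lengths were measured on.
#'
#' Elastic-network pairs are excluded from non-bonded interactions, as are
#' bonded (consecutive) pairs.
#'
#' @slot sequence character vector of one-letter residue codes, one per bead.
#' @slot masses numeric, bead masses (Da).
#' @slot charges numeric, bead charges (elementary charges).
#' @slot lambdas numeric, per-bead stickiness in [0, 1].
#' @slot sigmas numeric, per-bead size (nm).
#' @slot bonds integer matrix (n-1 x 2) of consecutive bead pairs.
#' @slot bondR0,bondK equilibrium length (nm) and force constant
#'   (kJ/mol/nm^2) of the backbone bonds.
#' @slot restraints integer matrix (m x 2) of elastic-network pairs.
#' @slot restraintR0 numeric, reference distances (nm), one per restraint.
#' @slot restraintK numeric(1), elastic-network force constant (kJ/mol/nm^2).
#' @slot domains data.frame with columns \code{name}, \code{start},
#'   \code{end}, \code{group} (1-based inclusive spans).
#' @slot referenceCoords numeric matrix (n x 3), reference bead positions (nm).
#' @exportClass ChainTopology
setClass("ChainTopology",
  representation(
    sequence = "character",
    masses = "numeric",
    charges = "numeric",
    lambdas = "numeric",
    sigmas = "numeric",
    bonds = "matrix",
    bondR0 = "numeric",
    bondK = "numeric",
    restraints = "matrix",
    restraintR0 = "numeric",
    restraintK = "numeric",
    domains = "data.frame",
    referenceCoords = "matrix"
  )
)

setValidity("ChainTopology", function(object) {
  n <- length(object@sequence)
  msg <- character()
  if (length(object@masses) != n || length(object@charges) != n ||
      length(object@lambdas) != n || length(object@sigmas) != n)
    msg <- c(msg, "per-bead parameter vectors must match sequence length")
  if (nrow(object@referenceCoords) != n || ncol(object@referenceCoords) != 3)
    msg <- c(msg, "referenceCoords must be an n x 3 matrix")
  if (nrow(object@bonds) > 0) {
    if (any(object@bonds[, 2] - object@bonds[, 1] != 1L))
      msg <- c(msg, "bonds must connect consecutive beads only")
  }
  if (nrow(object@restraints) > 0) {
    if (length(object@restraintR0) != nrow(object@restraints))
      msg <- c(msg, "one reference distance per restraint required")
    if (any(object@restraintR0 <= 0))
      msg <- c(msg, "restraint reference distances must be positive")
    if (any(abs(object@restraints[, 2] - object@restraints[, 1]) < 2))
      msg <- c(msg, "restraints must not duplicate bonded (consecutive) pairs")
  }
  if (nrow(object@domains) > 0) {
    if (any(object@domains$start < 1) || any(object@domains$end > n))
      msg <- c(msg, "domain spans must lie within the sequence")
  }
  if (length(msg)) msg else TRUE
})

#' Trajectory of bead coordinates
#'
#' Ordered frames of 3D bead coordinates (nm) with their times (ps), the
#' save interval, and a replica identifier.  Velocities (nm/ps) are retained
#' only when the integrator is asked to, for thermostat diagnostics.
#'
#' @slot coords numeric array, beads x 3 x frames (nm).
#' @slot times numeric, frame times (ps), strictly increasing.
#' @slot dt numeric(1), save interval (ps).
#' @slot replica integer(1), replica id.
#' @slot velocities either \code{NULL} or an array like \code{coords} (nm/ps).
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    coords = "array",
    times = "numeric",
    dt = "numeric",
    replica = "integer",
    velocities = "ANY"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    msg <- c(msg, "coords must be a beads x 3 x frames array")
  if (length(object@times) != d[3])
    msg <- c(msg, "one time per frame required")
  if (d[3] > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "frame times must be strictly increasing")
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "all coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' Groove definition: interior/exterior labeling of groove residues
#'
#' Residues of the groove-bearing domain are labeled either interior (lining
#' the hydrophobic groove) or exterior (on the convex back).  The alignment
#' threshold scales the groove's own radial envelope in the principal-axis
#' test of \code{\link{classifyFrame}}; 1 keeps candidates within the
#' interior group's envelope.
#'
#' @slot interior integer vector of interior residue indices (>= 4 of them).
#' @slot exterior integer vector of exterior residue indices.
#' @slot threshold numeric(1), dimensionless axis-alignment scale (> 0).
#' @exportClass GrooveDefinition
setClass("GrooveDefinition",
  representation(
    interior = "integer",
    exterior = "integer",
    threshold = "numeric"
  ),
  prototype(threshold = 1.0)
)

setValidity("GrooveDefinition", function(object) {
  msg <- character()
  if (length(object@interior) < 4)
    msg <- c(msg, "at least 4 interior residues are required (principal axis)")
  if (length(object@exterior) < 1)
    msg <- c(msg, "at least 1 exterior residue is required")
  if (length(intersect(object@interior, object@exterior)))
    msg <- c(msg, "interior and exterior sets must be disjoint")
  if (length(object@threshold) != 1 || object@threshold <= 0)
    msg <- c(msg, "threshold must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Per-residue groove occupancy probabilities
#'
#' Occupancy probability per candidate residue, averaged over replicas, with
#' the across-replica standard deviation as the spread.
#'
#' @slot residues integer, candidate residue indices.
#' @slot probability numeric in [0, 1], one per residue.
#' @slot spread numeric >= 0, across-replica SD, one per residue.
#' @slot nFrames integer, frames per replica.
#' @slot nReplicas integer(1).
#' @exportClass OccupancyProfile
setClass("OccupancyProfile",
  representation(
    residues = "integer",
    probability = "numeric",
    spread = "numeric",
    nFrames = "integer",
    nReplicas = "integer"
  )
)

setValidity("OccupancyProfile", function(object) {
  msg <- character()
  k <- length(object@residues)
  if (length(object@probability) != k || length(object@spread) != k)
    msg <- c(msg, "probability and spread must match residues in length")
  if (any(object@probability < 0 | object@probability > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (any(object@spread < 0))
    msg <- c(msg, "spread must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Per-residue fold enrichment over an excluded-volume baseline
#'
#' Ratio of observed occupancy to baseline occupancy.  Residues where the
#' baseline is zero are flagged: \code{"undefined"} when the observed
#' probability is also zero, \code{"infinite"} when it is positive.  No
#' pseudo-count is applied.
#'
#' @slot residues integer residue indices.
#' @slot enrichment numeric ratios (NA where flagged).
#' @slot status character, one of "ok", "undefined", "infinite".
#' @exportClass ExcessProfile
setClass("ExcessProfile",
  representation(
    residues = "integer",
    enrichment = "numeric",
    status = "character"
  )
)

setValidity("ExcessProfile", function(object) {
  msg <- character()
  k <- length(object@residues)
  if (length(object@enrichment) != k || length(object@status) != k)
    msg <- c(msg, "enrichment and status must match residues in length")
  if (!all(object@status %in% c("ok", "undefined", "infinite")))
    msg <- c(msg, "status must be 'ok', 'undefined' or 'infinite'")
  if (any(object@enrichment[object@status == "ok"] < 0, na.rm = TRUE))
    msg <- c(msg, "defined enrichments must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Small-angle scattering profile
#'
#' (q, I, sigma I) triples for Guinier analysis; q in inverse Angstrom,
#' intensities in arbitrary units.
#'
#' @slot q numeric, strictly increasing, positive (A^-1).
#' @slot I numeric intensities.
#' @slot sigma numeric intensity uncertainties (same length, may be zero).
#' @exportClass ScatteringProfile
setClass("ScatteringProfile",
  representation(q = "numeric", I = "numeric", sigma = "numeric")
)

setValidity("ScatteringProfile", function(object) {
  msg <- character()
  if (length(object@I) != length(object@q) ||
      length(object@sigma) != length(object@q))
    msg <- c(msg, "q, I and sigma must have equal length")
  if (any(object@q <= 0))
    msg <- c(msg, "q values must be positive")
  if (length(object@q) > 1 && any(diff(object@q) <= 0))
    msg <- c(msg, "q must be strictly increasing")
  if (!all(is.finite(object@I)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' NMR relaxation delay-intensity series for one residue
#'
#' @slot delays numeric relaxation delays (s); duplicates allowed and kept
#'   as independent observations.
#' @slot intensities numeric peak heights (arbitrary units).
#' @slot noise numeric(1), spectral noise estimate used for Monte Carlo
#'   error analysis.
#' @exportClass RelaxationSeries
setClass("RelaxationSeries",
  representation(delays = "numeric", intensities = "numeric",
                 noise = "numeric")
)

setValidity("RelaxationSeries", function(object) {
  msg <- character()
  if (length(object@intensities) != length(object@delays))
    msg <- c(msg, "one intensity per delay required")
  if (length(unique(object@delays)) < 2)
    msg <- c(msg, "at least 2 distinct delays are required")
  if (object@noise < 0)
    msg <- c(msg, "noise must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Rigid toy groove system with known geometry
#'
#' A hemicylindrical arrangement of beads: interior beads on the concave
#' face of a half-cylinder of the given radius, exterior beads on the convex
#' back at a larger radius.  The geometry is rigid and gives an unambiguous
#' interior/exterior ground truth with a well-defined principal (long) axis.
#'
#' @slot groove a \code{\link{GrooveDefinition}} over the system's beads.
#' @slot coords numeric matrix (beads x 3), rigid coordinates (nm).
#' @slot radius numeric(1), groove radius (nm).
#' @exportClass ToyGrooveSystem
setClass("ToyGrooveSystem",
  representation(groove = "GrooveDefinition", coords = "matrix",
                 radius = "numeric")
)

#' Radius-of-gyration ensemble summary
#'
#' @slot perFrame list of numeric vectors, per-frame Rg (Angstrom), one
#'   entry per replica.
#' @slot replicaMeans numeric, per-replica mean Rg (Angstrom).
#' @slot mean numeric(1), grand mean across replicas (Angstrom).
#' @slot sem numeric(1), standard error of the mean across replicas.
#' @slot histogram list with \code{mids} and \code{density} of the pooled
#'   normalized Rg distribution.
#' @exportClass RgSummary
setClass("RgSummary",
  representation(perFrame = "list", replicaMeans = "numeric",
                 mean = "numeric", sem = "numeric", histogram = "list")
)

setValidity("RgSummary", function(object) {
  msg <- character()
  if (any(unlist(object@perFrame) < 0))
    msg <- c(msg, "Rg values must be non-negative")
  if (length(object@replicaMeans) &&
      (object@mean < min(object@replicaMeans) - 1e-9 ||
       object@mean > max(object@replicaMeans) + 1e-9))
    msg <- c(msg, "grand mean must lie within the range of replica means")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "ChainTopology", function(object) {
  cat(sprintf("ChainTopology: %d beads, %d bonds, %d elastic restraints\n",
              length(object@sequence), nrow(object@bonds),
              nrow(object@restraints)))
  if (nrow(object@domains) > 0) {
    cat("domains:\n")
    for (i in seq_len(nrow(object@domains)))
      cat(sprintf("  %s: %d-%d (group %s)\n", object@domains$name[i],
                  object@domains$start[i], object@domains$end[i],
                  as.character(object@domains$group[i])))
  }
  cat(sprintf("net charge %+.2f e, mean lambda %.3f\n",
              sum(object@charges), mean(object@lambdas)))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf(
    "Trajectory: %d beads, %d frames, %.4g ps spacing (replica %d)\n",
    d[1], d[3], object@dt, object@replica))
  if (d[3] > 0)
    cat(sprintf("time range %.4g - %.4g ps\n", object@times[1],
                object@times[d[3]]))
})

setMethod("show", "GrooveDefinition", function(object) {
  cat(sprintf(
    "GrooveDefinition: %d interior, %d exterior residues, threshold %.3g\n",
    length(object@interior), length(object@exterior), object@threshold))
})

setMethod("show", "OccupancyProfile", function(object) {
  cat(sprintf(
    "OccupancyProfile: %d residues, %d replica(s), %s frames each\n",
    length(object@residues), object@nReplicas,
    paste(unique(object@nFrames), collapse = "/")))
  cat(sprintf("occupancy range %.4g - %.4g\n",
              min(object@probability), max(object@probability)))
})

setMethod("show", "ExcessProfile", function(object) {
  ok <- object@status == "ok"
  cat(sprintf(
    "ExcessProfile: %d residues (%d defined, %d undefined, %d infinite)\n",
    length(object@residues), sum(ok), sum(object@status == "undefined"),
    sum(object@status == "infinite")))
})

setMethod("show", "ScatteringProfile", function(object) {
  cat(sprintf("ScatteringProfile: %d points, q %.4g - %.4g A^-1\n",
              length(object@q), min(object@q), max(object@q)))
})

setMethod("show", "RgSummary", function(object) {
  cat(sprintf("RgSummary: %d replica(s), mean Rg %.2f +/- %.2f A (SEM)\n",
              length(object@replicaMeans), object@mean, object@sem))
})

setMethod("show", "ToyGrooveSystem", function(object) {
  cat(sprintf(
    "ToyGrooveSystem: %d beads (radius %.3g nm), %d interior / %d exterior\n",
    nrow(object@coords), object@radius, length(object@groove@interior),
    length(object@groove@exterior)))
})
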
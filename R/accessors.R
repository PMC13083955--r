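## Accessor generics and methods.  Slot access from user code is discouraged;
## these are the supported surface.

#' Number of beads in a chain or trajectory
#' @param x a \code{ChainTopology} or \code{Trajectory}.
#' @return integer bead count.
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))

#' @rdname nBeads
setMethod("nBeads", "ChainTopology", function(x) length(x@sequence))

#' @rdname nBeads
setMethod("nBeads", "Trajectory", function(x) dim(x@coords)[1])

#' Number of frames in a trajectory
#' @param x a \code{Trajectory}.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' Frame times of a trajectory (ps)
#' @param x a \code{Trajectory}.
#' @return numeric vector of frame times in ps.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname frameTimes
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' Coordinates of a single frame
#' @param x a \code{Trajectory}.
#' @param i frame index (1-based).
#' @return numeric matrix (beads x 3), nm.
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname frameCoords
setMethod("frameCoords", "Trajectory", function(x, i) {
  stopifnot(i >= 1, i <= dim(x@coords)[3])
  x@coords[, , i, drop = TRUE]
})

#' Full coordinate array of a trajectory
#' @param x a \code{Trajectory}.
#' @return numeric array beads x 3 x frames (nm).
#' @export
setGeneric("coordArray", function(x) standardGeneric("coordArray"))

#' @rdname coordArray
setMethod("coordArray", "Trajectory", function(x) x@coords)

#' Chain sequence as a character vector of one-letter codes
#' @param x a \code{ChainTopology}.
#' @return character vector.
#' @export
setGeneric("chainSequence", function(x) standardGeneric("chainSequence"))

#' @rdname chainSequence
setMethod("chainSequence", "ChainTopology", function(x) x@sequence)

#' Per-bead charges (elementary charges)
#' @param x a \code{ChainTopology}.
#' @return numeric vector.
#' @export
setGeneric("beadCharges", function(x) standardGeneric("beadCharges"))

#' @rdname beadCharges
setMethod("beadCharges", "ChainTopology", function(x) x@charges)

#' Per-bead stickiness parameters
#' @param x a \code{ChainTopology}.
#' @return numeric vector in [0, 1].
#' @export
setGeneric("beadLambdas", function(x) standardGeneric("beadLambdas"))

#' @rdname beadLambdas
setMethod("beadLambdas", "ChainTopology", function(x) x@lambdas)

#' Per-bead sizes (nm)
#' @param x a \code{ChainTopology}.
#' @return numeric vector.
#' @export
setGeneric("beadSigmas", function(x) standardGeneric("beadSigmas"))

#' @rdname beadSigmas
setMethod("beadSigmas", "ChainTopology", function(x) x@sigmas)

#' Per-bead masses (Da)
#' @param x a \code{ChainTopology}.
#' @return numeric vector.
#' @export
setGeneric("beadMasses", function(x) standardGeneric("beadMasses"))

#' @rdname beadMasses
setMethod("beadMasses", "ChainTopology", function(x) x@masses)

#' Elastic-network restraint pairs
#' @param x a \code{ChainTopology}.
#' @return data.frame with columns \code{i}, \code{j}, \code{r0} (nm).
#' @export
setGeneric("restraintPairs", function(x) standardGeneric("restraintPairs"))

#' @rdname restraintPairs
setMethod("restraintPairs", "ChainTopology", function(x) {
  if (nrow(x@restraints) == 0)
    return(data.frame(i = integer(), j = integer(), r0 = numeric()))
  data.frame(i = x@restraints[, 1], j = x@restraints[, 2],
             r0 = x@restraintR0)
})

#' Domain annotation table
#' @param x a \code{ChainTopology}.
#' @return data.frame with columns \code{name}, \code{start}, \code{end},
#'   \code{group}.
#' @export
setGeneric("domainTable", function(x) standardGeneric("domainTable"))

#' @rdname domainTable
setMethod("domainTable", "ChainTopology", function(x) x@domains)

#' Reference coordinates used for restraints and initial conformations
#' @param x a \code{ChainTopology}.
#' @return numeric matrix (beads x 3), nm.
#' @export
setGeneric("referenceCoords", function(x) standardGeneric("referenceCoords"))

#' @rdname referenceCoords
setMethod("referenceCoords", "ChainTopology", function(x) x@referenceCoords)

#' Interior residue indices of a groove definition
#' @param x a \code{GrooveDefinition}.
#' @return integer vector.
#' @export
setGeneric("grooveInterior", function(x) standardGeneric("grooveInterior"))

#' @rdname grooveInterior
setMethod("grooveInterior", "GrooveDefinition", function(x) x@interior)

#' Exterior residue indices of a groove definition
#' @param x a \code{GrooveDefinition}.
#' @return integer vector.
#' @export
setGeneric("grooveExterior", function(x) standardGeneric("grooveExterior"))

#' @rdname grooveExterior
setMethod("grooveExterior", "GrooveDefinition", function(x) x@exterior)

#' Occupancy probabilities as a data.frame
#' @param x an \code{OccupancyProfile}.
#' @return data.frame with columns \code{residue}, \code{probability},
#'   \code{spread}.
#' @export
setGeneric("occupancyTable", function(x) standardGeneric("occupancyTable"))

#' @rdname occupancyTable
setMethod("occupancyTable", "OccupancyProfile", function(x) {
  data.frame(residue = x@residues, probability = x@probability,
             spread = x@spread)
})

#' Fold enrichments as a data.frame
#' @param x an \code{ExcessProfile}.
#' @return data.frame with columns \code{residue}, \code{enrichment},
#'   \code{status}.
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' @rdname enrichmentTable
setMethod("enrichmentTable", "ExcessProfile", function(x) {
  data.frame(residue = x@residues, enrichment = x@enrichment,
             status = x@status)
})

#' Scattering profile as a data.frame
#' @param x a \code{ScatteringProfile}.
#' @return data.frame with columns \code{q}, \code{I}, \code{sigma}.
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname profileTable
setMethod("profileTable", "ScatteringProfile", function(x) {
  data.frame(q = x@q, I = x@I, sigma = x@sigma)
})

#' Mean radius of gyration of an ensemble summary (Angstrom)
#' @param x an \code{RgSummary}.
#' @return named numeric: \code{mean} and \code{sem}.
#' @export
setGeneric("rgMean", function(x) standardGeneric("rgMean"))

#' @rdname rgMean
setMethod("rgMean", "RgSummary", function(x) c(mean = x@mean, sem = x@sem))
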
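#' Build a coarse-grained chain topology
#'
#' Constructs the one-bead-per-residue representation of a chain: per-bead
#' interaction parameters from the residue table, charges from sequence and
#' pH, harmonic bonds between all consecutive beads, and elastic-network
#' restraints within each folded-domain restraint group.  A restraint is
#' placed between every pair of beads \code{(i, j)} with \code{|i - j| >= 2}
#' that belong to the same restraint group and whose reference distance is
#' below \code{enmCutoff}; restrained pairs (and bonded pairs) are excluded
#' from non-bonded interactions in the simulator.
#'
#' Buried-residue stickiness rescaling: residues of folded domains that are
#' buried, approximated at bead resolution as having at least
#' \code{buriedMinNeighbors} reference neighbors within \code{enmCutoff},
#' can have their lambda scaled by \code{buriedLambdaScale}.  The default
#' scale of 1 leaves stickiness untouched.
#'
#' @param sequence one-letter amino-acid string (or character vector).
#' @param params residue parameter table from
#'   \code{\link{loadParameterTable}}.
#' @param referenceCoords numeric matrix (n x 3) of reference bead
#'   positions (nm); restraint lengths are measured on it.
#' @param domains optional data.frame with columns \code{name},
#'   \code{start}, \code{end} and optionally \code{group} (defaults to one
#'   group per domain).  1-based inclusive spans.
#' @param enmCutoff elastic-network distance cutoff (nm); default 0.9.
#' @param enmK elastic-network force constant (kJ/mol/nm^2); default 700.
#' @param bondR0 backbone bond length (nm); default 0.38.
#' @param bondK backbone bond force constant (kJ/mol/nm^2); default 8033.
#' @param pH solution pH used for charge assignment; default 6.8.
#' @param hisPKa histidine pKa; default 6.0.
#' @param includeTermini terminal +1/-1 charges; default TRUE.
#' @param buriedLambdaScale multiplier applied to the lambda of buried
#'   folded-domain beads; default 1 (off).
#' @param buriedMinNeighbors coordination-number threshold defining burial;
#'   default 8.
#' @return a \code{\link{ChainTopology}}.
#' @export
buildTopology <- function(sequence, params = loadParameterTable(),
                          referenceCoords, domains = NULL,
                          enmCutoff = 0.9, enmK = 700,
                          bondR0 = 0.38, bondK = 8033,
                          pH = 6.8, hisPKa = 6.0, includeTermini = TRUE,
                          buriedLambdaScale = 1, buriedMinNeighbors = 8) {
  seq <- .splitSequence(sequence)
  n <- length(seq)
  if (n < 2) stop("sequence must contain at least 2 residues")
  referenceCoords <- as.matrix(referenceCoords)
  if (nrow(referenceCoords) != n || ncol(referenceCoords) != 3)
    stop("referenceCoords must be an n x 3 matrix matching the sequence")
  if (!all(is.finite(referenceCoords)))
    stop("referenceCoords contains non-finite values")
  bad <- setdiff(unique(seq), .aaCodes)
  if (length(bad))
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "))

  domains <- .normalizeDomains(domains, n)
  group <- .restraintGroups(domains, n)

  lambdas <- params[seq, "lambda"]
  sigmas <- params[seq, "sigma"]
  masses <- params[seq, "mass"]
  charges <- assignCharges(seq, pH = pH, hisPKa = hisPKa,
                           includeTermini = includeTermini)

  res <- .enumerateRestraints(referenceCoords, group, enmCutoff)

  if (buriedLambdaScale != 1 && any(!is.na(group))) {
    coordNum <- .coordinationNumbers(referenceCoords, group, enmCutoff)
    buried <- !is.na(group) & coordNum >= buriedMinNeighbors
    lambdas[buried] <- lambdas[buried] * buriedLambdaScale
  }

  bonds <- cbind(seq_len(n - 1), 2:n)
  storage.mode(bonds) <- "integer"

  new("ChainTopology",
      sequence = seq, masses = as.numeric(masses),
      charges = as.numeric(charges), lambdas = as.numeric(lambdas),
      sigmas = as.numeric(sigmas),
      bonds = bonds, bondR0 = bondR0, bondK = bondK,
      restraints = res$pairs, restraintR0 = res$r0, restraintK = enmK,
      domains = domains, referenceCoords = referenceCoords)
}

.normalizeDomains <- function(domains, n) {
  if (is.null(domains) || nrow(as.data.frame(domains)) == 0)
    return(data.frame(name = character(), start = integer(),
                      end = integer(), group = character()))
  domains <- as.data.frame(domains)
  if (!all(c("name", "start", "end") %in% names(domains)))
    stop("domains must have columns name, start, end")
  if (is.null(domains$group)) domains$group <- domains$name
  if (any(domains$start < 1) || any(domains$end > n))
    stop("domain span exceeds sequence length")
  if (any(domains$start > domains$end))
    stop("domain start must not exceed end")
  o <- order(domains$start)
  d <- domains[o, ]
  if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
    stop("domain spans must not overlap")
  domains
}

## Per-bead restraint-group label (NA outside all domains).
.restraintGroups <- function(domains, n) {
  group <- rep(NA_character_, n)
  for (i in seq_len(nrow(domains)))
    group[domains$start[i]:domains$end[i]] <- as.character(domains$group[i])
  group
}

## All (i, j), |i-j| >= 2, same group, reference distance < cutoff.
.enumerateRestraints <- function(coords, group, cutoff) {
  pairs <- matrix(integer(), 0, 2)
  r0 <- numeric()
  if (cutoff > 0 && any(!is.na(group))) {
    for (g in unique(group[!is.na(group)])) {
      idx <- which(!is.na(group) & group == g)
      if (length(idx) < 3) next
      d <- as.matrix(stats::dist(coords[idx, , drop = FALSE]))
      cmb <- which(upper.tri(d), arr.ind = TRUE)
      ii <- idx[cmb[, 1]]; jj <- idx[cmb[, 2]]
      keep <- abs(jj - ii) >= 2 & d[cmb] < cutoff
      if (any(keep)) {
        pr <- cbind(pmin(ii[keep], jj[keep]), pmax(ii[keep], jj[keep]))
        pairs <- rbind(pairs, pr)
        r0 <- c(r0, d[cmb][keep])
      }
    }
  }
  storage.mode(pairs) <- "integer"
  o <- order(pairs[, 1], pairs[, 2])
  list(pairs = pairs[o, , drop = FALSE], r0 = r0[o])
}

.coordinationNumbers <- function(coords, group, cutoff) {
  n <- nrow(coords)
  cn <- integer(n)
  idx <- which(!is.na(group))
  if (length(idx) > 1) {
    d <- as.matrix(stats::dist(coords[idx, , drop = FALSE]))
    cn[idx] <- rowSums(d < cutoff) - 1L
  }
  cn
}

#' Excluded-volume variant of a topology
#'
#' Returns a copy of the topology with all stickiness parameters and (by
#' default) all charges set to zero, leaving only steric repulsion, chain
#' connectivity and the elastic network.  This is the null model for
#' occupancy expected from connectivity and sterics alone.
#'
#' @param topology a \code{\link{ChainTopology}}.
#' @param keepCharges keep electrostatics (default FALSE: the baseline
#'   zeroes both stickiness and charge).
#' @return a \code{\link{ChainTopology}}.
#' @export
excludedVolumeVariant <- function(topology, keepCharges = FALSE) {
  stopifnot(is(topology, "ChainTopology"))
  topology@lambdas <- numeric(length(topology@lambdas))
  if (!keepCharges)
    topology@charges <- numeric(length(topology@charges))
  validObject(topology)
  topology
}

#' Bound-complex variant: merge restraint groups in a bound pose
#'
#' Regenerates the elastic network so that pairs spanning the merged groups
#' are also restrained when they are within the cutoff in the supplied bound
#' pose.  Intra-group restraints of the original topology are kept
#' unchanged; reference coordinates of the merged beads are replaced by the
#' bound-pose coordinates (so initial conformations start bound).
#'
#' @param topology a \code{\link{ChainTopology}}.
#' @param groupsToMerge character vector of >= 2 restraint-group ids.
#' @param mergedReferenceCoords numeric matrix (n x 3, nm); must provide
#'   finite coordinates for every bead of the merged groups (other rows may
#'   be NA).
#' @param enmCutoff elastic-network cutoff (nm); default 0.9.
#' @return a \code{\link{ChainTopology}} with the enlarged restraint set.
#' @export
boundComplexVariant <- function(topology, groupsToMerge,
                                mergedReferenceCoords, enmCutoff = 0.9) {
  stopifnot(is(topology, "ChainTopology"))
  if (length(groupsToMerge) < 2)
    stop("at least two restraint groups must be merged")
  n <- nBeads(topology)
  mergedReferenceCoords <- as.matrix(mergedReferenceCoords)
  if (nrow(mergedReferenceCoords) != n || ncol(mergedReferenceCoords) != 3)
    stop("mergedReferenceCoords must be an n x 3 matrix")
  group <- .restraintGroups(topology@domains, n)
  merged <- which(!is.na(group) & group %in% groupsToMerge)
  if (!length(merged))
    stop("no beads belong to the requested groups: ",
         paste(groupsToMerge, collapse = ", "))
  if (!all(is.finite(mergedReferenceCoords[merged, ])))
    stop("mergedReferenceCoords is missing coordinates for merged-group beads")

  ## inter-group pairs within cutoff in the bound pose
  grpOf <- group[merged]
  d <- as.matrix(stats::dist(mergedReferenceCoords[merged, , drop = FALSE]))
  cmb <- which(upper.tri(d), arr.ind = TRUE)
  ii <- merged[cmb[, 1]]; jj <- merged[cmb[, 2]]
  inter <- grpOf[cmb[, 1]] != grpOf[cmb[, 2]]
  keep <- inter & abs(jj - ii) >= 2 & d[cmb] < enmCutoff
  addPairs <- cbind(pmin(ii[keep], jj[keep]), pmax(ii[keep], jj[keep]))
  storage.mode(addPairs) <- "integer"
  addR0 <- d[cmb][keep]

  topology@restraints <- rbind(topology@restraints, addPairs)
  topology@restraintR0 <- c(topology@restraintR0, addR0)
  ## adopt the bound pose wherever it is supplied (merged domains plus any
  ## re-routed connecting segments), so initial conformations start bound
  ref <- topology@referenceCoords
  have <- which(rowSums(is.finite(mergedReferenceCoords)) == 3)
  ref[have, ] <- mergedReferenceCoords[have, ]
  topology@referenceCoords <- ref
  validObject(topology)
  topology
}
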
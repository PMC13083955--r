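#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are converted from nm to Angstrom.  One MODEL per frame;
#' bead centers are written as CA atoms.
#'
#' @param trajectory a \code{\link{Trajectory}}.
#' @param path output file path.
#' @param sequence optional one-letter codes for residue naming.
#' @return invisibly, the path.
#' @export
writeTrajectoryPDB <- function(trajectory, path, sequence = NULL) {
  stopifnot(is(trajectory, "Trajectory"))
  n <- nBeads(trajectory)
  nf <- nFrames(trajectory)
  xyz <- matrix(0, nf, 3 * n)
  for (f in seq_len(nf))
    xyz[f, ] <- as.numeric(t(frameCoords(trajectory, f))) * 10
  resid <- if (is.null(sequence)) rep("ALA", n)
           else .one2three(.splitSequence(sequence))
  bio3d::write.pdb(file = path, xyz = xyz, resno = seq_len(n),
                   resid = resid, elety = rep("CA", n),
                   chain = rep("A", n))
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Coordinates are converted from Angstrom to nm.  Frame times are assigned
#' from the supplied save interval.
#'
#' @param path PDB file path.
#' @param dt frame spacing (ps); default 1.
#' @param replica replica id; default 1.
#' @return a \code{\link{Trajectory}}.
#' @export
readTrajectoryPDB <- function(path, dt = 1, replica = 1L) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  n <- ncol(xyz) / 3
  coords <- array(0, dim = c(n, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) / 10
  .newTrajectory(coords, times = seq_len(nf) * dt, dt = dt,
                 replica = replica)
}

#' Read a chain sequence from a FASTA file
#'
#' @param path FASTA file path; the first record is used.
#' @return character string of one-letter codes.
#' @export
readSequenceFASTA <- function(path) {
  lines <- readLines(path)
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no FASTA header found in ", path)
  from <- headers[1] + 1
  to <- if (length(headers) > 1) headers[2] - 1 else length(lines)
  toupper(gsub("[^A-Za-z]", "", paste(lines[from:to], collapse = "")))
}

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.one2three <- function(seq) unname(.aa3[seq])
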
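.aaCodes <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Load and validate a residue parameter table
#'
#' Reads a CSV with columns \code{residue} (one-letter code), \code{lambda}
#' (stickiness, dimensionless in [0, 1]), \code{sigma} (bead size, nm),
#' \code{charge} (valence at reference pH, e) and \code{mass} (Da).  The
#' table must contain exactly the 20 standard amino acids.  Numeric values
#' in the bundled default are the published hydropathy-scale defaults for
#' the one-bead-per-residue model family this simulator implements.
#'
#' @param source path to a CSV file; default is the bundled table.
#' @return a validated data.frame with rownames set to the residue codes.
#' @examples
#' params <- loadParameterTable()
#' nrow(params)  # 20
#' @export
loadParameterTable <- function(source = NULL) {
  if (is.null(source))
    source <- system.file("extdata", "residue_parameters.csv",
                          package = "GrooveSim", mustWork = TRUE)
  if (!file.exists(source)) stop("parameter table not found: ", source)
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  required <- c("residue", "lambda", "sigma", "charge", "mass")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("parameter table is missing column(s): ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(tab$residue, .aaCodes)
  if (length(unknown))
    stop("unknown residue code(s) in parameter table: ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(.aaCodes, tab$residue)
  if (length(absent))
    stop("parameter table is missing residue(s): ",
         paste(absent, collapse = ", "))
  if (anyDuplicated(tab$residue))
    stop("duplicate residue rows in parameter table")
  bad <- which(tab$lambda < 0 | tab$lambda > 1)
  if (length(bad))
    stop("lambda outside [0, 1] for residue(s): ",
         paste(tab$residue[bad], collapse = ", "))
  bad <- which(tab$sigma <= 0)
  if (length(bad))
    stop("non-positive sigma for residue(s): ",
         paste(tab$residue[bad], collapse = ", "))
  bad <- which(tab$mass <= 0)
  if (length(bad))
    stop("non-positive mass for residue(s): ",
         paste(tab$residue[bad], collapse = ", "))
  rownames(tab) <- tab$residue
  tab
}

#' Assign per-residue charges from sequence and pH
#'
#' Aspartate and glutamate carry -1 e, lysine and arginine +1 e.  Histidine
#' carries the Henderson-Hasselbalch fractional charge
#' \eqn{1/(1+10^{pH-pKa})}.  Optionally the first bead gains +1 (free amine)
#' and the last bead -1 (free carboxylate).
#'
#' @param sequence character string or vector of one-letter residue codes.
#' @param pH solution pH.
#' @param hisPKa histidine side-chain pKa; default 6.0.
#' @param includeTermini add terminal +1/-1 charges (default TRUE).
#' @return numeric vector of charges (elementary charges), one per residue.
#' @examples
#' assignCharges("DKH", pH = 6.8, includeTermini = FALSE)
#' @export
assignCharges <- function(sequence, pH = 6.8, hisPKa = 6.0,
                          includeTermini = TRUE) {
  seq <- .splitSequence(sequence)
  if (length(seq) == 0) stop("sequence must be non-empty")
  bad <- setdiff(unique(seq), .aaCodes)
  if (length(bad))
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "))
  q <- numeric(length(seq))
  q[seq %in% c("D", "E")] <- -1
  q[seq %in% c("K", "R")] <- 1
  q[seq == "H"] <- 1 / (1 + 10^(pH - hisPKa))
  if (includeTermini) {
    q[1] <- q[1] + 1
    q[length(q)] <- q[length(q)] - 1
  }
  q
}

## Accepts "ACDE" or c("A","C","D","E").
.splitSequence <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) > 1)
    strsplit(sequence, "")[[1]]
  else as.character(sequence)
}
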
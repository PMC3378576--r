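#' Amino-acid column order of a PSI-BLAST PSSM
#'
#' The 20 standard amino acids in the column order used by the ASCII
#' PSI-BLAST position-specific scoring matrix header
#' (A R N D C Q E G H I L K M F P S T W Y V). All feature extraction and
#' PSSM I/O in this package follow this order.
#'
#' @return Character vector of 20 one-letter amino-acid codes.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' The four major structural classes
#'
#' Canonical labels and ordering for the four major SCOP structural
#' classes used throughout the package (confusion matrices, factors,
#' file formats).
#'
#' @return Character vector of the four class labels, in fixed order.
#' @export
#' @examples
#' structuralClasses()
structuralClasses <- function() {
  c("all-alpha", "all-beta", "alpha/beta", "alpha+beta")
}

#' Secondary-structure element codes
#'
#' Per-residue element alphabet: `H` alpha-helix, `A` anti-parallel beta
#' sheet, `P` parallel beta sheet, `C` coil/other.
#'
#' @return Character vector of the four element codes.
#' @export
ssCodes <- function() c("H", "A", "P", "C")

# internal shorthand
.AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.CLASSES <- c("all-alpha", "all-beta", "alpha/beta", "alpha+beta")
.DIMS <- c("x", "y1", "y2", "z")

# required sign of each structural-vector coordinate per class;
# 0 means the coordinate is left at its base value (not clamped).
.REQUIRED_SIGNS <- matrix(
  c( 1, -1,  1,  0,   # all-alpha
    -1,  1, -1,  0,   # all-beta
     0,  1,  1,  1,   # alpha/beta
     0,  1,  1, -1),  # alpha+beta
  nrow = 4, byrow = TRUE,
  dimnames = list(.CLASSES, .DIMS))

.checkClassLabel <- function(classLabel) {
  if (length(classLabel) != 1L || !classLabel %in% .CLASSES)
    stop("unknown structural class '", paste(classLabel, collapse = ","),
         "'; expected one of: ", paste(.CLASSES, collapse = ", "))
  classLabel
}

.asClassFactor <- function(labels) {
  bad <- setdiff(unique(as.character(labels)), .CLASSES)
  if (length(bad))
    stop("unknown structural class label(s): ", paste(bad, collapse = ", "))
  factor(as.character(labels), levels = .CLASSES)
}

# evaluate code under a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
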
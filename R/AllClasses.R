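#' @import methods
NULL

#' PSSM: a position-specific scoring matrix with its query sequence
#'
#' Container for the log-odds block of a PSI-BLAST position-specific scoring
#' matrix. Holds the query (domain or parent-protein) sequence and an
#' `L x 20` integer-valued score matrix whose columns follow the PSI-BLAST
#' header order ([aminoAcids()]). Entry `(i, j)` scores the substitution of
#' the residue at position `i` by amino-acid type `j` during evolution;
#' positive values mark substitutions more frequent than the pseudo-count
#' background.
#'
#' @slot sequence Single character string, length `L`, uppercase.
#' @slot scores Numeric `L x 20` matrix, columns named by [aminoAcids()].
#'
#' @seealso [readPSSM()], [sliceDomain()], [extractFeatures()]
#' @export
setClass("PSSM", slots = c(sequence = "character", scores = "matrix"))

setValidity("PSSM", function(object) {
  msg <- character(0)
  if (length(object@sequence) != 1L || is.na(object@sequence) ||
      nchar(object@sequence) < 1L)
    msg <- c(msg, "sequence must be a single non-empty string")
  if (!is.numeric(object@scores))
    msg <- c(msg, "scores must be numeric")
  else {
    if (ncol(object@scores) != 20L)
      msg <- c(msg, "scores must have exactly 20 columns")
    else if (!identical(colnames(object@scores), .AA))
      msg <- c(msg, "score columns must follow PSI-BLAST order A R N D C Q E G H I L K M F P S T W Y V")
    if (length(object@sequence) == 1L && !is.na(object@sequence) &&
        nrow(object@scores) != nchar(object@sequence))
      msg <- c(msg, "number of score rows must equal sequence length")
    if (any(!is.finite(object@scores)))
      msg <- c(msg, "scores must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PSSM object
#'
#' @param sequence Query sequence (single string); uppercased.
#' @param scores `L x 20` numeric matrix of log-odds scores in PSI-BLAST
#'   column order. Column names are set to [aminoAcids()] if absent.
#' @return A [PSSM-class] object.
#' @export
#' @examples
#' p <- PSSM("ACD", matrix(0L, 3, 20))
#' length(p)
PSSM <- function(sequence, scores) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)) && ncol(scores) == 20L)
    colnames(scores) <- .AA
  new("PSSM", sequence = toupper(as.character(sequence)), scores = scores)
}

#' @describeIn PSSM-class Number of positions `L`.
#' @param x,object A `PSSM`.
#' @export
setMethod("length", "PSSM", function(x) nchar(x@sequence))

#' Accessors for PSSM objects
#'
#' `pssmScores()` returns the `L x 20` log-odds matrix; `querySequence()`
#' the query sequence string.
#'
#' @param x A [PSSM-class] object.
#' @return A matrix or a character string.
#' @export
setGeneric("pssmScores", function(x) standardGeneric("pssmScores"))

#' @rdname pssmScores
#' @export
setMethod("pssmScores", "PSSM", function(x) x@scores)

#' @rdname pssmScores
#' @export
setGeneric("querySequence", function(x) standardGeneric("querySequence"))

#' @rdname pssmScores
#' @export
setMethod("querySequence", "PSSM", function(x) x@sequence)

setMethod("show", "PSSM", function(object) {
  L <- length(object)
  cat("PSSM with", L, "positions\n")
  cat("  sequence:",
      if (L > 40) paste0(substr(object@sequence, 1, 40), "...")
      else object@sequence, "\n")
  cat("  score range: [", min(object@scores), ", ",
      max(object@scores), "]\n", sep = "")
})

#' DomainSet: a labelled collection of protein domains
#'
#' Column-aligned container for a set of domains: identifiers, the
#' 440-dimensional sequence feature matrix, per-residue secondary-structure
#' strings (over [ssCodes()]) and the structural-class factor. This is the
#' unit consumed by [trainModel()], [crossValidate()] and [jackknife()].
#'
#' @slot ids Character vector of domain identifiers.
#' @slot features Numeric `n x 440` matrix, columns named by
#'   [featureNames()].
#' @slot ss Character vector of secondary-structure strings.
#' @slot classLabel Factor with levels [structuralClasses()].
#'
#' @export
setClass("DomainSet",
         slots = c(ids = "character", features = "matrix",
                   ss = "character", classLabel = "factor"))

setValidity("DomainSet", function(object) {
  n <- length(object@ids)
  msg <- character(0)
  if (nrow(object@features) != n || length(object@ss) != n ||
      length(object@classLabel) != n)
    msg <- c(msg, "ids, features, ss and classLabel must align")
  if (ncol(object@features) != 440L)
    msg <- c(msg, "feature matrix must have exactly 440 columns")
  if (!identical(levels(object@classLabel), .CLASSES))
    msg <- c(msg, "classLabel levels must be the four structural classes")
  if (n && any(!grepl("^[HAPC]+$", object@ss)))
    msg <- c(msg, "secondary-structure strings may only use codes H, A, P, C")
  if (length(msg)) msg else TRUE
})

#' Construct a DomainSet
#'
#' @param ids Domain identifiers.
#' @param features `n x 440` feature matrix (see [extractFeatures()]).
#' @param ss Secondary-structure strings over [ssCodes()].
#' @param classLabel Class labels (character or factor over
#'   [structuralClasses()]).
#' @return A [DomainSet-class] object.
#' @export
DomainSet <- function(ids, features, ss, classLabel) {
  features <- as.matrix(features)
  if (is.null(colnames(features)) && ncol(features) == 440L)
    colnames(features) <- featureNames()
  new("DomainSet", ids = as.character(ids), features = features,
      ss = as.character(ss), classLabel = .asClassFactor(classLabel))
}

#' @describeIn DomainSet-class Number of domains.
#' @param x,object A `DomainSet`.
#' @export
setMethod("length", "DomainSet", function(x) length(x@ids))

#' Accessors for DomainSet objects
#'
#' @param x A [DomainSet-class] object.
#' @return `domainIds()` a character vector; `featureMatrix()` the
#'   `n x 440` matrix; `ssStrings()` a character vector; `classLabels()`
#'   a factor over [structuralClasses()].
#' @export
setGeneric("domainIds", function(x) standardGeneric("domainIds"))
#' @rdname domainIds
#' @export
setMethod("domainIds", "DomainSet", function(x) x@ids)
#' @rdname domainIds
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname domainIds
#' @export
setMethod("featureMatrix", "DomainSet", function(x) x@features)
#' @rdname domainIds
#' @export
setGeneric("ssStrings", function(x) standardGeneric("ssStrings"))
#' @rdname domainIds
#' @export
setMethod("ssStrings", "DomainSet", function(x) x@ss)
#' @rdname domainIds
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname domainIds
#' @export
setMethod("classLabels", "DomainSet", function(x) x@classLabel)

#' @describeIn DomainSet-class Subset by index or logical vector.
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "DomainSet", function(x, i, j, ..., drop = FALSE) {
  new("DomainSet", ids = x@ids[i],
      features = x@features[i, , drop = FALSE],
      ss = x@ss[i], classLabel = x@classLabel[i])
})

setMethod("show", "DomainSet", function(object) {
  cat("DomainSet with", length(object), "domains\n")
  if (length(object)) {
    tab <- table(object@classLabel)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
    cat("  features:", ncol(object@features), "per domain\n")
  }
})

#' StrucClassModel: trained structural-class regression model
#'
#' Result of [trainModel()]: the `4 x 441` coefficient matrix mapping a
#' standardized 440-dimensional sequence feature vector (plus intercept)
#' onto the 4-dimensional structural feature vector `(x, y1, y2, z)`,
#' together with the feature standardization parameters and, when forward
#' selection was used, the per-dimension selected feature indices.
#'
#' @slot coefficients Numeric `4 x 441` matrix; rows `x, y1, y2, z`;
#'   columns the 440 features plus `"(Intercept)"`.
#' @slot center,scale Numeric length-440 standardization parameters fit on
#'   the training set.
#' @slot selected Named list of 4 integer vectors: the feature indices with
#'   (potentially) non-zero slopes per dimension.
#' @slot params Parameter list from [strucClassParams()] used at training.
#'
#' @export
setClass("StrucClassModel",
         slots = c(coefficients = "matrix", center = "numeric",
                   scale = "numeric", selected = "list", params = "list"))

setValidity("StrucClassModel", function(object) {
  msg <- character(0)
  if (!identical(dim(object@coefficients), c(4L, 441L)))
    msg <- c(msg, "coefficients must be a 4 x 441 matrix")
  if (!identical(rownames(object@coefficients), .DIMS))
    msg <- c(msg, "coefficient rows must be x, y1, y2, z")
  if (length(object@center) != 440L || length(object@scale) != 440L)
    msg <- c(msg, "center and scale must have length 440")
  if (!identical(names(object@selected), .DIMS))
    msg <- c(msg, "selected must name the four dimensions x, y1, y2, z")
  if (length(msg)) msg else TRUE
})

#' @describeIn StrucClassModel-class The `4 x 441` coefficient matrix.
#' @param object A `StrucClassModel`.
#' @param ... Ignored.
#' @export
setMethod("coef", "StrucClassModel", function(object, ...)
  object@coefficients)

#' Selected feature indices of a trained model
#'
#' @param x A [StrucClassModel-class].
#' @return Named list of 4 integer vectors (one per structural dimension).
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname selectedFeatures
#' @export
setMethod("selectedFeatures", "StrucClassModel", function(x) x@selected)

setMethod("show", "StrucClassModel", function(object) {
  nsel <- vapply(object@selected, length, integer(1))
  cat("StrucClassModel: 4 x 441 coefficient matrix",
      sprintf("(%d coefficients)\n", length(object@coefficients)))
  cat("  features per dimension:",
      paste(names(nsel), nsel, sep = "=", collapse = ", "), "\n")
})
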
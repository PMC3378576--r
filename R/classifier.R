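# Orchestration: the four pairwise regressions on their class subsets, the
# assembled 4 x 441 model, and the sign decision tree.

# per-dimension training subsets as full-class unions, with the sign each
# member class requires for that dimension
.SUBSET_CLASSES <- list(
  x  = c("all-alpha", "all-beta"),
  y1 = c("all-alpha", "alpha/beta", "alpha+beta"),
  y2 = c("all-beta", "alpha/beta", "alpha+beta"),
  z  = c("alpha/beta", "alpha+beta"))

#' Per-dimension training subsets
#'
#' Groups a labelled set of domains into the four training subsets, one per
#' structural dimension: `x` = all-alpha vs all-beta; `y1` = all-alpha vs
#' mixed (alpha/beta and alpha+beta); `y2` = all-beta vs mixed; `z` =
#' alpha/beta vs alpha+beta. Every domain falls into two or three subsets.
#' Each subset records, per member, the sign its class requires for that
#' dimension.
#'
#' @param classLabel Vector (character or factor) of class labels over
#'   [structuralClasses()].
#' @return Named list (`x`, `y1`, `y2`, `z`) of lists with integer `idx`
#'   (positions in `classLabel`) and numeric `requiredSign` (+1/-1).
#' @export
#' @examples
#' s <- buildSubsets(rep(structuralClasses(), each = 10))
#' lengths(lapply(s, `[[`, "idx"))
buildSubsets <- function(classLabel) {
  lab <- .asClassFactor(classLabel)
  if (!length(lab)) stop("empty training set")
  out <- lapply(.DIMS, function(d) {
    member <- .SUBSET_CLASSES[[d]]
    idx <- which(lab %in% member)
    signs <- .REQUIRED_SIGNS[as.character(lab[idx]), d]
    if (length(unique(signs)) < 2L)
      stop("training subset for dimension '", d,
           "' contains only one side; classes present: ",
           paste(intersect(member, unique(as.character(lab))),
                 collapse = ", "))
    list(idx = idx, requiredSign = unname(signs))
  })
  stats::setNames(out, .DIMS)
}

#' Train the structural-class model
#'
#' Full training pipeline: feature standardization is fit once on the whole
#' training set; for each structural dimension, the class-adjusted targets
#' ([makeTarget()]) are built on that dimension's subset, optional
#' sequential forward selection ([forwardSelect()]) picks `select` features,
#' and the two-round iterative regression ([iterativeFit()]) estimates the
#' coefficients. The four coefficient vectors are assembled into the
#' `4 x 441` matrix (440 features + intercept per dimension; slopes of
#' unselected features are zero when selection is on).
#'
#' @param trainingSet A [DomainSet-class] containing all four classes.
#' @param params Parameter list from [strucClassParams()].
#' @param select Optional per-dimension feature budget (e.g. 120); `NULL`
#'   (default) uses all 440 features.
#' @return A [StrucClassModel-class].
#' @export
trainModel <- function(trainingSet, params = strucClassParams(),
                       select = NULL) {
  stopifnot(is(trainingSet, "DomainSet"))
  X <- featureMatrix(trainingSet)
  std <- standardizeFit(X)
  Xs <- standardizeApply(X, std$center, std$scale)
  subsets <- buildSubsets(classLabels(trainingSet))
  targets <- makeTargets(ssStrings(trainingSet),
                         classLabels(trainingSet), params)

  coefs <- matrix(0, nrow = 4L, ncol = 441L,
                  dimnames = list(.DIMS, c(featureNames(), "(Intercept)")))
  selected <- vector("list", 4L)
  names(selected) <- .DIMS
  for (d in .DIMS) {
    sub <- subsets[[d]]
    Xd <- Xs[sub$idx, , drop = FALSE]
    td <- targets[sub$idx, d]
    if (is.null(select)) {
      sel <- seq_len(440L)
    } else {
      sel <- forwardSelect(Xd, td, select)
    }
    design <- cbind(Xd[, sel, drop = FALSE], `(Intercept)` = 1)
    beta <- iterativeFit(design, td, sub$requiredSign,
                         margin = params$margin,
                         ridgeLambda = params$ridgeLambda)
    coefs[d, sel] <- beta[seq_along(sel)]
    coefs[d, 441L] <- beta[length(beta)]
    selected[[d]] <- as.integer(sel)
  }
  new("StrucClassModel", coefficients = coefs, center = std$center,
      scale = std$scale, selected = selected, params = params)
}

#' Predict 4D structural feature vectors
#'
#' Applies the trained model: features are standardized with the training
#' parameters, the intercept is appended, and the `4 x 441` coefficient
#' matrix produces `(x, y1, y2, z)` per domain.
#'
#' @param model A [StrucClassModel-class].
#' @param features A length-440 vector, an `n x 440` matrix, or a
#'   [DomainSet-class].
#' @return Numeric `n x 4` matrix with columns `x, y1, y2, z`.
#' @export
predictVector <- function(model, features) {
  stopifnot(is(model, "StrucClassModel"))
  if (is(features, "DomainSet")) features <- featureMatrix(features)
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  features <- as.matrix(features)
  if (ncol(features) != 440L)
    stop("feature matrix must have 440 columns, got ", ncol(features))
  Xs <- standardizeApply(features, model@center, model@scale)
  out <- cbind(Xs, 1) %*% t(model@coefficients)
  colnames(out) <- .DIMS
  rownames(out) <- rownames(features)
  out
}

#' Structural class from a 4D structural vector
#'
#' The sign decision tree: `x > 0` and `y1 < 0` determine an all-alpha
#' domain; `x <= 0` and `y2 < 0` an all-beta domain; otherwise the domain
#' is mixed and `z > 0` determines alpha/beta, `z <= 0` alpha+beta.
#' Zero coordinates take the `else` branch of each comparison (`x = 0`
#' routes to the beta side, `y = 0` to mixed, `z = 0` to alpha+beta), a
#' fixed convention making the rule total over the whole 4D space.
#'
#' @param v Named length-4 vector `(x, y1, y2, z)` or an `n x 4` matrix as
#'   returned by [predictVector()].
#' @return Factor of class labels over [structuralClasses()].
#' @export
#' @examples
#' decideClass(c(x = 1, y1 = -1, y2 = 0.3, z = 0.2))
decideClass <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1,
                                   dimnames = list(NULL, names(v)))
  v <- as.matrix(v)
  stopifnot(ncol(v) == 4L, all(is.finite(v)))
  if (!is.null(colnames(v)) && all(.DIMS %in% colnames(v)))
    v <- v[, .DIMS, drop = FALSE]
  x <- v[, 1]; y1 <- v[, 2]; y2 <- v[, 3]; z <- v[, 4]
  out <- ifelse(x > 0,
                ifelse(y1 < 0, "all-alpha",
                       ifelse(z > 0, "alpha/beta", "alpha+beta")),
                ifelse(y2 < 0, "all-beta",
                       ifelse(z > 0, "alpha/beta", "alpha+beta")))
  factor(out, levels = .CLASSES)
}

#' Predict structural classes for a set of domains
#'
#' Convenience wrapper combining [predictVector()] and [decideClass()].
#'
#' @param model A [StrucClassModel-class].
#' @param newdata An `n x 440` feature matrix or a [DomainSet-class].
#' @return `data.frame` with columns `domain_id`, `x`, `y1`, `y2`, `z`,
#'   `class`.
#' @export
predictClasses <- function(model, newdata) {
  v <- predictVector(model, newdata)
  ids <- if (is(newdata, "DomainSet")) domainIds(newdata)
         else if (!is.null(rownames(v))) rownames(v)
         else sprintf("domain%03d", seq_len(nrow(v)))
  data.frame(domain_id = ids, x = v[, 1], y1 = v[, 2], y2 = v[, 3],
             z = v[, 4], class = as.character(decideClass(v)),
             row.names = NULL, stringsAsFactors = FALSE)
}
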
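# Confusion-matrix metrics (Sn, Sp, MCC, accuracy, GC2) and the
# cross-validation / jackknife harnesses.

#' Four-class confusion matrix
#'
#' Counts with rows = true class and columns = predicted class, both in the
#' fixed order [structuralClasses()].
#'
#' @param truth,predicted Vectors of class labels (character or factor) of
#'   equal length.
#' @return Integer `4 x 4` matrix.
#' @export
#' @examples
#' confusionCounts(rep(structuralClasses(), 2), rep(structuralClasses(), 2))
confusionCounts <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  t_ <- .asClassFactor(truth)
  p_ <- .asClassFactor(predicted)
  cm <- table(true = t_, predicted = p_)
  matrix(as.integer(cm), 4, 4, dimnames = list(true = .CLASSES,
                                               predicted = .CLASSES))
}

#' Per-class sensitivity, specificity and MCC
#'
#' One-vs-rest metrics for one class of a confusion matrix:
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)` and the Matthews correlation
#' coefficient `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' with `MCC = 0` whenever a denominator factor is zero. A class absent
#' from the truth yields `Sn = NaN` with a warning.
#'
#' @param cm `4 x 4` confusion matrix from [confusionCounts()].
#' @param classLabel One of [structuralClasses()].
#' @return Named numeric vector `c(Sn=, Sp=, MCC=)`.
#' @export
classMetrics <- function(cm, classLabel) {
  .checkClassLabel(classLabel)
  stopifnot(identical(dim(cm), c(4L, 4L)))
  if (sum(cm) == 0) stop("empty confusion matrix")
  i <- match(classLabel, .CLASSES)
  cm <- matrix(as.numeric(cm), 4, 4)   # avoid integer overflow in MCC
  TP <- cm[i, i]
  FN <- sum(cm[i, ]) - TP
  FP <- sum(cm[, i]) - TP
  TN <- sum(cm) - TP - FN - FP
  if (TP + FN == 0) {
    warning("class '", classLabel, "' absent from truth; Sn undefined")
    Sn <- NaN
  } else Sn <- TP / (TP + FN)
  Sp <- if (TN + FP == 0) NaN else TN / (TN + FP)
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  MCC <- if (denom == 0) 0 else (TP * TN - FP * FN) / sqrt(denom)
  c(Sn = Sn, Sp = Sp, MCC = MCC)
}

#' Generalized squared correlation of a confusion matrix
#'
#' Multi-class chi-square agreement measure:
#' `GC2 = chi2 / (N (K - 1))` with `K = 4` classes and
#' `chi2 = sum (O - E)^2 / E` over cells with expected count `E > 0`,
#' where `E` comes from the row/column marginals under independence.
#' Ranges from 0 (predictions independent of truth) to 1 (perfect
#' association; note a label-permuted perfect matrix also scores 1 —
#' GC2 measures association, not accuracy).
#'
#' @param cm `4 x 4` confusion matrix.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' gc2(diag(c(5L, 5L, 5L, 5L)))
gc2 <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(identical(dim(cm), c(4L, 4L)), all(cm >= 0))
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix")
  rs <- rowSums(cm)
  cs <- colSums(cm)
  if (sum(rs > 0) < 2L || sum(cs > 0) < 2L)
    stop("degenerate marginals: need at least 2 non-empty rows and columns")
  E <- outer(rs, cs) / N
  keep <- E > 0
  chi2 <- sum((cm[keep] - E[keep])^2 / E[keep])
  chi2 / (N * (length(.CLASSES) - 1L))
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm `4 x 4` confusion matrix.
#' @return Fraction of correctly classified domains.
#' @export
overallAccuracy <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  sum(diag(as.matrix(cm))) / sum(cm)
}

#' Full metrics report for a confusion matrix
#'
#' @param cm `4 x 4` confusion matrix from [confusionCounts()].
#' @return List with `confusion` (the matrix), `perClass` (data.frame of
#'   Sn, Sp, MCC per class), `accuracy` and `gc2`.
#' @export
metricsReport <- function(cm) {
  per <- t(vapply(.CLASSES, function(cl) classMetrics(cm, cl), numeric(3)))
  list(confusion = cm,
       perClass = data.frame(class = .CLASSES, Sn = per[, "Sn"],
                             Sp = per[, "Sp"], MCC = per[, "MCC"],
                             row.names = NULL),
       accuracy = overallAccuracy(cm),
       gc2 = gc2(cm))
}

#' Stratified k-fold cross-validation
#'
#' Splits the domains into `kFolds` stratified folds (per-class fold sizes
#' differ by at most one), trains the full model on each training portion
#' and predicts the held-out fold, then scores the pooled confusion matrix.
#' Deterministic given `seed`.
#'
#' @param dataset A [DomainSet-class] with every class having at least
#'   `kFolds` members.
#' @param kFolds Number of folds (default 10).
#' @param seed Integer seed driving the fold assignment.
#' @param params,select Passed to [trainModel()].
#' @return A [metricsReport()] list with extra elements `folds` (fold id
#'   per domain) and `perFold` (per-fold confusion matrices).
#' @export
crossValidate <- function(dataset, kFolds = 10, seed = 1,
                          params = strucClassParams(), select = NULL) {
  stopifnot(is(dataset, "DomainSet"))
  lab <- classLabels(dataset)
  small <- table(lab) < kFolds
  if (any(small))
    stop("class(es) with fewer members than kFolds = ", kFolds, ": ",
         paste(names(which(small)), collapse = ", "))
  folds <- integer(length(dataset))
  .withSeed(seed, {
    for (cl in .CLASSES) {
      ii <- sample(which(lab == cl))
      folds[ii] <- rep_len(seq_len(kFolds), length(ii))
    }
  })
  truth <- character(0); pred <- character(0)
  perFold <- vector("list", kFolds)
  for (f in seq_len(kFolds)) {
    test <- folds == f
    model <- trainModel(dataset[!test], params, select)
    p <- predictClasses(model, dataset[test])
    truth <- c(truth, as.character(lab[test]))
    pred <- c(pred, p$class)
    perFold[[f]] <- confusionCounts(lab[test], p$class)
  }
  rep <- metricsReport(confusionCounts(truth, pred))
  rep$folds <- folds
  rep$perFold <- perFold
  rep
}

#' Jackknife (leave-one-out) evaluation
#'
#' Trains `n` models, each leaving out one domain and predicting it, and
#' scores the pooled confusion matrix. The most stringent resampling test
#' of the pipeline; use [crossValidate()] for larger sets.
#'
#' @param dataset A [DomainSet-class]; leaving out any single domain must
#'   leave all four classes represented.
#' @param params,select Passed to [trainModel()].
#' @return A [metricsReport()] list.
#' @export
jackknife <- function(dataset, params = strucClassParams(), select = NULL) {
  stopifnot(is(dataset, "DomainSet"))
  n <- length(dataset)
  if (any(table(classLabels(dataset)) < 2L))
    stop("jackknife needs at least 2 domains per class")
  pred <- character(n)
  for (i in seq_len(n)) {
    model <- trainModel(dataset[-i], params, select)
    pred[i] <- predictClasses(model, dataset[i])$class
  }
  metricsReport(confusionCounts(classLabels(dataset), pred))
}
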
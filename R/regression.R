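# Least-squares machinery: feature standardization, QR-based multiple
# linear regression with a ridge fallback for rank-deficient designs, the
# two-round iterative target-refinement fit, and sequential forward
# stepwise feature selection.

#' Fit feature standardization parameters
#'
#' Per-column mean and standard deviation of a raw feature matrix.
#' Zero-variance columns get scale 1 so that standardization maps them to
#' all-zero columns. The feature groups differ by orders of magnitude
#' (compositions vs squared integer scores), so regression is always run on
#' standardized features.
#'
#' @param X Raw numeric matrix (`n >= 2` rows).
#' @return List with numeric vectors `center` and `scale`.
#' @export
standardizeFit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows to fit standardization")
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

#' Apply feature standardization
#'
#' @param X Raw numeric matrix.
#' @param center,scale Vectors from [standardizeFit()].
#' @return Standardized matrix of the same shape.
#' @export
standardizeApply <- function(X, center, scale) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == length(center), ncol(X) == length(scale))
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

#' Least-squares multiple linear regression
#'
#' Minimises `sum((t - X b)^2)` over `b` via a QR decomposition. `X` must
#' already contain the intercept column if one is wanted. When the design
#' is rank deficient (e.g. more features than samples) a ridge-regularised
#' solve with strength `ridgeLambda` is used instead and a message is
#' emitted.
#'
#' @param X Design matrix (`n x p`, intercept column included by caller).
#' @param t Numeric target vector of length `n`.
#' @param ridgeLambda Ridge strength of the rank-deficiency fallback.
#' @return Numeric coefficient vector of length `p`.
#' @export
#' @examples
#' X <- cbind(1, matrix(rnorm(40), 20, 2))
#' b <- c(0.5, 1, -2)
#' fitMLR(X, as.vector(X %*% b))
fitMLR <- function(X, t, ridgeLambda = 1e-8) {
  X <- as.matrix(X)
  t <- as.numeric(t)
  if (nrow(X) == 0L) stop("cannot fit a regression on 0 samples")
  stopifnot(length(t) == nrow(X))
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    message("rank-deficient design (rank ", dec$rank, " < ", ncol(X),
            " columns): applying ridge fallback, lambda = ", ridgeLambda)
    G <- crossprod(X)
    diag(G) <- diag(G) + ridgeLambda
    beta <- solve(G, crossprod(X, t))
    return(as.vector(beta))
  }
  as.vector(qr.coef(dec, t))
}

#' Two-round iterative MLR with target refinement
#'
#' Round 1 fits the initial targets by ordinary least squares. The targets
#' are then rebuilt from the round-1 fitted values: where a fitted value
#' already carries the sign its domain's class requires, with magnitude at
#' least `margin`, the fitted value itself becomes the new target
#' (self-consistency); otherwise the target is reset to
#' `requiredSign * margin`. Round 2 refits and its coefficients are
#' returned. Refining toward the model's own well-placed predictions relaxes
#' the arbitrary initial target magnitudes while the sign/margin guard keeps
#' every training domain on the correct side of the decision boundary.
#'
#' @param X Design matrix (intercept included).
#' @param t Initial target vector.
#' @param requiredSign Vector of `+1`/`-1` per row: the sign the domain's
#'   class requires for this structural dimension.
#' @param margin Positive sign margin.
#' @param ridgeLambda Passed to [fitMLR()].
#' @return Numeric coefficient vector (round-2 coefficients).
#' @export
iterativeFit <- function(X, t, requiredSign, margin = 0.05,
                         ridgeLambda = 1e-8) {
  X <- as.matrix(X)
  stopifnot(length(requiredSign) == nrow(X),
            all(requiredSign %in% c(-1, 1)), margin > 0)
  b1 <- fitMLR(X, t, ridgeLambda)
  fitted <- as.vector(X %*% b1)
  ok <- sign(fitted) == requiredSign & abs(fitted) >= margin
  t2 <- ifelse(ok, fitted, requiredSign * margin)
  fitMLR(X, t2, ridgeLambda)
}

#' Sequential forward stepwise feature selection
#'
#' Greedy forward selection of `m` features for one regression target. The
#' first feature maximises the absolute Pearson correlation with the target
#' (a zero-variance feature is assigned correlation 0); each subsequent
#' feature minimises the residual sum of squares of the refit model that
#' includes it together with the already-chosen features (intercept always
#' in). Ties are broken toward the lowest feature index. Implemented by
#' Gram-Schmidt residualisation, so each step costs one pass over the
#' remaining columns while being exactly equivalent to refitting.
#'
#' @param X Feature matrix (`n x p`, no intercept column).
#' @param t Target vector.
#' @param m Feature budget, `0 <= m <= p`.
#' @return Integer vector of `m` column indices of `X`, in selection order.
#' @export
#' @examples
#' X <- matrix(rnorm(200), 20, 10)
#' t <- X[, 3] + rnorm(20, sd = 0.01)
#' forwardSelect(X, t, 2)[1] == 3
forwardSelect <- function(X, t, m) {
  X <- as.matrix(X)
  t <- as.numeric(t)
  p <- ncol(X)
  m <- as.integer(m)
  if (m < 0L || m > p)
    stop("feature budget m = ", m, " outside 0..", p)
  if (m == 0L) return(integer(0))
  stopifnot(nrow(X) == length(t))

  # correlations, with zero-variance features scored 0
  sds <- apply(X, 2, stats::sd)
  cors <- rep(0, p)
  live <- is.finite(sds) & sds > 0 & stats::sd(t) > 0
  if (any(live))
    cors[live] <- abs(stats::cor(X[, live, drop = FALSE], t))
  cors[!is.finite(cors)] <- 0
  first <- which.max(cors)               # ties -> lowest index

  selected <- integer(m)
  selected[1L] <- first
  R <- sweep(X, 2, colMeans(X))          # centered: intercept absorbed
  r <- t - mean(t)
  tol <- 1e-12
  orth <- function(s) {
    q <- R[, s]
    qn <- sum(q^2)
    if (qn > tol) {
      r <<- r - q * (sum(q * r) / qn)
      R <<- R - q %o% (as.vector(crossprod(q, R)) / qn)
    }
    R[, s] <<- 0
  }
  orth(first)
  if (m > 1L) for (step in 2L:m) {
    nrm <- colSums(R^2)
    red <- as.vector(crossprod(R, r))^2
    score <- ifelse(nrm > tol, red / nrm, 0)
    score[selected[seq_len(step - 1L)]] <- -Inf
    nxt <- which.max(score)
    selected[step] <- nxt
    orth(nxt)
  }
  selected
}
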
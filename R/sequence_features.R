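# Feature families extracted from a PSSM. Throughout, P+ = max(P, 0) and
# P- = min(P, 0); L is the domain length; columns follow aminoAcids().

.G5_LAGS <- 1:7
.G34_LAGS <- 1:10
.G6_SEGMENTS <- c(4L, 8L, 16L)

#' Names of the 440 sequence features
#'
#' Stable, unique, group-prefixed labels for the 440-dimensional sequence
#' feature vector, in the fixed concatenation order
#' G1 (20) | G2 (40) | G3 (20) | G4 (20) | G5 (140) | G6 (120) | G7 (80).
#'
#' @return Character vector of length 440.
#' @export
#' @examples
#' head(featureNames())
featureNames <- function() {
  c(paste0("G1.comp.", .AA),
    paste0("G2.posMean.", .AA), paste0("G2.negMean.", .AA),
    paste0("G3.hydroPos.k", .G34_LAGS), paste0("G3.hydroNeg.k", .G34_LAGS),
    paste0("G4.massPos.k", .G34_LAGS), paste0("G4.massNeg.k", .G34_LAGS),
    paste0("G5.auto.", rep(.AA, each = length(.G5_LAGS)),
           ".k", rep(.G5_LAGS, 20)),
    paste0("G6.segPos.k", rep(.G6_SEGMENTS, each = 20), ".", rep(.AA, 3)),
    paste0("G6.segNeg.k", rep(.G6_SEGMENTS, each = 20), ".", rep(.AA, 3)),
    paste0("G7.", rep(.AA, each = 4),
           ".", rep(c("mean", "spread", "bias", "edge"), 20)))
}

#' Square-root amino-acid composition (G1, 20 features)
#'
#' `sqrt(N_j / L)` per amino-acid type `j`, where `N_j` counts occurrences
#' of type `j` in the query sequence and `L` is the sequence length.
#' Non-standard letters (e.g. `X`) contribute to `L` but to no `N_j`.
#'
#' @param sequence Query sequence (single string).
#' @return Named numeric vector of 20 values in `[0, 1]`.
#' @export
#' @examples
#' g1Composition("AAAA")["A"]
g1Composition <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || nchar(sequence) < 1L)
    stop("sequence must be a single non-empty string")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  counts <- vapply(.AA, function(a) sum(chars == a), numeric(1))
  sqrt(counts / length(chars))
}

#' Average positive and negative mutation scores (G2, 40 features)
#'
#' Per amino-acid type `j`, the mean over positions of the positive part and
#' of the negative part of the PSSM column: `pos_j = mean_i P+_{i,j}` and
#' `neg_j = mean_i P-_{i,j}`. These summarise how favourably (and how
#' unfavourably) the domain mutates into each residue type.
#'
#' @param pssm A [PSSM-class] object.
#' @return Named numeric vector of 40 values (20 positive-part means, then
#'   20 negative-part means).
#' @export
g2MutationMeans <- function(pssm) {
  P <- pssmScores(pssm)
  c(colMeans(pmax(P, 0)), colMeans(pmin(P, 0)))
}

# shared autocorrelation of a per-position signal at the given lags;
# lags with no valid pair (k >= L) are emitted as 0 with a warning
.signalAutocorr <- function(h, lags, what) {
  L <- length(h)
  short <- lags >= L
  if (any(short))
    warning("domain of length ", L, " shorter than ", what,
            " lag(s) ", paste(lags[short], collapse = ","),
            "; emitting 0 for those features")
  vapply(lags, function(k) {
    if (k >= L) return(0)
    sum(h[1:(L - k)] * h[(1 + k):L]) / (L - k)
  }, numeric(1))
}

#' Hydrophobicity autocorrelation features (G3, 20 features)
#'
#' PSSM-weighted hydrophobicity autocorrelation at lags 1..10. Position `i`
#' gets the profile-weighted hydrophobicity `h+_i = sum_j H_j P+_{i,j}`
#' (and `h-_i` from the negative part); the feature at lag `k` is
#' `mean_i h_i h_{i+k}` over the `L - k` valid pairs.
#'
#' @param pssm A [PSSM-class] object.
#' @param scale Named hydrophobicity table over [aminoAcids()]
#'   (default Kyte-Doolittle).
#' @return Named numeric vector of 20 values (10 positive-part lags, then
#'   10 negative-part lags).
#' @export
g3HydrophobicityAutocorr <- function(pssm, scale = kyteDoolittle()) {
  .weightedAutocorr(pssm, scale, "hydrophobicity")
}

#' Side-chain-mass autocorrelation features (G4, 20 features)
#'
#' As [g3HydrophobicityAutocorr()] with the side-chain mass table in place
#' of the hydrophobicity index.
#'
#' @param pssm A [PSSM-class] object.
#' @param scale Named side-chain-mass table over [aminoAcids()].
#' @return Named numeric vector of 20 values.
#' @export
g4MassAutocorr <- function(pssm, scale = sideChainMasses()) {
  .weightedAutocorr(pssm, scale, "side-chain mass")
}

.weightedAutocorr <- function(pssm, scale, what) {
  P <- pssmScores(pssm)
  w <- scale[.AA]
  hp <- as.vector(pmax(P, 0) %*% w)
  hn <- as.vector(pmin(P, 0) %*% w)
  c(.signalAutocorr(hp, .G34_LAGS, what),
    .signalAutocorr(hn, .G34_LAGS, what))
}

#' Per-column PSSM autocorrelation (G5, 140 features)
#'
#' Raw PSSM score autocorrelation, per amino-acid column `j` and lag
#' `k = 1..7`: `mean_i P_{i,j} P_{i+k,j}` over the `L - k` valid pairs.
#' Ordered column-major: all 7 lags of column A, then R, ...
#'
#' @param pssm A [PSSM-class] object.
#' @return Named numeric vector of 140 values.
#' @export
g5PssmAutocorr <- function(pssm) {
  P <- pssmScores(pssm)
  L <- nrow(P)
  short <- .G5_LAGS >= L
  if (any(short))
    warning("domain of length ", L, " shorter than PSSM autocorrelation ",
            "lag(s) ", paste(.G5_LAGS[short], collapse = ","),
            "; emitting 0 for those features")
  perLag <- vapply(.G5_LAGS, function(k) {
    if (k >= L) return(numeric(20))
    colSums(P[1:(L - k), , drop = FALSE] *
            P[(1 + k):L, , drop = FALSE]) / (L - k)
  }, numeric(20))                        # 20 x 7
  out <- as.vector(t(perLag))            # column-major over AA, lag inner
  names(out) <- paste0("G5.auto.", rep(.AA, each = 7), ".k", rep(.G5_LAGS, 20))
  out
}

#' Segment mean-square features (G6, 120 features)
#'
#' For segment lengths `k` in {4, 8, 16} and each amino-acid column `j`:
#' the mean over all length-`k` windows of the squared window average of
#' `P+` (and, separately, of `P-`):
#' `pos_{j,k} = mean_t ( mean_{i in window t} P+_{i,j} )^2`.
#' Captures locally sustained substitution preference along the backbone.
#'
#' @param pssm A [PSSM-class] object.
#' @return Named numeric vector of 120 values (60 positive-part, then 60
#'   negative-part; within each part, the 20 columns for k=4, then k=8,
#'   then k=16).
#' @export
g6SegmentMeanSquare <- function(pssm) {
  P <- pssmScores(pssm)
  L <- nrow(P)
  block <- function(M) {
    cs <- apply(M, 2, cumsum)
    cs <- rbind(0, cs)
    unlist(lapply(.G6_SEGMENTS, function(k) {
      if (L < k) {
        warning("domain of length ", L, " shorter than segment length ", k,
                "; emitting 0 for that block")
        return(stats::setNames(numeric(20), .AA))
      }
      nw <- L - k + 1L
      wm <- (cs[(k + 1L):(L + 1L), , drop = FALSE] -
             cs[1:nw, , drop = FALSE]) / k
      colSums(wm^2) / nw
    }))
  }
  c(block(pmax(P, 0)), block(pmin(P, 0)))
}

#' Mutation position-preference features (G7, 80 features)
#'
#' Where along the chain each amino-acid type is favoured. For column `j`,
#' with weights `w_i = P+_{i,j}`, `W = sum(w)` and relative positions
#' `r_i = i / L`: (a) weighted mean position `sum(w r) / W`; (b) weighted
#' positional spread `sqrt(sum(w (r - mean)^2) / W)`; (c) terminal bias —
#' first-half minus second-half weight, normalised by `W` (halves split at
#' `ceiling(L/2)`); (d) edge preference `sum(w |r - 0.5|) / W`. A column
#' with `W = 0` emits the neutral values `(0.5, 0, 0, 0.25)`.
#'
#' @param pssm A [PSSM-class] object.
#' @return Named numeric vector of 80 values (4 statistics per column).
#' @export
g7PositionPreference <- function(pssm) {
  P <- pssmScores(pssm)
  L <- nrow(P)
  r <- seq_len(L) / L
  firstHalf <- seq_len(L) <= ceiling(L / 2)
  out <- vapply(seq_len(20L), function(j) {
    w <- pmax(P[, j], 0)
    W <- sum(w)
    if (W == 0) return(c(0.5, 0, 0, 0.25))
    m <- sum(w * r) / W
    c(m,
      sqrt(sum(w * (r - m)^2) / W),
      (sum(w[firstHalf]) - sum(w[!firstHalf])) / W,
      sum(w * abs(r - 0.5)) / W)
  }, numeric(4))
  stats::setNames(as.vector(out),
                  paste0("G7.", rep(.AA, each = 4), ".",
                         rep(c("mean", "spread", "bias", "edge"), 20)))
}

#' Extract the 440-dimensional sequence feature vector
#'
#' Concatenates the seven feature families computed from a domain's PSSM
#' (and its query sequence) in the fixed order G1|G2|G3|G4|G5|G6|G7,
#' 20+40+20+20+140+120+80 = 440 features, named by [featureNames()]. The
#' intercept is *not* part of the vector; it is appended as the 441st slot
#' at regression time.
#'
#' @param pssm A [PSSM-class] object for the domain (use [sliceDomain()] to
#'   cut a domain out of a parent-protein PSSM).
#' @param params Parameter list from [strucClassParams()]; supplies the
#'   hydrophobicity and side-chain-mass tables.
#' @return Named numeric vector of length 440.
#' @export
#' @examples
#' p <- PSSM("ACDEFGHIKLMNPQRSTVWY", matrix(1L, 20, 20))
#' length(extractFeatures(p))
extractFeatures <- function(pssm, params = strucClassParams()) {
  stopifnot(is(pssm, "PSSM"))
  out <- c(g1Composition(querySequence(pssm)),
           g2MutationMeans(pssm),
           g3HydrophobicityAutocorr(pssm, params$hydrophobicity),
           g4MassAutocorr(pssm, params$sideChainMass),
           g5PssmAutocorr(pssm),
           g6SegmentMeanSquare(pssm),
           g7PositionPreference(pssm))
  stats::setNames(out, featureNames())
}
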
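.checkSS <- function(ss) {
  if (length(ss) != 1L || is.na(ss) || nchar(ss) < 1L)
    stop("secondary-structure string must be a single non-empty string")
  if (!grepl("^[HAPC]+$", ss))
    stop("secondary-structure string may only contain codes H, A, P, C")
  ss
}

#' Sliding-window secondary-structure composition
#'
#' Average composition of the three structured elements (helix `H`,
#' anti-parallel sheet `A`, parallel sheet `P`) over all length-`k` windows
#' of a secondary-structure string: for element `i`,
#' \deqn{\bar f_i(k) = \frac{1}{L-k+1} \sum_{t=1}^{L-k+1} n_{i,t} / k,}
#' where `n_{i,t}` counts element `i` in the window starting at `t`. With
#' `k = L` this reduces to the whole-sequence content of each element; for
#' an element distributed uniformly along the sequence it equals the
#' whole-sequence content at any `k`, so departures from that value capture
#' the spatial organisation of the elements.
#'
#' @param ss Secondary-structure string over [ssCodes()].
#' @param k Window length in residues, `1 <= k <= nchar(ss)`.
#' @return Named numeric vector `c(H=, A=, P=)` of average window fractions.
#' @export
#' @examples
#' windowComposition("HHHHCCAA", 4)
windowComposition <- function(ss, k) {
  .checkSS(ss)
  L <- nchar(ss)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > L)
    stop("window length k must satisfy 1 <= k <= L (L = ", L, ")")
  chars <- strsplit(ss, "", fixed = TRUE)[[1]]
  nw <- L - k + 1L
  vapply(c(H = "H", A = "A", P = "P"), function(e) {
    cs <- c(0, cumsum(chars == e))
    sum(cs[(k + 1L):(L + 1L)] - cs[1:nw]) / (k * nw)
  }, numeric(1))
}

#' Base structural scores of a domain
#'
#' Maps the window composition of a secondary-structure string onto the raw
#' (un-adjusted) 4-dimensional structural scores. With `c_H`, `c_A`, `c_P`
#' the window compositions at window length `min(k0, L)`:
#' \itemize{
#'   \item `x  = c_H - (c_A + c_P)` — helix vs sheet contrast
#'     (all-alpha vs all-beta);
#'   \item `y1 = (c_A + c_P) - theta` — sheet presence (all-alpha vs mixed);
#'   \item `y2 = c_H - theta` — helix presence (all-beta vs mixed);
#'   \item `z  = (c_P - c_A) / (c_P + c_A + delta)` — parallel vs
#'     anti-parallel sheet contrast (alpha/beta vs alpha+beta).
#' }
#'
#' @param ss Secondary-structure string.
#' @param params Parameter list from [strucClassParams()].
#' @return Named numeric vector `c(x=, y1=, y2=, z=)`.
#' @export
#' @examples
#' baseScores(strrep("H", 40))
baseScores <- function(ss, params = strucClassParams()) {
  .checkSS(ss)
  L <- nchar(ss)
  comp <- windowComposition(ss, min(params$k0, L))
  cH <- comp[["H"]]; cA <- comp[["A"]]; cP <- comp[["P"]]
  c(x  = cH - (cA + cP),
    y1 = (cA + cP) - params$theta,
    y2 = cH - params$theta,
    z  = (cP - cA) / (cP + cA + params$delta))
}

#' Class-adjusted 4D structural target vector
#'
#' Builds the training target `(x, y1, y2, z)` for a domain of known class.
#' Each coordinate starts from its base score ([baseScores()]) and is then
#' adjusted by the structural-class-dependent rule: where the class requires
#' the coordinate to carry a given sign, a base score on the wrong side of
#' the sign margin `m` is clamped to `+/- m`; coordinates the class places
#' no requirement on are kept at their base value. Required sign patterns:
#' all-alpha `x>0, y1<0, y2>0`; all-beta `x<0, y1>0, y2<0`; alpha/beta
#' `y1>0, y2>0, z>0`; alpha+beta `y1>0, y2>0, z<0`.
#'
#' The clamp is idempotent: re-applying it to an emitted target changes
#' nothing.
#'
#' @param ss Secondary-structure string of the domain.
#' @param classLabel One of [structuralClasses()].
#' @param params Parameter list from [strucClassParams()]; `margin` is the
#'   clamp margin `m`.
#' @return Named numeric vector `c(x=, y1=, y2=, z=)` obeying the class's
#'   sign pattern.
#' @export
#' @examples
#' makeTarget(strrep("H", 40), "all-alpha")
makeTarget <- function(ss, classLabel, params = strucClassParams()) {
  .checkClassLabel(classLabel)
  base <- baseScores(ss, params)
  .clampToSigns(base, .REQUIRED_SIGNS[classLabel, ], params$margin)
}

.clampToSigns <- function(v, signs, m) {
  out <- v
  pos <- signs > 0 & v < m
  neg <- signs < 0 & v > -m
  out[pos] <- m
  out[neg] <- -m
  out
}

#' Target matrix for a set of domains
#'
#' Vectorised [makeTarget()]: one row per domain.
#'
#' @param ss Character vector of secondary-structure strings.
#' @param classLabel Vector of class labels, same length.
#' @param params See [strucClassParams()].
#' @return Numeric `n x 4` matrix with columns `x, y1, y2, z`.
#' @export
makeTargets <- function(ss, classLabel, params = strucClassParams()) {
  stopifnot(length(ss) == length(classLabel))
  classLabel <- as.character(classLabel)
  out <- t(mapply(function(s, cl) makeTarget(s, cl, params),
                  ss, classLabel, USE.NAMES = FALSE))
  colnames(out) <- .DIMS
  out
}
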
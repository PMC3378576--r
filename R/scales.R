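#' Kyte-Doolittle hydrophobicity scale
#'
#' Hydropathy index of the 20 standard amino acids (Kyte & Doolittle 1982),
#' used by the hydrophobicity autocorrelation features. Positive values are
#' hydrophobic. The scale can be swapped for another via
#' [strucClassParams()].
#'
#' @return Named numeric vector over [aminoAcids()].
#' @export
#' @examples
#' kyteDoolittle()[c("I", "R")]
kyteDoolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)[.AA]
}

#' Average side-chain masses
#'
#' Average (isotope-weighted) side-chain masses of the 20 standard amino
#' acids in Daltons (residue mass minus the common backbone), used by the
#' side-chain-mass autocorrelation features. Replaceable via
#' [strucClassParams()].
#'
#' @return Named numeric vector over [aminoAcids()], in Daltons.
#' @export
sideChainMasses <- function() {
  c(A =  15.035, R = 100.143, N =  58.060, D =  59.044, C =  47.095,
    Q =  72.086, E =  73.071, G =   1.008, H =  81.096, I =  57.114,
    L =  57.114, K =  72.129, M =  75.149, F =  91.131, P =  42.080,
    S =  31.034, T =  45.061, W = 130.166, Y = 107.131, V =  43.087)[.AA]
}

#' Tunable parameters of the structural-class model
#'
#' Collects every tunable constant of the pipeline in one validated list, so
#' they can be set once and passed through training, target construction and
#' feature extraction.
#'
#' @param k0 Window length (residues) of the sliding-window
#'   secondary-structure composition used to build training targets; windows
#'   shorter than the domain are required, so `min(k0, L)` is used per
#'   domain. Default 8, about two helix turns.
#' @param theta Mixed-content threshold subtracted from the helix/sheet
#'   window content in the `y1`/`y2` base scores (fraction, default 0.1).
#' @param delta Small positive constant stabilising the parallel vs
#'   anti-parallel contrast `z` when a domain has no sheet content
#'   (default 1e-6).
#' @param margin Sign margin `m` of the class-dependent target adjustment:
#'   a training target whose base score violates (or under-shoots) the sign
#'   its class requires is clamped to `+/- m` (default 0.05).
#' @param ridgeLambda Ridge fallback strength used only when the regression
#'   design is rank deficient (default 1e-8).
#' @param hydrophobicity Named numeric over [aminoAcids()]; default
#'   [kyteDoolittle()].
#' @param sideChainMass Named numeric over [aminoAcids()]; default
#'   [sideChainMasses()].
#'
#' @return A named list of class parameters.
#' @export
#' @examples
#' p <- strucClassParams(margin = 0.1)
#' p$margin
strucClassParams <- function(k0 = 8, theta = 0.1, delta = 1e-6,
                             margin = 0.05, ridgeLambda = 1e-8,
                             hydrophobicity = kyteDoolittle(),
                             sideChainMass = sideChainMasses()) {
  stopifnot(k0 >= 1, theta >= 0, delta > 0, margin > 0, ridgeLambda >= 0)
  for (tab in list(hydrophobicity, sideChainMass))
    if (!all(.AA %in% names(tab)))
      stop("residue scale must name all 20 standard amino acids")
  list(k0 = as.integer(k0), theta = theta, delta = delta, margin = margin,
       ridgeLambda = ridgeLambda,
       hydrophobicity = hydrophobicity[.AA],
       sideChainMass = sideChainMass[.AA])
}
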
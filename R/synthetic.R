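# Synthetic domain generator: class-conditioned secondary-structure block
# grammars, element-conditioned residue sampling, and integer log-odds
# PSSMs with a planted evolutionary-conservation signal. Everything the
# train/predict/evaluate loop needs can be simulated, so no external data
# (SCOP, NR, PSI-BLAST runs) is required to exercise the pipeline.

# residue propensity groups used for both sequence sampling and PSSM
# structure
.HELIX_FORMERS <- c("A", "E", "L", "M", "Q", "K", "R", "H")
.BETA_BRANCHED <- c("V", "I", "Y", "W", "F", "T", "C")
.COIL_FORMERS  <- c("G", "P", "S", "N", "D")

.elementGroup <- function(code) {
  switch(code,
         H = .HELIX_FORMERS,
         A = .BETA_BRANCHED,
         P = .BETA_BRANCHED,
         C = .COIL_FORMERS)
}

# element-conditioned amino-acid sampling weights (normalised by sample())
.ELEMENT_PROPENSITY <- local({
  w <- matrix(1, nrow = 4, ncol = 20, dimnames = list(c("H", "A", "P", "C"),
                                                      .AA))
  w["H", ] <- 0.02
  w["H", c("A", "E", "L", "M")] <- 0.10
  w["H", c("Q", "K", "R", "H")] <- 0.06
  w["A", ] <- 0.025
  w["A", .BETA_BRANCHED] <- 0.09
  w["P", ] <- 0.025
  w["P", .BETA_BRANCHED] <- 0.09
  w["C", ] <- 0.03
  w["C", .COIL_FORMERS] <- 0.11
  w
})

#' Simulate a class-conditioned secondary-structure string
#'
#' Block-structured grammars, one per structural class: all-alpha
#' alternates coil with helix blocks of 6-20 residues; all-beta alternates
#' coil with anti-parallel strand blocks of 3-10; alpha/beta alternates
#' helix and parallel-strand blocks (the beta-alpha-beta motif of parallel
#' sheets, no `A`); alpha+beta emits a helical region followed by an
#' anti-parallel sheet region (segregated elements, no `P`). Uses the
#' global RNG; seed with `set.seed()` or via [simulateDataset()].
#'
#' @param classLabel One of [structuralClasses()].
#' @param L Domain length (>= 30 residues, mirroring the usual short-domain
#'   exclusion).
#' @return Secondary-structure string of length `L` over [ssCodes()].
#' @export
#' @examples
#' set.seed(1)
#' simulateSS("all-alpha", 60)
simulateSS <- function(classLabel, L) {
  .checkClassLabel(classLabel)
  L <- as.integer(L)
  if (L < 30L) stop("domain length must be at least 30 residues")
  blk <- function(code, lo, hi) strrep(code, sample(lo:hi, 1))
  coil <- function(lo = 2, hi = 6) blk("C", lo, hi)
  out <- ""
  if (classLabel == "all-alpha") {
    while (nchar(out) < L) out <- paste0(out, coil(), blk("H", 6, 20))
  } else if (classLabel == "all-beta") {
    while (nchar(out) < L) out <- paste0(out, coil(), blk("A", 3, 10))
  } else if (classLabel == "alpha/beta") {
    while (nchar(out) < L)
      out <- paste0(out, coil(1, 4), blk("H", 6, 14),
                    coil(1, 4), blk("P", 3, 8))
  } else {
    half <- ceiling(L / 2)
    while (nchar(out) < half) out <- paste0(out, coil(), blk("H", 6, 16))
    while (nchar(out) < L) out <- paste0(out, coil(), blk("A", 3, 10))
  }
  substr(out, 1, L)
}

#' Simulate a sequence from a secondary-structure string
#'
#' Draws each residue from an element-conditioned propensity table: helix
#' positions favour helix formers (A, E, L, M strongest), strand positions
#' favour beta-branched/aromatic residues, coil positions favour turn
#' formers (G, P, S, N, D). Uses the global RNG.
#'
#' @param ss Secondary-structure string over [ssCodes()].
#' @return Amino-acid sequence of the same length.
#' @export
simulateSequence <- function(ss) {
  .checkSS(ss)
  chars <- strsplit(ss, "", fixed = TRUE)[[1]]
  res <- vapply(chars, function(e)
    sample(.AA, 1, prob = .ELEMENT_PROPENSITY[e, ]), character(1))
  paste(res, collapse = "")
}

#' Simulate an integer log-odds PSSM
#'
#' Emulates the structure of a PSI-BLAST log-odds profile: the residue
#' actually present scores about +4, residues in the same propensity group
#' are mildly positive (+1), all others negative (-2); positions inside a
#' secondary-structure element get an extra `signalStrength` on that
#' element's propensity-group columns (evolutionary conservation of the
#' element's residue character). Gaussian noise of sd `noiseSd` is added,
#' scores are rounded to integers and clipped to `[-10, 13]` like real
#' PSSMs. Uses the global RNG.
#'
#' @param sequence Amino-acid sequence.
#' @param ss Secondary-structure string of the same length.
#' @param noiseSd Noise standard deviation (default 1).
#' @param signalStrength Element-conservation bonus (default 1).
#' @return A [PSSM-class] object.
#' @export
simulatePSSM <- function(sequence, ss, noiseSd = 1, signalStrength = 1) {
  .checkSS(ss)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  elems <- strsplit(ss, "", fixed = TRUE)[[1]]
  if (length(chars) != length(elems))
    stop("sequence and secondary-structure string lengths differ")
  L <- length(chars)
  M <- matrix(-2, nrow = L, ncol = 20, dimnames = list(NULL, .AA))
  for (i in seq_len(L)) {
    grp <- .elementGroup(elems[i])
    M[i, grp] <- M[i, grp] + signalStrength
    own <- chars[i]
    if (own %in% .AA) {
      same <- if (own %in% .HELIX_FORMERS) .HELIX_FORMERS
              else if (own %in% .BETA_BRANCHED) .BETA_BRANCHED
              else .COIL_FORMERS
      M[i, same] <- pmax(M[i, same], 1)
      M[i, own] <- 4
    }
  }
  if (noiseSd > 0) M <- M + matrix(stats::rnorm(L * 20, sd = noiseSd), L, 20)
  M <- pmin(pmax(round(M), -10), 13)
  PSSM(sequence, M)
}

#' Simulate a labelled domain dataset with a train/test split
#'
#' Generates `nPerClass` domains per structural class (secondary structure,
#' sequence, PSSM, 440-dimensional features), then splits them 80/20 into
#' training and held-out sets, stratified by class. Fully reproducible from
#' `seed`. The defaults (250 domains per class, lengths 60-300) give a
#' 200/50 per-class train/test split.
#'
#' @param nPerClass Domains per class (default 250).
#' @param lengthRange Integer range of domain lengths (default
#'   `c(60, 300)`; minimum 30).
#' @param noiseSd PSSM noise sd, see [simulatePSSM()] (default 1).
#' @param signalStrength Element-conservation bonus (default 1).
#' @param seed Integer seed (default 1).
#' @param params Feature-extraction parameters ([strucClassParams()]).
#' @return List with [DomainSet-class] elements `train` and `test`, plus
#'   `pssms` (named list of the simulated [PSSM-class] objects).
#' @export
#' @examples
#' sim <- simulateDataset(nPerClass = 5, lengthRange = c(40, 80), seed = 7)
#' length(sim$train)
simulateDataset <- function(nPerClass = 250, lengthRange = c(60, 300),
                            noiseSd = 1, signalStrength = 1, seed = 1,
                            params = strucClassParams()) {
  stopifnot(nPerClass >= 2, lengthRange[1] >= 30,
            lengthRange[2] >= lengthRange[1])
  .withSeed(seed, {
    n <- nPerClass * 4L
    ids <- character(n); sss <- character(n)
    labs <- character(n); pssms <- vector("list", n)
    feats <- matrix(NA_real_, n, 440L,
                    dimnames = list(NULL, featureNames()))
    k <- 0L
    for (cl in .CLASSES) {
      for (j in seq_len(nPerClass)) {
        k <- k + 1L
        L <- sample(lengthRange[1]:lengthRange[2], 1)
        ss <- simulateSS(cl, L)
        seqn <- simulateSequence(ss)
        pssm <- simulatePSSM(seqn, ss, noiseSd, signalStrength)
        code <- c("all-alpha" = "aa", "all-beta" = "bb",
                  "alpha/beta" = "ab", "alpha+beta" = "apb")[[cl]]
        ids[k] <- sprintf("syn_%s_%04d", code, j)
        sss[k] <- ss
        labs[k] <- cl
        pssms[[k]] <- pssm
        feats[k, ] <- extractFeatures(pssm, params)
      }
    }
    rownames(feats) <- ids
    names(pssms) <- ids
    # stratified 80/20 split
    testIdx <- unlist(lapply(.CLASSES, function(cl) {
      ii <- which(labs == cl)
      sample(ii, max(1L, round(0.2 * length(ii))))
    }))
    isTest <- seq_len(n) %in% testIdx
    list(train = DomainSet(ids[!isTest], feats[!isTest, , drop = FALSE],
                           sss[!isTest], labs[!isTest]),
         test = DomainSet(ids[isTest], feats[isTest, , drop = FALSE],
                          sss[isTest], labs[isTest]),
         pssms = pssms)
  })
}

#' Write a simulated dataset to standard files
#'
#' Materialises a simulated dataset in the exact external formats the
#' pipeline reads: `sequences.fasta`, one ASCII PSSM per domain under
#' `pssm/`, `domains.tsv` (domain_id, parent_id, start, end, class) and
#' `ss.tsv` (domain_id, secondary-structure string). Each synthetic domain
#' is its own parent sequence (start = 1, end = L).
#'
#' @param dir Output directory (created if missing).
#' @param nPerClass,lengthRange,noiseSd,signalStrength,seed,params Passed
#'   to [simulateDataset()].
#' @return Invisibly, the [simulateDataset()] result.
#' @export
writeSyntheticData <- function(dir, nPerClass = 10,
                               lengthRange = c(40, 120), noiseSd = 1,
                               signalStrength = 1, seed = 1,
                               params = strucClassParams()) {
  sim <- simulateDataset(nPerClass, lengthRange, noiseSd, signalStrength,
                         seed, params)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "pssm"), showWarnings = FALSE)
  ids <- c(domainIds(sim$train), domainIds(sim$test))
  sss <- c(ssStrings(sim$train), ssStrings(sim$test))
  labs <- c(as.character(classLabels(sim$train)),
            as.character(classLabels(sim$test)))
  seqs <- vapply(sim$pssms[ids], querySequence, character(1))
  writeFastaFile(seqs, file.path(dir, "sequences.fasta"))
  for (id in ids)
    writePSSMFile(sim$pssms[[id]], file.path(dir, "pssm", paste0(id, ".pssm")))
  writeDomainTable(
    data.frame(domain_id = ids, parent_id = ids, start = 1L,
               end = nchar(seqs), class = labs,
               stringsAsFactors = FALSE),
    file.path(dir, "domains.tsv"))
  writeSSTable(stats::setNames(sss, ids), file.path(dir, "ss.tsv"))
  invisible(sim)
}
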
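# Shared fixtures and independent brute-force oracles. The oracles use
# naive loops only and never call the package's vectorised feature code,
# so they stay an independent check of the implementation.

AAs <- aminoAcids()

randomSequence <- function(L) paste(sample(AAs, L, replace = TRUE),
                                    collapse = "")

randomPSSM <- function(L) {
  PSSM(randomSequence(L),
       matrix(sample(-10:13, L * 20, replace = TRUE), L, 20,
              dimnames = list(NULL, AAs)))
}

randomSS <- function(L) paste(sample(ssCodes(), L, replace = TRUE),
                              collapse = "")

# a small, clean DomainSet with well-separated synthetic classes
smallDomainSet <- function(nPerClass, seed = 1,
                           lengthRange = c(40, 90)) {
  simulateDataset(nPerClass = nPerClass, lengthRange = lengthRange,
                  seed = seed)
}

# ---- brute-force oracles -------------------------------------------------

bruteWindowComposition <- function(ss, k) {
  chars <- strsplit(ss, "")[[1]]
  L <- length(chars)
  out <- c(H = 0, A = 0, P = 0)
  nw <- L - k + 1
  for (e in names(out)) {
    acc <- 0
    for (t in 1:nw) acc <- acc + sum(chars[t:(t + k - 1)] == e) / k
    out[e] <- acc / nw
  }
  out
}

bruteWeightedAutocorr <- function(pssm, scale) {
  P <- pssmScores(pssm)
  L <- nrow(P)
  hp <- numeric(L); hn <- numeric(L)
  for (i in 1:L) for (j in 1:20) {
    s <- P[i, j] * scale[AAs[j]]
    if (P[i, j] > 0) hp[i] <- hp[i] + s
    if (P[i, j] < 0) hn[i] <- hn[i] + s
  }
  lagprod <- function(h, k) {
    acc <- 0
    for (i in 1:(L - k)) acc <- acc + h[i] * h[i + k]
    acc / (L - k)
  }
  unname(c(vapply(1:10, function(k) lagprod(hp, k), numeric(1)),
           vapply(1:10, function(k) lagprod(hn, k), numeric(1))))
}

bruteG5 <- function(pssm) {
  P <- pssmScores(pssm)
  L <- nrow(P)
  out <- numeric(0)
  for (j in 1:20) for (k in 1:7) {
    acc <- 0
    for (i in 1:(L - k)) acc <- acc + P[i, j] * P[i + k, j]
    out <- c(out, acc / (L - k))
  }
  unname(out)
}

bruteG6 <- function(pssm) {
  P <- pssmScores(pssm)
  L <- nrow(P)
  half <- function(M) {
    out <- numeric(0)
    for (k in c(4, 8, 16)) {
      for (j in 1:20) {
        acc <- 0
        for (t in 1:(L - k + 1)) acc <- acc + mean(M[t:(t + k - 1), j])^2
        out <- c(out, acc / (L - k + 1))
      }
    }
    out
  }
  c(half(pmax(P, 0)), half(pmin(P, 0)))
}

bruteG7 <- function(pssm) {
  P <- pssmScores(pssm)
  L <- nrow(P)
  out <- numeric(0)
  for (j in 1:20) {
    w <- pmax(P[, j], 0)
    W <- sum(w)
    if (W == 0) {
      out <- c(out, 0.5, 0, 0, 0.25)
      next
    }
    r <- (1:L) / L
    m <- sum(w * r) / W
    sp <- sqrt(sum(w * (r - m)^2) / W)
    bias <- (sum(w[1:ceiling(L / 2)]) -
             sum(w[(ceiling(L / 2) + 1):L])) / W
    edge <- sum(w * abs(r - 0.5)) / W
    out <- c(out, m, sp, bias, edge)
  }
  unname(out)
}

normalEquationsFit <- function(X, t) {
  as.vector(solve(t(X) %*% X) %*% t(X) %*% t)
}

bruteChi2 <- function(cm) {
  N <- sum(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  acc <- 0
  for (r in 1:4) for (c in 1:4) {
    E <- rs[r] * cs[c] / N
    if (E > 0) acc <- acc + (cm[r, c] - E)^2 / E
  }
  acc
}
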
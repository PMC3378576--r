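test_that("feature registry has the documented group structure", {
  fn <- featureNames()
  expect_length(fn, 440L)
  expect_false(anyDuplicated(fn) > 0)
  counts <- table(sub("\\..*$", "", fn))
  expect_equal(as.integer(counts[paste0("G", 1:7)]),
               c(20L, 40L, 20L, 20L, 140L, 120L, 80L))
})

test_that("G1 is the square-root amino-acid composition", {
  g <- g1Composition("AAAA")
  expect_equal(g[["A"]], 1)
  expect_equal(sum(g != 0), 1L)

  g <- g1Composition("AC")
  expect_equal(g[["A"]], sqrt(0.5))
  expect_equal(g[["C"]], sqrt(0.5))

  set.seed(1)
  for (i in 1:20)
    expect_equal(sum(g1Composition(randomSequence(sample(5:80, 1)))^2), 1)

  # non-standard letters count toward length but toward no N_j
  g <- g1Composition("AAXX")
  expect_equal(g[["A"]], sqrt(0.5))
  expect_equal(sum(g^2), 0.5)
})

test_that("G2 splits positive and negative mean mutation scores", {
  zero <- PSSM("ACDE", matrix(0L, 4, 20))
  expect_true(all(g2MutationMeans(zero) == 0))

  M <- matrix(0L, 2, 20, dimnames = list(NULL, AAs))
  M[, "A"] <- c(2L, -1L)
  g <- g2MutationMeans(PSSM("AC", M))
  expect_equal(unname(g[1]), 1.0)   # pos_A
  expect_equal(unname(g[21]), -0.5) # neg_A

  set.seed(2)
  for (i in 1:10) {
    g <- g2MutationMeans(randomPSSM(sample(10:40, 1)))
    expect_true(all(g[1:20] >= 0))
    expect_true(all(g[21:40] <= 0))
  }
})

test_that("autocorrelation and segment features match brute-force oracles", {
  set.seed(101)
  p <- strucClassParams()
  for (i in 1:30) {
    pssm <- randomPSSM(sample(17:40, 1))
    expect_equal(unname(g3HydrophobicityAutocorr(pssm, p$hydrophobicity)),
                 unname(bruteWeightedAutocorr(pssm, p$hydrophobicity)),
                 tolerance = 1e-10)
    expect_equal(unname(g4MassAutocorr(pssm, p$sideChainMass)),
                 unname(bruteWeightedAutocorr(pssm, p$sideChainMass)),
                 tolerance = 1e-10)
    expect_equal(unname(g5PssmAutocorr(pssm)), bruteG5(pssm),
                 tolerance = 1e-10)
    expect_equal(unname(g6SegmentMeanSquare(pssm)), bruteG6(pssm),
                 tolerance = 1e-10)
    expect_equal(unname(g7PositionPreference(pssm)), bruteG7(pssm),
                 tolerance = 1e-10)
  }
})

test_that("constant signals produce the closed-form c^2 autocorrelations", {
  L <- 30
  ones <- PSSM(randomSequence(L), matrix(1, L, 20))
  cH <- sum(kyteDoolittle())  # h+_i is constant at the scale sum
  g3 <- g3HydrophobicityAutocorr(ones)
  expect_equal(unname(g3[1:10]), rep(cH^2, 10))
  expect_true(all(g3[11:20] == 0))

  g5 <- g5PssmAutocorr(ones)
  expect_equal(unname(g5), rep(1, 140))  # every column constant at 1

  threes <- PSSM(randomSequence(L), matrix(3, L, 20))
  g6 <- g6SegmentMeanSquare(threes)
  expect_equal(unname(g6[1:60]), rep(9, 60))
  expect_true(all(g6[61:120] == 0))
})

test_that("G5 responds to a column shift exactly as the closed form predicts", {
  set.seed(5)
  pssm <- randomPSSM(25)
  P <- pssmScores(pssm)
  delta <- 3
  P2 <- P; P2[, "D"] <- P2[, "D"] + delta
  g5a <- g5PssmAutocorr(pssm)
  g5b <- g5PssmAutocorr(PSSM(querySequence(pssm), P2))
  L <- 25
  j <- which(AAs == "D")
  for (k in 1:7) {
    pred <- g5a[[paste0("G5.auto.D.k", k)]] +
      delta * (sum(P[1:(L - k), j]) + sum(P[(1 + k):L, j])) / (L - k) +
      delta^2
    expect_equal(g5b[[paste0("G5.auto.D.k", k)]], pred, tolerance = 1e-10)
  }
  # untouched columns unchanged
  untouched <- !grepl("\\.D\\.", names(g5a))
  expect_equal(g5a[untouched], g5b[untouched])
})

test_that("G7 position preference matches hand arithmetic and defaults", {
  M <- matrix(0L, 10, 20, dimnames = list(NULL, AAs))
  M[1, "A"] <- 7L
  g <- g7PositionPreference(PSSM(randomSequence(10), M))
  expect_equal(unname(g[c("G7.A.mean", "G7.A.spread",
                          "G7.A.bias", "G7.A.edge")]),
               c(0.1, 0, 1, 0.4))
  # all-zero column -> stated neutral defaults
  expect_equal(unname(g[c("G7.C.mean", "G7.C.spread",
                          "G7.C.bias", "G7.C.edge")]),
               c(0.5, 0, 0, 0.25))

  # uniform positive column: bias vanishes up to the odd-length residue
  M2 <- matrix(2L, 11, 20, dimnames = list(NULL, AAs))
  g2 <- g7PositionPreference(PSSM(randomSequence(11), M2))
  expect_lt(abs(g2[["G7.A.bias"]]), 1 / 11 + 1e-12)
})

test_that("extractFeatures assembles 440 named features", {
  pssm <- randomPSSM(40)
  v <- extractFeatures(pssm)
  expect_length(v, 440L)
  expect_identical(names(v), featureNames())
  expect_true(all(is.finite(v)))

  # all-zero PSSM leaves only the composition group non-zero
  zero <- PSSM(strrep("A", 30), matrix(0L, 30, 20))
  v0 <- extractFeatures(zero)
  expect_true(all(v0[21:360] == 0))
  expect_equal(v0[["G1.comp.A"]], 1)
  expect_length(v0, 440L)
})

test_that("short domains emit zero-padded features with a warning", {
  pssm <- randomPSSM(8)
  w3 <- testthat::capture_warnings(v <- g3HydrophobicityAutocorr(pssm))
  expect_match(w3, "lag", all = TRUE)
  expect_length(v, 20L)
  expect_true(all(v[c(8:10, 18:20)] == 0))

  w6 <- testthat::capture_warnings(v6 <- g6SegmentMeanSquare(pssm))
  expect_match(w6, "segment length 16", all = FALSE)
  expect_length(v6, 120L)

  # the assembled vector stays fixed at 440 entries, one warning per
  # affected family
  ws <- testthat::capture_warnings(full <- extractFeatures(pssm))
  expect_gte(length(ws), 3L)
  expect_length(full, 440L)
})
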
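test_that("confusionCounts tallies labels in the fixed class order", {
  cls <- structuralClasses()
  same <- rep(cls, times = c(3, 4, 2, 1))
  cm <- confusionCounts(same, same)
  expect_equal(diag(cm), setNames(c(3L, 4L, 2L, 1L), cls))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)

  pred <- same
  pred[c(1, 4, 8)] <- c(cls[2], cls[3], cls[1])  # 3 planted mismatches
  cm <- confusionCounts(same, pred)
  expect_equal(sum(cm) - sum(diag(cm)), 3L)

  # hand tally of a printed 12-item toy list
  truth <- cls[c(1, 1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4)]
  predd <- cls[c(1, 2, 1, 2, 2, 3, 3, 3, 4, 4, 1, 4)]
  cm <- confusionCounts(truth, predd)
  hand <- matrix(c(2, 1, 0, 0,
                   0, 2, 1, 0,
                   0, 0, 2, 1,
                   1, 0, 0, 2), 4, 4, byrow = TRUE)
  expect_equal(unname(cm), hand)

  expect_error(confusionCounts(cls[1:3], cls[1:2]), "equal length")
  expect_error(confusionCounts(c("all-alpha", "other"), cls[1:2]),
               "unknown")
})

test_that("classMetrics computes one-vs-rest Sn, Sp and MCC", {
  perfect <- diag(c(5L, 6L, 7L, 8L))
  dimnames(perfect) <- list(structuralClasses(), structuralClasses())
  for (cl in structuralClasses())
    expect_equal(classMetrics(perfect, cl), c(Sn = 1, Sp = 1, MCC = 1))

  # a blind-test style row: 240 of 251 all-alpha domains correct
  cm <- matrix(0L, 4, 4)
  cm[1, ] <- c(240L, 4L, 3L, 4L)
  cm[2, 2] <- 100L; cm[3, 3] <- 100L; cm[4, 4] <- 100L
  met <- classMetrics(cm, "all-alpha")
  expect_equal(met[["Sn"]], 240 / 251)
  expect_equal(round(100 * met[["Sn"]], 1), 95.6)
  expect_equal(met[["Sp"]], 1)  # no other class predicted as all-alpha

  # collapsed two-class matrix checked against the explicit formula
  cm2 <- matrix(0L, 4, 4)
  cm2[1, 1] <- 8L; cm2[1, 2] <- 2L; cm2[2, 1] <- 1L; cm2[2, 2] <- 9L
  met <- classMetrics(cm2, "all-alpha")
  TP <- 8; FN <- 2; FP <- 1; TN <- 9
  expect_equal(met[["MCC"]],
               (TP * TN - FP * FN) /
                 sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)))
  expect_equal(met[["Sn"]], 0.8)
  expect_equal(met[["Sp"]], 0.9)

  # zero denominator factor -> MCC defined as 0
  none <- matrix(0L, 4, 4); none[2, 2] <- 5L
  expect_warning(met <- classMetrics(none, "all-alpha"), "absent")
  expect_true(is.nan(met[["Sn"]]))
  expect_equal(met[["MCC"]], 0)
})

test_that("gc2 is the chi-square association normalised to [0, 1]", {
  perfect <- diag(c(5L, 5L, 5L, 5L))
  expect_equal(gc2(perfect), 1)

  # permuting rows of a perfect matrix keeps the association maximal
  expect_equal(gc2(perfect[c(2, 1, 4, 3), ]), 1)

  # independence: observed equals the marginal expectation
  indep <- outer(c(10, 20, 30, 40), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(gc2(indep), 0)

  # random matrices agree with the cell-by-cell brute-force chi-square
  set.seed(31)
  for (i in 1:25) {
    cm <- matrix(sample(1:30, 16, replace = TRUE), 4, 4)
    expect_equal(gc2(cm), bruteChi2(cm) / (sum(cm) * 3), tolerance = 1e-12)
  }

  single <- matrix(0L, 4, 4); single[1, 1] <- 10L
  expect_error(gc2(single), "degenerate")
})

test_that("MCC and GC2 stay inside their documented ranges", {
  set.seed(32)
  for (i in 1:1000) {
    cm <- matrix(sample(0:15, 16, replace = TRUE), 4, 4)
    if (sum(cm) == 0) next
    for (cl in structuralClasses()) {
      m <- suppressWarnings(classMetrics(cm, cl))
      if (!is.nan(m[["MCC"]]))
        expect_true(m[["MCC"]] >= -1 && m[["MCC"]] <= 1)
    }
    if (sum(rowSums(cm) > 0) >= 2 && sum(colSums(cm) > 0) >= 2) {
      g <- gc2(cm)
      expect_true(g >= 0 && g <= 1 + 1e-12)
    }
  }
})

test_that("cross-validation builds disjoint stratified folds deterministically", {
  sim <- smallDomainSet(10, seed = 33)
  ds <- sim$train  # 8 per class
  rep1 <- suppressMessages(crossValidate(ds, kFolds = 4, seed = 5,
                                         select = 10))
  rep2 <- suppressMessages(crossValidate(ds, kFolds = 4, seed = 5,
                                         select = 10))
  expect_identical(rep1$confusion, rep2$confusion)
  expect_identical(rep1$folds, rep2$folds)

  # stratification: per-class fold sizes differ by at most one
  for (cl in structuralClasses()) {
    sizes <- table(rep1$folds[classLabels(ds) == cl])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # the folds partition the dataset
  expect_setequal(unique(rep1$folds), 1:4)
  expect_equal(sum(rep1$confusion), length(ds))

  expect_error(crossValidate(ds, kFolds = 10), "fewer members")
})

test_that("jackknife scores every domain exactly once", {
  sim <- smallDomainSet(4, seed = 34)
  tr <- sim$train
  idx <- unlist(lapply(structuralClasses(),
                       function(cl) which(classLabels(tr) == cl)[1:2]))
  ds <- tr[idx]  # clean 2 domains per class
  rep <- suppressMessages(jackknife(ds, select = 4))
  expect_equal(sum(rep$confusion), 8)
  expect_error(jackknife(ds[1:5]), "at least 2")
})

test_that("jackknife and 10-fold cross-validation estimate the same accuracy", {
  # at this problem size (80 training domains) a single-seed accuracy
  # carries binomial noise of several domains, so the two resampling
  # protocols are compared on their 5-seed averages
  accs <- vapply(1:5, function(s) {
    sim <- simulateDataset(nPerClass = 25, lengthRange = c(50, 140),
                           seed = s)
    ds <- sim$train  # 20 per class
    cv <- suppressMessages(crossValidate(ds, kFolds = 10, seed = s,
                                         select = 12))
    jk <- suppressMessages(jackknife(ds, select = 12))
    c(cv$accuracy, jk$accuracy)
  }, numeric(2))
  expect_lte(abs(mean(accs[1, ]) - mean(accs[2, ])), 0.05)
})
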
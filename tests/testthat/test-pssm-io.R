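test_that("FASTA reading handles single, wrapped and malformed records", {
  f <- withr::local_tempfile(fileext = ".fasta")

  writeLines(c(">d1", "ACDE"), f)
  expect_equal(readFastaFile(f), c(d1 = "ACDE"))

  writeLines(c(">d1 some description", "acde",
               ">d2", "ACD", "EFG", "HIK"), f)
  got <- readFastaFile(f)
  expect_equal(got, c(d1 = "ACDE", d2 = "ACDEFGHIK"))

  writeLines(c(">d1", "", ">d2", "ACDE"), f)
  expect_error(readFastaFile(f), "d1")

  writeLines(character(0), f)
  expect_error(readFastaFile(f))
})

test_that("FASTA round-trips preserve sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- setNames(vapply(c(10, 75, 130), randomSequence, character(1)),
                   c("a", "b", "c"))
  writeFastaFile(seqs, f)
  expect_equal(readFastaFile(f), seqs)
})

test_that("PSSM reader parses the ASCII body and reports malformed rows", {
  f <- withr::local_tempfile(fileext = ".pssm")
  p <- randomPSSM(5)
  writePSSMFile(p, f)
  got <- readPSSM(f)
  expect_equal(length(got), 5L)
  expect_equal(dim(pssmScores(got)), c(5L, 20L))
  expect_equal(pssmScores(got), pssmScores(p), ignore_attr = TRUE)

  # residue letters pass through into the query sequence
  q <- PSSM("ACWDE", matrix(0L, 5, 20))
  writePSSMFile(q, f)
  expect_equal(substr(querySequence(readPSSM(f)), 3, 3), "W")

  # truncate the numeric block of body row 3 -> parse error naming the line
  writePSSMFile(p, f)
  lines <- readLines(f)
  bodyLines <- grep("^\\s*\\d+\\s+[A-Z]", lines)
  fields <- strsplit(trimws(lines[bodyLines[3]]), "\\s+")[[1]]
  lines[bodyLines[3]] <- paste(head(fields, -5), collapse = " ")
  writeLines(lines, f)
  expect_error(readPSSM(f), paste0("line ", bodyLines[3]))
})

test_that("PSSM write/read round-trips 100 random fixtures", {
  f <- withr::local_tempfile(fileext = ".pssm")
  set.seed(42)
  for (i in 1:100) {
    p <- randomPSSM(sample(5:30, 1))
    writePSSMFile(p, f)
    got <- readPSSM(f)
    expect_identical(querySequence(got), querySequence(p))
    expect_equal(unname(pssmScores(got)), unname(pssmScores(p)))
  }
})

test_that("sliceDomain extracts contiguous sub-profiles with 1-based bounds", {
  p <- randomPSSM(5)

  whole <- sliceDomain(p, 1, 5)
  expect_equal(pssmScores(whole), pssmScores(p))
  expect_equal(querySequence(whole), querySequence(p))

  one <- sliceDomain(p, 3, 3)
  expect_equal(length(one), 1L)
  expect_equal(unname(pssmScores(one)[1, ]), unname(pssmScores(p)[3, ]))

  sub <- sliceDomain(p, 2, 4)
  for (r in 1:3) for (j in 1:20)
    expect_identical(pssmScores(sub)[r, j], pssmScores(p)[r + 1, j])
  expect_equal(querySequence(sub), substr(querySequence(p), 2, 4))

  expect_error(sliceDomain(p, 0, 3), "out of bounds")
  expect_error(sliceDomain(p, 2, 6), "out of bounds")
  expect_error(sliceDomain(p, 4, 2), "out of bounds")
})

test_that("model serialization round-trips and validates its format", {
  sim <- smallDomainSet(6, seed = 11)
  model <- suppressMessages(trainModel(sim$train))
  f <- withr::local_tempfile(fileext = ".json")
  writeModel(model, f)

  got <- readModel(f)
  expect_equal(coef(got), coef(model))
  expect_equal(got@center, model@center)
  expect_equal(got@scale, model@scale)
  expect_equal(selectedFeatures(got), lapply(selectedFeatures(model),
                                             as.integer))

  # a full model serializes all 4 x 441 = 1764 coefficient values
  raw <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_length(unlist(raw$coefficients), 1764L)

  # version-tag mismatch
  raw$format <- "other/9"
  jsonlite::write_json(raw, f, digits = NA, auto_unbox = TRUE)
  expect_error(readModel(f), "format tag")

  # missing standardization block
  writeModel(model, f)
  raw <- jsonlite::read_json(f, simplifyVector = TRUE)
  raw$standardization <- NULL
  jsonlite::write_json(raw, f, digits = NA, auto_unbox = TRUE)
  expect_error(readModel(f), "standardization")
})

test_that("domain, secondary-structure and feature tables round-trip", {
  dom <- data.frame(domain_id = c("d1", "d2"), parent_id = c("p1", "p1"),
                    start = c(1L, 10L), end = c(9L, 40L),
                    class = c("all-alpha", "alpha/beta"),
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDomainTable(dom, f)
  expect_equal(readDomainTable(f), dom)

  bad <- dom; bad$start[2] <- 50L
  writeDomainTable(bad, f)
  expect_error(readDomainTable(f), "d2")

  bad <- dom; bad$class[1] <- "beta-barrel"
  writeDomainTable(bad, f)
  expect_error(readDomainTable(f), "beta-barrel")

  ss <- c(d1 = "HHHHCCAAA", d2 = "CCPPHHHC")
  writeSSTable(ss, f)
  expect_equal(readSSTable(f), ss)
  writeLines(c("domain_id\tss", "d1\tHHQX"), f)
  expect_error(readSSTable(f), "d1")

  X <- matrix(rnorm(2 * 440), 2, 440,
              dimnames = list(c("d1", "d2"), featureNames()))
  writeFeatureTable(X, f)
  expect_equal(readFeatureTable(f), X, tolerance = 1e-12)
})
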
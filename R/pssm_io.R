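# I/O for the formats the pipeline touches: FASTA sequences (via
# Biostrings), PSI-BLAST ASCII PSSM profiles, domain interval tables,
# secondary-structure tables, feature matrices and serialized models.

.MODEL_FORMAT_TAG <- "strucClass-model/1"

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] adding the
#' plumbing checks the pipeline needs: the file must contain at least one
#' record and no record may have an empty sequence. Sequences are
#' uppercased; headers are truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
readFastaFile <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e)
                    stop("malformed FASTA file '", path, "': ",
                         conditionMessage(e)))
  if (length(set) == 0L)
    stop("FASTA file '", path, "' contains no records")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  empty <- nchar(seqs) == 0L
  if (any(empty))
    stop("FASTA record(s) with empty sequence: ",
         paste(names(seqs)[empty], collapse = ", "))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences.
#' @param path Output file.
#' @param width Line-wrap width (default 60).
#' @return Invisibly, `path`.
#' @export
writeFastaFile <- function(sequences, path, width = 60) {
  stopifnot(!is.null(names(sequences)))
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the ASCII matrix PSI-BLAST writes with `-Q`: header lines, then
#' one body row per position holding the position index, the query residue
#' letter, 20 log-odds integers, 20 weighted-percentage integers and two
#' trailing per-position statistics. Only the log-odds block is kept (the
#' nominal substitution scores the feature extraction uses); the
#' percentage block and trailing statistics are ignored. A body row whose
#' 40-column numeric block is malformed raises a parse error naming the
#' line.
#'
#' @param path PSSM file.
#' @return A [PSSM-class] object whose sequence is the concatenation of
#'   the per-row residue letters.
#' @export
readPSSM <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  bodyRe <- "^\\s*\\d+\\s+[A-Za-z]\\b"
  isBody <- grepl(bodyRe, lines)
  if (!any(isBody))
    stop("no PSSM body rows found in '", path, "'")
  rows <- which(isBody)
  letters_ <- character(length(rows))
  scores <- matrix(NA_real_, nrow = length(rows), ncol = 20,
                   dimnames = list(NULL, .AA))
  for (r in seq_along(rows)) {
    ln <- rows[r]
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    letters_[r] <- toupper(fields[2])
    nums <- suppressWarnings(as.numeric(fields[-(1:2)]))
    if (anyNA(nums))
      stop("non-numeric field in PSSM body at line ", ln, " of '", path, "'")
    # 40 integers (log-odds + percentages), optionally followed by the two
    # per-position information/weight statistics
    if (!(length(nums) %in% c(40L, 42L)))
      stop("expected 40 numeric matrix fields in PSSM body at line ", ln,
           " of '", path, "', found ", length(nums))
    scores[r, ] <- nums[1:20]
  }
  PSSM(paste(letters_, collapse = ""), scores)
}

#' Write a PSSM in PSI-BLAST ASCII format
#'
#' Emits the standard ASCII layout [readPSSM()] consumes: two header
#' lines, the 40-column body (log-odds block followed by a
#' weighted-percentage block, here written as zeros) and two trailing
#' per-position statistics columns.
#'
#' @param pssm A [PSSM-class] object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writePSSMFile <- function(pssm, path) {
  stopifnot(is(pssm, "PSSM"))
  P <- pssmScores(pssm)
  chars <- strsplit(querySequence(pssm), "", fixed = TRUE)[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", c(.AA, .AA)), collapse = " "))),
    con)
  for (i in seq_len(nrow(P))) {
    writeLines(sprintf("%5d %s  %s %s  %4.2f %4.2f", i, chars[i],
                       paste(sprintf("%3d", as.integer(round(P[i, ]))),
                             collapse = " "),
                       paste(sprintf("%3d", integer(20)), collapse = " "),
                       0, 0), con)
  }
  writeLines(c("", "                      K         Lambda"), con)
  invisible(path)
}

#' Slice a domain out of a parent-protein PSSM
#'
#' PSSMs are computed per protein sequence; a domain's PSSM is the
#' contiguous sub-block of its parent's. Coordinates are 1-based inclusive.
#'
#' @param pssm Parent [PSSM-class].
#' @param start,end 1-based inclusive residue positions,
#'   `1 <= start <= end <= length(pssm)`.
#' @return A [PSSM-class] of length `end - start + 1`.
#' @export
#' @examples
#' p <- PSSM("ACDEF", matrix(seq_len(100), 5, 20))
#' querySequence(sliceDomain(p, 2, 4))
sliceDomain <- function(pssm, start, end) {
  stopifnot(is(pssm, "PSSM"))
  L <- length(pssm)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end > L || start > end)
    stop("domain interval [", start, ", ", end,
         "] out of bounds for PSSM of length ", L)
  PSSM(substr(querySequence(pssm), start, end),
       pssmScores(pssm)[start:end, , drop = FALSE])
}

#' Read a domain interval table
#'
#' TSV with header `domain_id  parent_id  start  end  class` (the class
#' column may be absent or empty for prediction inputs). Coordinates are
#' 1-based inclusive positions in the parent sequence.
#'
#' @param path TSV file.
#' @return `data.frame` with those columns; `class` is `NA` where absent.
#' @export
readDomainTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("domain_id", "parent_id", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("domain table '", path, "' missing column(s): ",
         paste(miss, collapse = ", "))
  if (!"class" %in% names(df)) df$class <- NA_character_
  bad <- !is.na(df$start) & !is.na(df$end) &
    (df$start < 1 | df$start > df$end)
  if (any(bad))
    stop("invalid interval(s) in domain table: ",
         paste(df$domain_id[bad], collapse = ", "))
  withClass <- !is.na(df$class) & nzchar(df$class)
  badCl <- withClass & !df$class %in% .CLASSES
  if (any(badCl))
    stop("unknown class label(s) in domain table: ",
         paste(unique(df$class[badCl]), collapse = ", "))
  df[c("domain_id", "parent_id", "start", "end", "class")]
}

#' @rdname readDomainTable
#' @param table `data.frame` as returned by `readDomainTable()`.
#' @export
writeDomainTable <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write secondary-structure tables
#'
#' Two-column TSV `domain_id  ss` with per-residue element strings over
#' [ssCodes()].
#'
#' @param path TSV file.
#' @return Named character vector of secondary-structure strings.
#' @export
readSSTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("domain_id", "ss") %in% names(df)))
    stop("secondary-structure table '", path,
         "' must have columns domain_id and ss")
  bad <- !grepl("^[HAPC]+$", df$ss)
  if (any(bad))
    stop("invalid secondary-structure string(s) for: ",
         paste(df$domain_id[bad], collapse = ", "))
  stats::setNames(df$ss, df$domain_id)
}

#' @rdname readSSTable
#' @param ss Named character vector of secondary-structure strings.
#' @export
writeSSTable <- function(ss, path) {
  utils::write.table(data.frame(domain_id = names(ss), ss = unname(ss)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write feature matrices
#'
#' TSV with a `domain_id` column followed by the 440 labelled feature
#' columns ([featureNames()]).
#'
#' @param path TSV file.
#' @return Numeric `n x 440` matrix with domain ids as row names.
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"domain_id" %in% names(df))
    stop("feature table '", path, "' missing domain_id column")
  X <- as.matrix(df[setdiff(names(df), "domain_id")])
  if (ncol(X) != 440L)
    stop("feature table '", path, "' has ", ncol(X),
         " feature columns; expected 440")
  rownames(X) <- df$domain_id
  X
}

#' @rdname readFeatureTable
#' @param features Numeric matrix with 440 columns and domain-id row names.
#' @export
writeFeatureTable <- function(features, path) {
  stopifnot(ncol(features) == 440L)
  df <- data.frame(domain_id = rownames(features), features,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a trained model
#'
#' Versioned JSON carrying the 4 x 441 coefficient matrix (1764 values),
#' the feature standardization block and the per-dimension selected
#' feature indices. Numbers are written at full precision so a round trip
#' reproduces the stored decimal representation exactly.
#'
#' @param model A [StrucClassModel-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "StrucClassModel"))
  obj <- list(
    format = .MODEL_FORMAT_TAG,
    feature_names = featureNames(),
    coefficients = unclass(as.data.frame(model@coefficients)),
    standardization = list(center = unname(model@center),
                           scale = unname(model@scale)),
    selected = model@selected,
    params = model@params[c("k0", "theta", "delta", "margin",
                            "ridgeLambda")])
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Deserialize a trained model
#'
#' @param path File written by [writeModel()].
#' @return A [StrucClassModel-class].
#' @export
readModel <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse model file '", path, "': ",
                         conditionMessage(e)))
  if (!identical(obj$format, .MODEL_FORMAT_TAG))
    stop("model file '", path, "' has format tag '", obj$format,
         "'; expected '", .MODEL_FORMAT_TAG, "'")
  if (is.null(obj$standardization) ||
      length(obj$standardization$center) != 440L ||
      length(obj$standardization$scale) != 440L)
    stop("model file '", path, "' is missing a valid standardization block")
  coefs <- matrix(as.numeric(as.matrix(as.data.frame(obj$coefficients))),
                  nrow = 4L)
  dimnames(coefs) <- list(.DIMS, c(obj$feature_names, "(Intercept)"))
  params <- do.call(strucClassParams, obj$params)
  new("StrucClassModel", coefficients = coefs,
      center = stats::setNames(as.numeric(obj$standardization$center),
                               obj$feature_names),
      scale = stats::setNames(as.numeric(obj$standardization$scale),
                              obj$feature_names),
      selected = lapply(obj$selected, as.integer), params = params)
}
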
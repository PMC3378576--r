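#' Extract features for a table of domains
#'
#' File-level convenience used by the command-line interface: for each row
#' of a domain interval table, reads the parent protein's ASCII PSSM
#' (`<parent_id>.pssm` under `pssmDir`), slices the domain's interval out
#' of it and extracts the 440-dimensional feature vector.
#'
#' @param domains `data.frame` from [readDomainTable()].
#' @param pssmDir Directory holding one `<parent_id>.pssm` file per parent
#'   sequence.
#' @param params See [strucClassParams()].
#' @return Numeric `n x 440` matrix with domain ids as row names.
#' @export
extractDomainFeatures <- function(domains, pssmDir,
                                  params = strucClassParams()) {
  stopifnot(is.data.frame(domains))
  X <- matrix(NA_real_, nrow(domains), 440L,
              dimnames = list(domains$domain_id, featureNames()))
  cache <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(domains))) {
    pid <- domains$parent_id[r]
    if (is.null(cache[[pid]]))
      cache[[pid]] <- readPSSM(file.path(pssmDir, paste0(pid, ".pssm")))
    dom <- sliceDomain(cache[[pid]], domains$start[r], domains$end[r])
    X[r, ] <- extractFeatures(dom, params)
  }
  X
}

#' Assemble a DomainSet from file-level inputs
#'
#' Joins a feature matrix, a secondary-structure table and class labels on
#' domain id into a [DomainSet-class], erroring on missing entries.
#'
#' @param features `n x 440` matrix with domain-id row names.
#' @param ss Named character vector of secondary-structure strings.
#' @param classLabel Named vector of class labels.
#' @return A [DomainSet-class].
#' @export
assembleDomainSet <- function(features, ss, classLabel) {
  ids <- rownames(features)
  missSS <- setdiff(ids, names(ss))
  if (length(missSS))
    stop("no secondary-structure string for: ",
         paste(utils::head(missSS, 5), collapse = ", "))
  missCl <- setdiff(ids, names(classLabel))
  if (length(missCl))
    stop("no class label for: ",
         paste(utils::head(missCl, 5), collapse = ", "))
  DomainSet(ids, features, ss[ids], classLabel[ids])
}
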
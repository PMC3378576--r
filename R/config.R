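# Run configuration: documented defaults merged with an optional YAML
# config file; unknown keys are rejected.

#' Default run configuration
#'
#' Every tunable setting of the pipeline with its documented default, in
#' the nested sections the YAML config file uses: `targets` (window length
#' `k0`, threshold `theta`, stabiliser `delta`, sign margin `margin`),
#' `regression` (`ridge_lambda`, feature budget `select`, `NULL` = all
#' 440), `simulate` (`n_per_class`, `length_min`, `length_max`,
#' `pssm_noise_sd`, `signal_strength`) and `evaluate` (`folds`).
#'
#' @return Nested named list of settings.
#' @export
defaultRunConfig <- function() {
  list(
    targets = list(k0 = 8, theta = 0.1, delta = 1e-6, margin = 0.05),
    regression = list(ridge_lambda = 1e-8, select = NULL),
    simulate = list(n_per_class = 250, length_min = 60, length_max = 300,
                    pssm_noise_sd = 1, signal_strength = 1),
    evaluate = list(folds = 10))
}

#' Load and merge a run configuration
#'
#' Reads a YAML config file and merges it over [defaultRunConfig()]:
#' file values override defaults; keys not present in the defaults are
#' rejected with an error naming them.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Nested named list of settings.
#' @export
loadRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop("config file must be a YAML mapping")
  for (section in names(user)) {
    if (!section %in% names(cfg))
      stop("unknown config section '", section, "'")
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]]))
        stop("unknown config key '", section, ".", key, "'")
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  cfg
}

#' Parameter list from a run configuration
#'
#' @param cfg Nested list from [loadRunConfig()].
#' @return A [strucClassParams()] list.
#' @export
paramsFromConfig <- function(cfg) {
  strucClassParams(k0 = cfg$targets$k0, theta = cfg$targets$theta,
                   delta = cfg$targets$delta, margin = cfg$targets$margin,
                   ridgeLambda = cfg$regression$ridge_lambda)
}
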
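#' Read an experiment configuration from a YAML or JSON file
#'
#' The file is a plain key-value mapping with two blocks plus run settings:
#'
#' ```yaml
#' scheme: "5-10-15"          # or {low: 5, high: 15, risk_averse: 10, p_high: 0.5}
#' events: 1                  #    or {p_high: 0.1, mean: 10, variance: 25}
#' selection: {kind: power, z: 1.26}
#' N: 100
#' initial_k: 50              # optional, default floor(N/2)
#' replicates: 5000
#' base_seed: 1
#' max_generations: 1e6       # optional
#' empty_parent_policy: error # optional
#' ```
#'
#' A scheme given as a string uses the `"low-riskaverse-high"` shorthand with
#' the mean-matching `p_high`; a mapping with `mean` and `variance` goes
#' through [scheme_from_moments()]; otherwise `low`/`high` (and optionally
#' `risk_averse`, `p_high`) are passed to [payoff_scheme()].
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return An [experiment_config()].
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `N:` key as a boolean; restore the intended name
  names(cfg)[names(cfg) %in% c("FALSE", "false")] <- "N"
  for (field in c("scheme", "selection", "N"))
    if (is.null(cfg[[field]]))
      stop("configuration is missing required field '", field, "'")
  events <- if (is.null(cfg$events)) 1L else as.integer(cfg$events)
  scheme <- .scheme_from_config(cfg$scheme, events)
  selection <- as_selection_scheme(cfg$selection)
  experiment_config(
    scheme = scheme, selection = selection, N = cfg$N,
    initial_k = cfg$initial_k,
    replicates = if (is.null(cfg$replicates)) 2000L else cfg$replicates,
    base_seed = if (is.null(cfg$base_seed)) 1L else cfg$base_seed,
    max_generations = if (is.null(cfg$max_generations)) 1e6 else as.double(cfg$max_generations),
    empty_parent_policy = if (is.null(cfg$empty_parent_policy)) "error" else cfg$empty_parent_policy)
}

.scheme_from_config <- function(x, events) {
  if (inherits(x, "payoff_scheme")) return(x)
  if (is.character(x))
    return(parse_scheme_string(x, events = events))
  stopifnot(is.list(x))
  if (!is.null(x$events)) events <- as.integer(x$events)
  if (!is.null(x$mean) && !is.null(x$variance)) {
    if (is.null(x$p_high))
      stop("moment-constrained scheme requires 'p_high'")
    return(scheme_from_moments(
      x$p_high, x$mean, x$variance,
      risk_averse = if (is.null(x$risk_averse)) x$mean else x$risk_averse,
      events = events))
  }
  if (is.null(x$low) || is.null(x$high))
    stop("scheme mapping requires either {low, high} or {p_high, mean, variance}")
  payoff_scheme(x$low, x$high,
                risk_averse = if (is.null(x$risk_averse)) 10 else x$risk_averse,
                p_high = x$p_high, events = events)
}

#' Write replicate results or scenario summaries to CSV
#'
#' @param results A data frame ([run_replicates()] or [run_scenario()]
#'   output).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
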
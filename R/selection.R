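#' Selection (reproduction) schemes
#'
#' A selection scheme maps the vector of accumulated payoffs realized in a
#' generation to the probability that each individual parents a given
#' offspring. Five schemes are available:
#'
#' * **proportional** — reproduction weight linear in accumulated payoff.
#' * **truncation (rank-based)** — only the top fraction `threshold` of the
#'   population by payoff rank reproduce, all with equal weight; ties at the
#'   cutoff are broken uniformly at random.
#' * **truncation (absolute)** — individuals whose accumulated payoff reaches a
#'   fixed cutoff reproduce with equal weight, however many they are.
#' * **power-weighted** — weight proportional to `payoff^z`; `z > 1` gives a
#'   convex fitness function, `z < 1` a concave one, and `z = 1` recovers
#'   proportional selection.
#' * **sigmoid-weighted** — weight proportional to a logistic transform of the
#'   payoff after normalizing by the generation's maximum payoff (the
#'   best-scoring individual has normalized payoff 1):
#'   `1 / (1 + exp(-steepness * (p_n - inflection)))`.
#'
#' @param threshold Top fraction of the population allowed to reproduce, in
#'   `(0, 1]` (rank-based truncation).
#' @param cutoff Absolute accumulated-payoff cutoff (absolute truncation).
#' @param z Nonnegative exponent of the power-weighted fitness function.
#' @param steepness Positive logistic steepness (sigmoid).
#' @param inflection Inflection point of the logistic on the normalized payoff
#'   scale, in `(0, 1]` (sigmoid).
#' @return An object of class `selection_scheme`.
#' @examples
#' selection_proportional()
#' selection_truncation(0.5)
#' selection_power(1.26)
#' selection_sigmoid(steepness = 10, inflection = 2/3)
#' @name selection_scheme
NULL

.new_selection <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "selection_scheme")
}

#' @rdname selection_scheme
#' @export
selection_proportional <- function() .new_selection("proportional")

#' @rdname selection_scheme
#' @export
selection_truncation <- function(threshold = 0.5) {
  stopifnot(length(threshold) == 1L, is.finite(threshold))
  if (threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]")
  .new_selection("truncation_rank", threshold = as.double(threshold))
}

#' @rdname selection_scheme
#' @export
selection_truncation_absolute <- function(cutoff) {
  stopifnot(length(cutoff) == 1L, is.finite(cutoff))
  .new_selection("truncation_absolute", cutoff = as.double(cutoff))
}

#' @rdname selection_scheme
#' @export
selection_power <- function(z) {
  stopifnot(length(z) == 1L, is.finite(z))
  if (z < 0) stop("'z' must be nonnegative")
  .new_selection("power", z = as.double(z))
}

#' @rdname selection_scheme
#' @export
selection_sigmoid <- function(steepness = 10, inflection = 2 / 3) {
  stopifnot(length(steepness) == 1L, is.finite(steepness),
            length(inflection) == 1L, is.finite(inflection))
  if (steepness <= 0) stop("'steepness' must be positive")
  if (inflection <= 0 || inflection > 1)
    stop("'inflection' must lie in (0, 1] (normalized payoff scale)")
  .new_selection("sigmoid", steepness = as.double(steepness),
                 inflection = as.double(inflection))
}

#' Build a selection scheme from a tagged list
#'
#' Used when reading configurations: the list must carry a `kind` field plus
#' exactly the parameters that kind requires; extraneous parameters are
#' rejected.
#'
#' @param x A list, e.g. `list(kind = "power", z = 1.26)`.
#' @return A `selection_scheme`.
#' @export
as_selection_scheme <- function(x) {
  if (inherits(x, "selection_scheme")) return(x)
  stopifnot(is.list(x), !is.null(x$kind))
  kind <- match.arg(x$kind, c("proportional", "truncation_rank",
                              "truncation_absolute", "power", "sigmoid"))
  required <- switch(kind,
    proportional = character(),
    truncation_rank = "threshold",
    truncation_absolute = "cutoff",
    power = "z",
    sigmoid = c("steepness", "inflection"))
  extra <- setdiff(names(x), c("kind", required))
  if (length(extra))
    stop(sprintf("scheme '%s' does not accept parameter(s): %s",
                 kind, paste(extra, collapse = ", ")))
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(sprintf("scheme '%s' requires parameter(s): %s",
                 kind, paste(missing, collapse = ", ")))
  switch(kind,
    proportional = selection_proportional(),
    truncation_rank = selection_truncation(x$threshold),
    truncation_absolute = selection_truncation_absolute(x$cutoff),
    power = selection_power(x$z),
    sigmoid = selection_sigmoid(x$steepness, x$inflection))
}

#' @export
print.selection_scheme <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat(sprintf("Selection scheme: %s", x$kind))
  if (length(pars))
    cat(" (", paste(sprintf("%s = %g", names(pars), unlist(pars)),
                    collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}
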
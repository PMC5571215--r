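#' Wilson score confidence interval for a proportion
#'
#' The Wilson interval behaves well near 0 and 1, which matters here because
#' fixation proportions close to 1 (e.g. 95.5%) are routine.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level (default 0.95).
#' @return A named numeric vector `c(low, high)`.
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Summarize fixation outcomes of replicate runs
#'
#' Estimates the fixation probability of the risk-averse strategy from a set
#' of replicate runs and tests it against a null proportion with a one-sample
#' proportion z-test (normal approximation,
#' `z = (p - p0) / sqrt(p0 (1 - p0) / n)`). Both the one-tailed p-value (in
#' the direction of the observed deviation) and the two-tailed p-value are
#' reported; the significance flag uses the one-tailed value at `alpha`
#' (default 0.001). For 0/1 fixation outcomes a t-test and the z-test
#' coincide asymptotically; the z-test is the primary statistic.
#'
#' @param results A data frame from [run_replicates()] (column
#'   `fixed_strategy`), or a character vector of fixed strategies.
#' @param null_proportion Null fixation probability of the risk-averse
#'   strategy (default 0.5, the neutral value from a 50/50 start).
#' @param alpha Significance level (default 0.001).
#' @param conf_level Confidence level of the Wilson interval.
#' @return An object of class `fixation_estimate`: a list with
#'   `n_replicates`, `n_fixed_risk_averse`, `proportion` (risk-averse),
#'   `ci_low`, `ci_high`, `z`, `p_one_tailed`, `p_two_tailed`, `significant`,
#'   `null_proportion`, `alpha`.
#' @examples
#' est <- summarize_fixation(rep(c("risk_averse", "risk_prone"), c(2700, 2300)))
#' est$z            # about 5.66
#' est$significant  # TRUE at alpha = 0.001
#' @export
summarize_fixation <- function(results, null_proportion = 0.5, alpha = 0.001,
                               conf_level = 0.95) {
  fixed <- if (is.data.frame(results)) results$fixed_strategy else results
  if (is.null(fixed) || length(fixed) == 0L)
    stop("no replicate results supplied")
  bad <- setdiff(unique(fixed), c("risk_averse", "risk_prone"))
  if (length(bad))
    stop("unknown fixed_strategy value(s): ", paste(bad, collapse = ", "))
  stopifnot(null_proportion >= 0, null_proportion <= 1)
  n <- length(fixed)
  x <- sum(fixed == "risk_averse")
  p <- x / n
  ci <- wilson_ci(x, n, conf_level)
  se0 <- sqrt(null_proportion * (1 - null_proportion) / n)
  z <- if (se0 > 0) (p - null_proportion) / se0 else Inf * sign(p - null_proportion)
  p_one <- stats::pnorm(abs(z), lower.tail = FALSE)
  structure(list(
    n_replicates = n,
    n_fixed_risk_averse = x,
    proportion = p,
    ci_low = unname(ci["low"]),
    ci_high = unname(ci["high"]),
    z = z,
    p_one_tailed = p_one,
    p_two_tailed = min(1, 2 * p_one),
    significant = p_one < alpha,
    null_proportion = null_proportion,
    alpha = alpha), class = "fixation_estimate")
}

#' Check a fixation estimate against a target within a sampling-error band
#'
#' Passes when the estimated proportion is within
#' `multiplier * sqrt(target (1 - target) / n)` of the target — the natural
#' acceptance band for a Monte Carlo proportion.
#'
#' @param estimate A [summarize_fixation()] result.
#' @param target Target proportion.
#' @param se_multiplier Width of the band in binomial standard errors
#'   (default 3).
#' @return `TRUE` or `FALSE`, with attributes `deviation` and `band`.
#' @export
compare_to_null_band <- function(estimate, target, se_multiplier = 3) {
  stopifnot(inherits(estimate, "fixation_estimate"),
            target >= 0, target <= 1)
  band <- se_multiplier * sqrt(target * (1 - target) / estimate$n_replicates)
  dev <- abs(estimate$proportion - target)
  structure(dev <= band, deviation = dev, band = band)
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("Fixation of risk-averse strategy: %.4f (%d of %d replicates)\n",
              x$proportion, x$n_fixed_risk_averse, x$n_replicates))
  cat(sprintf("  95%% Wilson CI [%.4f, %.4f]\n", x$ci_low, x$ci_high))
  cat(sprintf("  z = %.3f vs null %.3f; p = %.4g (one-tailed), %.4g (two-tailed)%s\n",
              x$z, x$null_proportion, x$p_one_tailed, x$p_two_tailed,
              if (x$significant) sprintf(" [significant at alpha = %g]", x$alpha)
              else " [not significant]"))
  invisible(x)
}

#' @export
as.data.frame.fixation_estimate <- function(x, ...) {
  data.frame(n = x$n_replicates,
             n_risk_averse = x$n_fixed_risk_averse,
             proportion_risk_averse = x$proportion,
             ci_low = x$ci_low, ci_high = x$ci_high,
             z = x$z, p_one_tailed = x$p_one_tailed,
             p_two_tailed = x$p_two_tailed,
             significant = x$significant)
}
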
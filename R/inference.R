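# Wilson score interval for a binomial proportion; vectorised closed form
wilson_interval <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Estimate cooperator frequency from colony counts
#'
#' The cooperator frequency is one minus the resistant fraction (resistant
#' colonies are cheaters, which carry the hygromycin cassette):
#' `p_hat = 1 - n_resistant / n_colonies`, with a Wilson score confidence
#' interval. The Wilson interval is used instead of the Wald interval for
#' its behaviour near 0 and 1, where trajectories close to exclusion or
#' fixation live.
#'
#' @param data A data frame with columns `n_resistant` and `n_colonies`
#'   (e.g. from [generate_coevolution_dataset()]), or a numeric vector of
#'   resistant counts (then supply `n_colonies`).
#' @param n_colonies Colonies scored; only used when `data` is a numeric
#'   vector.
#' @param level Confidence level. Default 0.95.
#'
#' @return If `data` is a data frame, `data` with columns `p_hat`,
#'   `ci_low`, `ci_high` appended; otherwise a tibble with columns
#'   `p_hat`, `ci_low`, `ci_high`, `n`.
#'
#' @examples
#' estimate_frequency(140, n_colonies = 200)  # the 3:7 early-batch reading
#' @export
estimate_frequency <- function(data, n_colonies = NULL, level = 0.95) {
  if (is.data.frame(data)) {
    if (!all(c("n_resistant", "n_colonies") %in% names(data))) {
      abort("`data` must have columns `n_resistant` and `n_colonies`.",
            class = "privcoop_domain_error")
    }
    k <- data$n_resistant
    n <- data$n_colonies
  } else {
    if (is.null(n_colonies)) {
      abort("supply `n_colonies` when `data` is a count vector.",
            class = "privcoop_domain_error")
    }
    k <- data
    n <- rep_len(n_colonies, length(k))
  }
  if (any(!is.finite(k)) || any(!is.finite(n)) || any(n < 1) ||
      any(k < 0) || any(k > n)) {
    abort("need 0 <= n_resistant <= n_colonies and n_colonies >= 1.",
          class = "privcoop_domain_error")
  }
  ci <- wilson_interval(n - k, n, level)  # interval on the cooperator share
  if (is.data.frame(data)) {
    dplyr::mutate(data, p_hat = 1 - k / n, ci_low = ci$low, ci_high = ci$high)
  } else {
    tibble::tibble(p_hat = 1 - k / n, ci_low = ci$low, ci_high = ci$high,
                   n = as.integer(n))
  }
}

#' Summarize replicate lines per assay generation
#'
#' Collapses a long assay table to the across-line mean and standard
#' deviation of the estimated cooperator frequency at each assay
#' generation, the summary plotted as the solid mean line over the
#' replicate trajectories.
#'
#' @param records A data frame with columns `line_id`, `generation`,
#'   `n_resistant`, `n_colonies` (the [generate_coevolution_dataset()]
#'   layout).
#' @return A tibble with columns `generation`, `mean_p`, `sd_p`,
#'   `n_lines`, one row per generation (`sd_p` is 0 for a single line).
#' @examples
#' d <- coevolution_design(truth = coop_params(alpha = 0, C = 0),
#'                         n_lines = 3, master_seed = 2)
#' generate_coevolution_dataset(d) |> summarize_lines()
#' @export
summarize_lines <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    abort("`records` must be a non-empty data frame.",
          class = "privcoop_domain_error")
  }
  needed <- c("line_id", "generation", "n_resistant", "n_colonies")
  if (!all(needed %in% names(records))) {
    abort(sprintf("`records` must have columns %s.",
                  paste0("`", needed, "`", collapse = ", ")),
          class = "privcoop_domain_error")
  }
  estimate_frequency(records) |>
    dplyr::group_by(.data$generation) |>
    dplyr::summarise(
      mean_p = mean(.data$p_hat),
      sd_p = if (dplyr::n() > 1L) sd(.data$p_hat) else 0,
      n_lines = dplyr::n_distinct(.data$line_id),
      .groups = "drop"
    )
}

#' Compare two groups of frequencies with a Student's t-test
#'
#' Classical two-sample Student's t-test (pooled variance) or its paired
#' variant, two-sided, on per-line frequency values — the test used
#' throughout for ancestor-vs-evolved comparisons. Welch's unequal-variance
#' form is available behind a flag. Two groups that are each constant with
#' equal means have no variance to test against and return `t = 0`,
#' `p = 1` by convention.
#'
#' @param a,b Numeric vectors of frequencies (each of length >= 2; equal
#'   lengths when `paired`).
#' @param paired Paired test? Default `FALSE` (unpaired).
#' @param welch Use Welch's unequal-variance form instead of the pooled
#'   variance? Default `FALSE`.
#'
#' @return A one-row tibble with columns `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `mean_difference` (`mean(a) -
#'   mean(b)`, or `mean(a - b)` when paired) and `method`.
#'
#' @examples
#' compare_groups(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
#' @export
compare_groups <- function(a, b, paired = FALSE, welch = FALSE) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) < 2L || length(b) < 2L) {
    abort("`a` and `b` must each hold at least two values.",
          class = "privcoop_domain_error")
  }
  if (paired && length(a) != length(b)) {
    abort("paired comparison needs equal-length groups.",
          class = "privcoop_domain_error")
  }
  mean_diff <- if (paired) mean(a - b) else mean(a) - mean(b)
  # constant data (up to rounding) has no variance to test against:
  # equal means are a no-signal convention, unequal means are an
  # infinitely strong signal
  tiny <- function(v) sd(v) < 1e-10 * max(1, abs(mean(v)))
  degenerate <- if (paired) tiny(a - b) else tiny(a) && tiny(b)
  if (degenerate) {
    df <- if (paired) length(a) - 1L else length(a) + length(b) - 2L
    no_diff <- abs(mean_diff) < 1e-10
    return(tibble::tibble(
      t_statistic = if (no_diff) 0 else sign(mean_diff) * Inf,
      degrees_of_freedom = as.numeric(df),
      p_value = if (no_diff) 1 else 0,
      mean_difference = if (no_diff) 0 else mean_diff,
      method = if (paired) "paired t" else "pooled t"
    ))
  }
  tt <- t.test(a, b, paired = paired, var.equal = !welch,
               alternative = "two.sided")
  tibble::tibble(
    t_statistic = unname(tt$statistic),
    degrees_of_freedom = unname(tt$parameter),
    p_value = tt$p.value,
    mean_difference = mean_diff,
    method = if (paired) "paired t" else if (welch) "Welch t" else "pooled t"
  )
}
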
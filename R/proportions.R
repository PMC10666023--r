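#' Binomial proportion summary with exact confidence interval
#'
#' Summarizes `k` successes out of `n` trials as an integer percentage
#' (rounded half away from zero) with an exact Clopper-Pearson 95%
#' confidence interval computed from beta quantiles:
#' lower = `qbeta(alpha/2, k, n - k + 1)` (0 when `k = 0`),
#' upper = `qbeta(1 - alpha/2, k + 1, n - k)` (1 when `k = n`).
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `proportion_summary` with fields `k`, `n`,
#'   `percent` (integer), `estimate` (k/n) and `ci` (length-2 numeric in
#'   [0, 1]).
#' @examples
#' proportion_from_counts(8, 9)$percent   # 89
#' proportion_from_counts(32, 59)$percent # 54
#' @export
proportion_from_counts <- function(k, n, conf = 0.95) {
  if (!is_count(n) || n <= 0) stop("n must be a positive count")
  if (!is_count(k)) stop("k must be a nonnegative count")
  if (k > n) stop("k must not exceed n")
  alpha <- 1 - conf
  lower <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  structure(list(k = k, n = n,
                 estimate = k / n,
                 percent = as.integer(round_half_away(100 * k / n)),
                 ci = c(lower, upper), conf = conf),
            class = "proportion_summary")
}

#' @export
print.proportion_summary <- function(x, ...) {
  cat(sprintf("%d%% (%d out of %d), %d%% CI [%.3f, %.3f]\n",
              x$percent, x$k, x$n, round(100 * x$conf), x$ci[1], x$ci[2]))
  invisible(x)
}
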
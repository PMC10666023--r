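#' @noRd
#' Symmetric Hann (raised-cosine) window of odd length M, rescaled to unit
#' sum so that smoothing preserves the local mean. The endpoint taps are
#' zero, as in the standard "periodic-symmetric" definition
#' w[k] = 0.5 * (1 - cos(2*pi*k / (M - 1))).
hann_window <- function(M) {
  if (M == 1) return(1)
  k <- 0:(M - 1)
  w <- 0.5 * (1 - cos(2 * pi * k / (M - 1)))
  w / sum(w)
}

#' Smooth a signal vector with a unit-sum Hann window
#'
#' Convolves `values` with a Hann window rescaled to unit sum. Edges are
#' handled by reflection padding, so a constant vector is returned
#' unchanged and the vector sum is preserved away from the edges.
#'
#' @param values Numeric vector.
#' @param window_bins Odd window length in bins; `1` is the identity. Must
#'   not exceed `length(values)`.
#' @return A numeric vector of the same length.
#' @examples
#' hann_smooth(c(0, 0, 1, 0, 0), 3)
#' @export
hann_smooth <- function(values, window_bins) {
  stopifnot(is.numeric(values))
  if (!is_count(window_bins, min = 1) || window_bins %% 2 == 0) {
    stop("window_bins must be an odd positive integer")
  }
  n <- length(values)
  if (window_bins > n) {
    stop("window_bins (", window_bins, ") exceeds vector length (", n, ")")
  }
  if (window_bins == 1) return(values)
  h <- (window_bins - 1) / 2
  w <- hann_window(window_bins)
  padded <- c(values[(h + 1):2], values, values[(n - 1):(n - h)])
  out <- stats::filter(padded, w, method = "convolution", sides = 2)
  as.numeric(out[(h + 1):(h + n)])
}
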
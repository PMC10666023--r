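#' Resection-length distribution from a co-oriented profile
#'
#' Converts a combined co-oriented average profile into the fraction of
#' resection-endpoint signal per distance bin. The estimated background
#' (profile value at `+background_offset_bp`) is subtracted; offsets at or
#' below `core_exclusion_bp` (central recombination-intermediate signal)
#' and beyond `background_offset_bp` are zeroed; negatives are clamped to
#' 0; the remaining signal is summed into `resection_bin_bp`-wide bins and
#' divided by its total.
#'
#' A profile with no resection signal is flagged degenerate rather than
#' erroring: either nothing remains after exclusion, or — because sampling
#' noise always leaves a small positive residue after clamping — the
#' resection window shows no real enrichment over the background estimate
#' (its maximum is below `min_peak_enrichment` times the background value).
#' Profiles from DSB-proficient samples exceed that ratio by an order of
#' magnitude; background-only controls sit near 1.
#'
#' @param profile A combined `cooriented_profile` covering
#'   `(0, background_offset_bp]`.
#' @param cfg An [analysis_config()].
#' @param min_peak_enrichment Minimum ratio of the resection-window
#'   maximum to the background value for the signal to count as real;
#'   ignored when the background estimate is zero.
#' @return An object of class `resection_distribution` with fields
#'   `bin_start`, `bin_end` (bp), `fraction`, `degenerate`. A degenerate
#'   distribution is all-zero (not an error).
#' @export
resection_length_distribution <- function(profile,
                                          cfg = analysis_config(),
                                          min_peak_enrichment = 3) {
  if (!profile$combined) stop("profile must be combined-strand")
  d <- profile$distances
  if (max(d) < cfg$background_offset_bp) {
    stop("profile must extend to background_offset_bp")
  }
  bg <- profile$values[match(cfg$background_offset_bp, d)]
  v <- profile$values - bg
  v[d <= cfg$core_exclusion_bp | d > cfg$background_offset_bp] <- 0
  v[v < 0] <- 0
  starts <- seq(cfg$core_exclusion_bp,
                cfg$background_offset_bp - cfg$resection_bin_bp,
                by = cfg$resection_bin_bp)
  sums <- vapply(starts, function(a) {
    sum(v[d > a & d <= a + cfg$resection_bin_bp])
  }, numeric(1))
  total <- sum(sums)
  win <- d > cfg$core_exclusion_bp & d <= cfg$background_offset_bp
  no_enrichment <- bg > 0 &&
    max(profile$values[win]) < min_peak_enrichment * bg
  degenerate <- total <= 0 || no_enrichment
  structure(list(bin_start = starts,
                 bin_end = starts + cfg$resection_bin_bp,
                 fraction = if (degenerate) sums * 0 else sums / total,
                 n_bins = length(starts),
                 degenerate = degenerate),
            class = "resection_distribution")
}

#' @export
print.resection_distribution <- function(x, ...) {
  if (x$degenerate) {
    cat("resection_distribution: degenerate (no signal after exclusion)\n")
  } else {
    cat("resection_distribution:", x$n_bins, "bins, mean",
        round(mean_resection_length(x), 1), "nt\n")
  }
  invisible(x)
}

#' Mean resection length of a distribution
#'
#' The bin-midpoint weighted mean of the fraction histogram: the midpoint
#' of `(a, a + w]` is `a + w/2`.
#'
#' @param dist A non-degenerate `resection_distribution`.
#' @return Mean resection length in nt.
#' @export
mean_resection_length <- function(dist) {
  if (dist$degenerate) {
    stop("cannot compute the mean of a degenerate (all-zero) distribution")
  }
  mid <- (dist$bin_start + dist$bin_end) / 2
  sum(dist$fraction * mid)
}

#' Compare resection-length distributions between two samples
#'
#' Reports the difference in mean resection length, `mean(a) - mean(b)`.
#' When both profiles carry per-hotspot matrices (built with
#' `cooriented_average(..., keep_per_hotspot = TRUE)`), a bootstrap over
#' hotspots — the natural unit of replication — yields a percentile
#' confidence interval: hotspots are resampled with replacement, the mean
#' profile is rebuilt, smoothed, and pushed through the same
#' background-subtraction and binning path.
#'
#' @param dist_a,dist_b Non-degenerate `resection_distribution`s.
#' @param profile_a,profile_b Optional `cooriented_profile`s with
#'   `per_hotspot` matrices, for the bootstrap CI.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @param cfg The [analysis_config()] used to build the distributions.
#' @param conf Confidence level of the percentile interval.
#' @return A list with `delta_mean` (nt), `ci` (length-2 vector or `NULL`
#'   when no per-hotspot profiles were supplied), and `n_boot`.
#' @export
compare_resection <- function(dist_a, dist_b,
                              profile_a = NULL, profile_b = NULL,
                              n_boot = 1000, seed = 1,
                              cfg = analysis_config(), conf = 0.95) {
  if (dist_a$degenerate || dist_b$degenerate) {
    stop("cannot compare degenerate resection distributions")
  }
  delta <- mean_resection_length(dist_a) - mean_resection_length(dist_b)
  ci <- NULL
  if (!is.null(profile_a) && !is.null(profile_b)) {
    if (is.null(profile_a$per_hotspot) || is.null(profile_b$per_hotspot)) {
      stop("profiles must be built with keep_per_hotspot = TRUE")
    }
    boots <- with_seed(seed, {
      ma <- boot_mean_lengths(profile_a, n_boot, cfg)
      mb <- boot_mean_lengths(profile_b, n_boot, cfg)
      ma - mb
    })
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  list(delta_mean = delta, ci = ci, n_boot = if (is.null(ci)) 0 else n_boot)
}

#' @noRd
#' Bootstrap distribution of the mean resection length for one sample:
#' resample hotspots, rebuild the mean combined profile over
#' [0, background_offset], Hann-smooth, then reuse the distribution path.
boot_mean_lengths <- function(profile, n_boot, cfg) {
  mat <- profile$per_hotspot
  nh <- nrow(mat)
  bin <- profile$bin_size
  d <- (0:(ncol(mat) - 1)) * bin
  wb <- as.integer(cfg$hann_window_bp / bin)
  if (wb %% 2L == 0L) wb <- wb + 1L
  starts <- seq(cfg$core_exclusion_bp,
                cfg$background_offset_bp - cfg$resection_bin_bp,
                by = cfg$resection_bin_bp)
  mids <- starts + cfg$resection_bin_bp / 2
  vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nh, nh, replace = TRUE)
    w <- tabulate(idx, nbins = nh)
    prof <- as.numeric(w %*% mat) / nh
    prof <- hann_smooth(prof, wb)
    bgv <- prof[match(cfg$background_offset_bp, d)]
    v <- prof - bgv
    v[d <= cfg$core_exclusion_bp | d > cfg$background_offset_bp] <- 0
    v[v < 0] <- 0
    tot <- sum(v)
    if (tot <= 0) return(NA_real_)
    sums <- vapply(starts, function(a) {
      sum(v[d > a & d <= a + cfg$resection_bin_bp])
    }, numeric(1))
    sum(sums / tot * mids)
  }, numeric(1))
}

#' Write or read a resection distribution as TSV
#'
#' Columns: `bin_start`, `bin_end`, `fraction`.
#'
#' @param dist A `resection_distribution`.
#' @param path File path.
#' @return `read_resection_tsv()` returns a `resection_distribution`.
#' @export
write_resection_tsv <- function(dist, path) {
  write.table(data.frame(bin_start = dist$bin_start,
                         bin_end = dist$bin_end,
                         fraction = dist$fraction),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_resection_tsv
#' @export
read_resection_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  structure(list(bin_start = df$bin_start, bin_end = df$bin_end,
                 fraction = df$fraction, n_bins = nrow(df),
                 degenerate = sum(df$fraction) <= 0),
            class = "resection_distribution")
}
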
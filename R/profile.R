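#' Hotspot-centered co-oriented average profile
#'
#' For every usable hotspot, extracts top-strand signal at offsets
#' `d` in `[-flank, +flank]` from the center and bottom-strand signal at
#' `-d` (the flip that superimposes leftward resection on the rightward
#' axis), then averages across hotspots. Hotspots whose window would run
#' past a chromosome end are skipped (and counted), not zero-padded, so
#' they cannot bias the average. Averaging is unweighted by default; set
#' `weight_by_heat = TRUE` to weight hotspots by their heat.
#'
#' @param track A `strand_track` whose `bin_size` equals
#'   `cfg$profile_bin_bp`.
#' @param hotspots A non-empty `hotspot_set`.
#' @param cfg An [analysis_config()].
#' @param combine If `TRUE` (default) the returned `values` are
#'   top + flipped-bottom; the two components are kept either way.
#' @param weight_by_heat Weight hotspots by heat instead of equally.
#' @param keep_per_hotspot If `TRUE`, retain the per-hotspot combined
#'   values at offsets `0..background_offset_bp` (matrix, one row per used
#'   hotspot) for bootstrap resampling in [compare_resection()].
#'
#' @return An object of class `cooriented_profile` with fields
#'   `distances` (bp offsets), `values`, `top`, `bottom_flipped`,
#'   `n_hotspots`, `n_skipped`, `combined`, `normalized`.
#' @export
cooriented_average <- function(track, hotspots, cfg = analysis_config(),
                               combine = TRUE, weight_by_heat = FALSE,
                               keep_per_hotspot = FALSE) {
  if (track$bin_size != cfg$profile_bin_bp) {
    stop("track bin size (", track$bin_size, ") must equal profile_bin_bp (",
         cfg$profile_bin_bp, ")")
  }
  if (nrow(hotspots) == 0) stop("hotspot set is empty")
  bin <- track$bin_size
  fb <- floor(cfg$profile_flank_bp / bin)
  width <- 2L * fb + 1L
  bg_bin <- floor(cfg$background_offset_bp / bin)
  acc_top <- numeric(width)
  acc_bot <- numeric(width)
  wsum <- 0
  used <- 0L
  ph <- if (keep_per_hotspot) {
    matrix(0, nrow = nrow(hotspots), ncol = bg_bin + 1L)
  }
  nbins <- vapply(track$top, length, integer(1))
  for (i in seq_len(nrow(hotspots))) {
    nm <- hotspots$chrom[i]
    cb <- floor(hotspots$center[i] / bin)
    if (cb - fb < 0 || cb + fb >= nbins[[nm]]) next
    idx <- (cb - fb):(cb + fb) + 1L
    tvals <- track$top[[nm]][idx]
    bvals <- rev(track$bottom[[nm]][idx])
    w <- if (weight_by_heat) hotspots$heat[i] else 1
    acc_top <- acc_top + w * tvals
    acc_bot <- acc_bot + w * bvals
    wsum <- wsum + w
    used <- used + 1L
    if (keep_per_hotspot) {
      ph[used, ] <- tvals[(fb + 1L):(fb + 1L + bg_bin)] +
        bvals[(fb + 1L):(fb + 1L + bg_bin)]
    }
  }
  if (used == 0L) stop("no usable hotspots: every window ran past a ",
                       "chromosome end")
  if (used < nrow(hotspots)) {
    ds_log("skipped ", nrow(hotspots) - used,
           " hotspot(s) at chromosome edges")
  }
  top <- acc_top / wsum
  bot <- acc_bot / wsum
  structure(list(distances = (-fb:fb) * bin,
                 values = if (combine) top + bot else top,
                 top = top, bottom_flipped = bot,
                 n_hotspots = used,
                 n_skipped = nrow(hotspots) - used,
                 combined = combine, normalized = FALSE,
                 per_hotspot = if (keep_per_hotspot) {
                   ph[seq_len(used), , drop = FALSE]
                 },
                 bin_size = bin),
            class = "cooriented_profile")
}

#' @export
print.cooriented_profile <- function(x, ...) {
  cat("cooriented_profile:", x$n_hotspots, "hotspots,",
      min(x$distances), "..", max(x$distances), "bp,",
      if (x$combined) "combined strands," else "top strand,",
      if (x$normalized) "peak-normalized" else "raw", "\n")
  invisible(x)
}

#' Smooth a co-oriented profile
#'
#' Applies [hann_smooth()] to the profile values (and strand components).
#' The window is given in bp and converted to bins.
#'
#' @param profile A `cooriented_profile`.
#' @param window_bp Odd window length in bp.
#' @return The smoothed `cooriented_profile`.
#' @export
smooth_profile <- function(profile, window_bp = 151) {
  wb <- as.integer(window_bp / profile$bin_size)
  if (wb %% 2L == 0L) wb <- wb + 1L
  profile$values <- hann_smooth(profile$values, wb)
  profile$top <- hann_smooth(profile$top, wb)
  profile$bottom_flipped <- hann_smooth(profile$bottom_flipped, wb)
  profile
}

#' Normalize a profile to the resection-endpoint peak
#'
#' Removes the estimated background by subtracting the profile value at
#' `+background_offset_bp` (the co-oriented side), rescales so that the
#' maximum over `(core_exclusion_bp, background_offset_bp]` is 1, and
#' clamps negative values to 0. This puts genotypes with different
#' absolute signal levels on a comparable spatial scale.
#'
#' @param profile A combined `cooriented_profile` covering offsets through
#'   `background_offset_bp`.
#' @param cfg An [analysis_config()].
#' @return The normalized `cooriented_profile` (max 1 on the resection
#'   window, 0 at the background offset).
#' @export
normalize_to_resection_peak <- function(profile, cfg = analysis_config()) {
  if (!profile$combined) stop("profile must be combined-strand")
  d <- profile$distances
  if (max(d) < cfg$background_offset_bp) {
    stop("profile must extend to background_offset_bp")
  }
  bg <- profile$values[match(cfg$background_offset_bp, d)]
  v <- profile$values - bg
  win <- d > cfg$core_exclusion_bp & d <= cfg$background_offset_bp
  m <- max(v[win])
  if (m <= 0) stop("no resection signal: maximum after background ",
                   "subtraction is <= 0")
  v <- v / m
  v[v < 0] <- 0
  profile$values <- v
  profile$top <- NULL
  profile$bottom_flipped <- NULL
  profile$normalized <- TRUE
  profile
}

#' Write or read a profile as TSV (distance_bp, value)
#'
#' @param profile A `cooriented_profile`.
#' @param path File path.
#' @return `read_profile_tsv()` returns a `cooriented_profile` (combined,
#'   components absent).
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(data.frame(distance_bp = profile$distances,
                         value = profile$values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("distance_bp", "value") %in% names(df))) {
    stop("profile TSV must have columns distance_bp, value")
  }
  d <- df$distance_bp
  structure(list(distances = d, values = df$value,
                 top = NULL, bottom_flipped = NULL,
                 n_hotspots = NA_integer_, n_skipped = NA_integer_,
                 combined = TRUE, normalized = NA,
                 per_hotspot = NULL,
                 bin_size = if (length(d) > 1) d[2] - d[1] else 1),
            class = "cooriented_profile")
}
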
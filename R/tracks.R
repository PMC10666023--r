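#' Bin strand-specific end counts into a coverage track
#'
#' Each end record increments the bin `floor(pos / bin_size)` of its strand
#' on its chromosome. Total bin mass equals the record count exactly.
#'
#' @param ends An [end_map()].
#' @param genome A [genome_spec()].
#' @param bin_size Bin width in bp (>= 1).
#' @return An object of class `strand_track`: per-chromosome `top` and
#'   `bottom` numeric vectors of length `ceiling(length / bin_size)`, plus
#'   `n_mapped` and a `normalized` flag.
#' @export
bin_coverage <- function(ends, genome, bin_size = 1) {
  stopifnot(is_count(bin_size, min = 1))
  if (nrow(ends) > 0) check_chrom(genome, ends$chrom)
  nbins <- ceiling(genome$chroms / bin_size)
  top <- lapply(nbins, numeric)
  bottom <- lapply(nbins, numeric)
  if (nrow(ends) > 0) {
    bin1 <- floor(ends$pos / bin_size) + 1L
    for (nm in unique(ends$chrom)) {
      sel <- ends$chrom == nm
      is_top <- sel & ends$strand == "top"
      top[[nm]] <- tabulate(bin1[is_top], nbins = nbins[[nm]])
      bottom[[nm]] <- tabulate(bin1[sel & !is_top], nbins = nbins[[nm]])
    }
  }
  structure(list(genome = genome, bin_size = bin_size,
                 top = top, bottom = bottom,
                 n_mapped = nrow(ends), normalized = FALSE),
            class = "strand_track")
}

#' @export
print.strand_track <- function(x, ...) {
  cat("strand_track:", x$n_mapped, "reads,", x$bin_size, "bp bins,",
      if (x$normalized) "RPM" else "raw counts", "\n")
  invisible(x)
}

#' Normalize a track to reads per million mapped reads (RPM)
#'
#' Multiplies every bin by `1e6 / n_mapped`. Normalizing an
#' already-normalized track is an error, never a silent rescale.
#'
#' @param track A `strand_track` of raw counts with `n_mapped > 0`.
#' @return The RPM-scaled `strand_track`.
#' @export
rpm_normalize <- function(track) {
  if (track$normalized) stop("track is already RPM-normalized")
  if (track$n_mapped == 0) stop("cannot RPM-normalize a track of 0 reads")
  f <- 1e6 / track$n_mapped
  track$top <- lapply(track$top, `*`, f)
  track$bottom <- lapply(track$bottom, `*`, f)
  track$normalized <- TRUE
  track
}

#' @noRd
#' Element-wise average of RPM tracks from replicate libraries.
average_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  if (!all(vapply(tracks, `[[`, logical(1), "normalized"))) {
    stop("replicate tracks must be RPM-normalized before averaging")
  }
  out <- tracks[[1]]
  k <- length(tracks)
  if (k == 1) return(out)
  for (nm in names(out$top)) {
    out$top[[nm]] <- Reduce(`+`, lapply(tracks, function(t) t$top[[nm]])) / k
    out$bottom[[nm]] <-
      Reduce(`+`, lapply(tracks, function(t) t$bottom[[nm]])) / k
  }
  out$n_mapped <- mean(vapply(tracks, `[[`, numeric(1), "n_mapped"))
  out
}

#' Write one strand of a track as bedGraph
#'
#' Intervals are 0-based half-open at the track's bin size; zero bins are
#' omitted. Runs of equal-valued adjacent bins are merged.
#'
#' @param track A `strand_track`.
#' @param strand `"top"` or `"bottom"`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, strand = c("top", "bottom"), path) {
  strand <- match.arg(strand)
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (nm in names(track$genome$chroms)) {
    v <- track[[strand]][[nm]]
    nz <- which(v != 0)
    if (length(nz) == 0) next
    # merge adjacent equal-value bins into single intervals
    brk <- c(TRUE, diff(nz) != 1L | diff(v[nz]) != 0)
    grp <- cumsum(brk)
    first <- nz[brk]
    last <- nz[cumsum(tabulate(grp))]
    starts <- (first - 1) * bs
    ends <- pmin(last * bs, track$genome$chroms[[nm]])
    writeLines(paste(nm,
                     format(starts, scientific = FALSE, trim = TRUE),
                     format(ends, scientific = FALSE, trim = TRUE),
                     format(v[first], scientific = FALSE, trim = TRUE,
                            digits = 15),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' @noRd
#' Combined-strand (top + bottom) per-chromosome vectors.
combined_track_values <- function(track) {
  out <- track$top
  for (nm in names(out)) out[[nm]] <- out[[nm]] + track$bottom[[nm]]
  out
}

#' Total combined-strand signal over an interval
#'
#' Sums top + bottom track values across the 0-based half-open interval
#' `[start, end)`. Bins partially covered by the interval contribute in
#' proportion to their overlap. Units follow the track (RPM if normalized).
#'
#' @param track A `strand_track`.
#' @param chrom Chromosome name.
#' @param start,end Interval bounds (0-based half-open, bp).
#' @return A single number.
#' @export
interval_signal <- function(track, chrom, start, end) {
  check_chrom(track$genome, chrom)
  L <- track$genome$chroms[[chrom]]
  if (start < 0 || end > L || start >= end) {
    stop("interval out of bounds: ", chrom, ":", start, "-", end)
  }
  v <- track$top[[chrom]] + track$bottom[[chrom]]
  bs <- track$bin_size
  b0 <- floor(start / bs) + 1L
  b1 <- ceiling(end / bs)
  idx <- b0:b1
  w <- rep(1, length(idx))
  w[1] <- w[1] - (start / bs - (b0 - 1))
  w[length(w)] <- w[length(w)] - (b1 - end / bs)
  if (length(idx) == 1L) w <- (end - start) / bs
  sum(v[idx] * w)
}
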
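#' Call DSB peaks with a Poisson sliding-window test
#'
#' Slides a window (default 1,000 bp, step half a window) across each
#' chromosome of a combined-strand raw-count track and tests each window
#' count against a Poisson null whose rate is the genome-wide mean read
#' density times the window size. P values are Benjamini-Hochberg adjusted
#' across all tested windows; significant windows (adjusted p below
#' `q_threshold`) within `merge_gap` bp of each other are merged. The
#' summit is the maximum-signal bin of the merged interval and the fold
#' enrichment is the peak's densest window rate over the background rate.
#'
#' @param track A `strand_track` of raw counts (not RPM); top and bottom
#'   strands are summed internally.
#' @param window Window size in bp; must be a multiple of `2 * bin_size`.
#' @param q_threshold Adjusted-p cutoff.
#' @param merge_gap Maximum gap (bp) between significant windows merged
#'   into one peak.
#' @return A data frame of class `peak_set` with columns `chrom`, `start`,
#'   `end` (0-based half-open), `summit`, `score` (-log10 adjusted p),
#'   `fold_enrichment`. Zero rows when nothing is significant. The numbers
#'   of windows tested and of significant windows are attached as
#'   attributes `n_windows` and `n_sig_windows`.
#' @export
call_peaks <- function(track, window = 1000, q_threshold = 0.01,
                       merge_gap = 500) {
  if (track$normalized) {
    stop("peak calling requires raw counts, not an RPM track")
  }
  bs <- track$bin_size
  if (window %% (2 * bs) != 0) {
    stop("window must be a multiple of 2 * bin_size")
  }
  wbins <- window %/% bs
  sbins <- wbins %/% 2L
  rate <- track$n_mapped / genome_length(track$genome)  # reads per bp
  lambda <- rate * window

  win <- list()
  for (nm in names(track$genome$chroms)) {
    v <- track$top[[nm]] + track$bottom[[nm]]
    nb <- length(v)
    if (nb < wbins) next
    s0 <- seq(0L, nb - wbins, by = sbins)
    cum <- c(0, cumsum(v))
    counts <- cum[s0 + wbins + 1L] - cum[s0 + 1L]
    win[[nm]] <- data.frame(chrom = nm, start = s0 * bs,
                            end = (s0 + wbins) * bs, count = counts,
                            stringsAsFactors = FALSE)
  }
  if (length(win) == 0) {
    return(empty_peak_set(0L, 0L))
  }
  win <- do.call(rbind, win)
  n_windows <- nrow(win)
  win$p <- ppois(win$count - 1, lambda, lower.tail = FALSE)
  win$padj <- p.adjust(win$p, method = "BH")
  sig <- win[win$padj < q_threshold, , drop = FALSE]
  ds_log("tested ", n_windows, " windows, ", nrow(sig), " significant")
  if (nrow(sig) == 0) {
    return(empty_peak_set(n_windows, 0L))
  }

  peaks <- list()
  for (nm in unique(sig$chrom)) {
    s <- sig[sig$chrom == nm, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    grp <- cumsum(c(1, s$start[-1] - cummax_end(s$end)[-nrow(s)] >
                      merge_gap))
    v <- track$top[[nm]] + track$bottom[[nm]]
    for (g in unique(grp)) {
      m <- s[grp == g, , drop = FALSE]
      start <- min(m$start); end <- max(m$end)
      b0 <- start %/% bs + 1L
      b1 <- end %/% bs
      summit_bin <- b0 + which.max(v[b0:b1]) - 1L
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = nm, start = start, end = end,
        summit = (summit_bin - 1L) * bs,
        score = -log10(max(min(m$padj), .Machine$double.xmin)),
        fold_enrichment = (max(m$count) / window) / rate,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, peaks)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  attr(out, "n_windows") <- n_windows
  attr(out, "n_sig_windows") <- nrow(sig)
  out
}

#' @noRd
cummax_end <- function(x) cummax(x)

#' @noRd
empty_peak_set <- function(n_windows, n_sig_windows = 0L) {
  out <- data.frame(chrom = character(), start = numeric(),
                    end = numeric(), summit = numeric(),
                    score = numeric(), fold_enrichment = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_set", "data.frame")
  attr(out, "n_windows") <- n_windows
  attr(out, "n_sig_windows") <- n_sig_windows
  out
}

#' Write or read peak calls as BED5 plus fold enrichment
#'
#' Columns: chrom, start, end, summit, score, fold_enrichment.
#'
#' @param peaks A `peak_set`.
#' @param path File path.
#' @return `read_peaks_bed()` returns a `peak_set`.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (nrow(peaks) == 0) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(chrom = peaks$chrom,
                   start = format(peaks$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(peaks$end, scientific = FALSE, trim = TRUE),
                   summit = format(peaks$summit, scientific = FALSE,
                                   trim = TRUE),
                   score = signif(peaks$score, 6),
                   fold = signif(peaks$fold_enrichment, 6))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) return(empty_peak_set(NA_integer_))
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("chrom", "start", "end", "summit",
                                 "score", "fold_enrichment"),
                   stringsAsFactors = FALSE)
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Count peak overlap with hotspot classes
#'
#' Hotspots become intervals `center +/- halfwidth`; a peak overlaps a
#' hotspot set if any base pair intersects. A peak may overlap both
#' classes, so the accounting identity
#' `n_overlap_prdm9 + n_overlap_default - n_overlap_both + n_neither =
#' n_peaks` holds exactly.
#'
#' @param peaks A `peak_set`.
#' @param prdm9 A `hotspot_set` of PRDM9-directed hotspots.
#' @param default_hs A `hotspot_set` of default hotspots.
#' @param halfwidth Hotspot interval halfwidth in bp.
#' @param genotype Optional label carried into the summary.
#' @return An object of class `overlap_summary` (one-row data frame) with
#'   counts and fractions per category.
#' @export
overlap_with_hotspots <- function(peaks, prdm9, default_hs,
                                  halfwidth = 1000, genotype = "") {
  np <- nrow(peaks)
  hit_p <- peak_hits(peaks, prdm9, halfwidth)
  hit_d <- peak_hits(peaks, default_hs, halfwidth)
  n_p <- sum(hit_p)
  n_d <- sum(hit_d)
  n_b <- sum(hit_p & hit_d)
  n_n <- sum(!hit_p & !hit_d)
  out <- data.frame(genotype = genotype, n_peaks = np,
                    n_overlap_prdm9 = n_p, n_overlap_default = n_d,
                    n_overlap_both = n_b, n_neither = n_n,
                    frac_prdm9 = if (np > 0) n_p / np else 0,
                    frac_default = if (np > 0) n_d / np else 0,
                    frac_both = if (np > 0) n_b / np else 0,
                    frac_neither = if (np > 0) n_n / np else 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("overlap_summary", "data.frame")
  out
}

#' @noRd
#' Logical vector: does each peak overlap any hotspot interval?
#' 0-based half-open coordinates are shifted to the 1-based closed system
#' of IRanges (start + 1, end).
peak_hits <- function(peaks, hotspots, halfwidth) {
  if (nrow(peaks) == 0) return(logical(0))
  if (nrow(hotspots) == 0) return(rep(FALSE, nrow(peaks)))
  gp <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
  gh <- GenomicRanges::GRanges(
    hotspots$chrom,
    IRanges::IRanges(start = pmax(hotspots$center - halfwidth, 0) + 1,
                     end = hotspots$center + halfwidth))
  GenomicRanges::countOverlaps(gp, gh) > 0
}
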
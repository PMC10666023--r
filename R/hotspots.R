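#' Construct a hotspot catalog
#'
#' DSB hotspots are point anchors with a relative "heat" (DSB propensity)
#' and a class: `prdm9` for PRDM9-directed hotspots or `default` for the
#' promoter/CpG-island sites used when PRDM9 targeting is absent.
#'
#' @param chrom Character vector of chromosome names.
#' @param center Numeric vector of 0-based center positions (bp).
#' @param heat Nonnegative numeric vector of relative DSB propensities.
#' @param hclass Character vector, each `"prdm9"` or `"default"`.
#' @param genome Optional [genome_spec()] used to validate positions.
#'
#' @return A data frame of class `hotspot_set` with columns `chrom`,
#'   `center`, `heat`, `hclass`.
#' @export
hotspot_set <- function(chrom = character(), center = numeric(),
                        heat = numeric(), hclass = character(),
                        genome = NULL) {
  hs <- data.frame(chrom = as.character(chrom),
                   center = as.numeric(center),
                   heat = as.numeric(heat),
                   hclass = as.character(hclass),
                   stringsAsFactors = FALSE)
  if (nrow(hs) > 0) {
    if (any(!hs$hclass %in% c("prdm9", "default"))) {
      stop("hotspot class must be 'prdm9' or 'default'")
    }
    if (any(hs$heat < 0) || any(!is.finite(hs$heat))) {
      stop("hotspot heat must be finite and >= 0")
    }
    if (!is.null(genome)) {
      check_chrom(genome, hs$chrom)
      lens <- genome$chroms[hs$chrom]
      if (any(hs$center < 0) || any(hs$center >= lens)) {
        bad <- which(hs$center < 0 | hs$center >= lens)[1]
        stop("hotspot center out of bounds: ", hs$chrom[bad], ":",
             hs$center[bad])
      }
    }
  }
  class(hs) <- c("hotspot_set", "data.frame")
  hs
}

#' Simulate a hotspot catalog
#'
#' Places `n` hotspots on the genome with a minimum same-chromosome spacing
#' and heats drawn from a gamma distribution (scale 1), mimicking the
#' heavy-tailed heat spectrum of SPO11-oligo hotspot maps. Hotspot counts
#' per chromosome are multinomial in chromosome length; within a chromosome,
#' positions are placed by the order-statistics construction that guarantees
#' the spacing exactly (sorted uniforms on the length remaining after
#' reserving `min_spacing` between consecutive hotspots).
#'
#' @param genome A [genome_spec()].
#' @param n Number of hotspots.
#' @param heat_shape Shape of the gamma heat distribution (scale fixed at 1).
#' @param hclass Class label for all hotspots: `"prdm9"` or `"default"`.
#' @param min_spacing Minimum distance (bp) between same-chromosome centers.
#' @param seed Integer seed; output is deterministic given the seed.
#'
#' @return A `hotspot_set` sorted by chromosome and center.
#' @examples
#' g <- genome_spec(c(chr1 = 1e7))
#' hs <- simulate_hotspots(g, n = 100, heat_shape = 2.5,
#'                         hclass = "prdm9", min_spacing = 1e4, seed = 1)
#' @export
simulate_hotspots <- function(genome, n, heat_shape = 2.5,
                              hclass = c("prdm9", "default"),
                              min_spacing = 1000, seed = 1) {
  hclass <- match.arg(hclass)
  stopifnot(is_count(n), is_positive_scalar(heat_shape), min_spacing >= 0)
  if (n == 0) return(hotspot_set())
  if (n * min_spacing >= genome_length(genome)) {
    stop("genome too small: n * min_spacing must be < total genome length")
  }
  with_seed(seed, {
    lens <- genome$chroms
    # bounded retries: a multinomial draw can overfill a short chromosome
    for (attempt in 1:100) {
      n_per <- as.vector(rmultinom(1, n, prob = lens / sum(lens)))
      names(n_per) <- names(lens)
      if (all(lens - (pmax(n_per - 1, 0)) * min_spacing > 0)) break
      if (attempt == 100) {
        stop("hotspot placement failed after bounded retries; ",
             "genome too small for n = ", n,
             " with min_spacing = ", min_spacing)
      }
    }
    chrom <- character(0); center <- numeric(0)
    for (nm in names(lens)) {
      k <- n_per[[nm]]
      if (k == 0) next
      slack <- lens[[nm]] - (k - 1) * min_spacing
      u <- sort(floor(runif(k, 0, slack)))
      pos <- u + (seq_len(k) - 1) * min_spacing
      chrom <- c(chrom, rep(nm, k))
      center <- c(center, pos)
    }
    heat <- rgamma(n, shape = heat_shape, scale = 1)
    hotspot_set(chrom, center, heat, rep(hclass, n), genome = genome)
  })
}

#' Read a hotspot catalog from TSV
#'
#' Expects four tab-separated columns: chrom, center, heat, class. Lines
#' are validated against the genome; a header line `chrom\tcenter...` is
#' permitted and skipped.
#'
#' @param path Path to the TSV file.
#' @param genome A [genome_spec()] for validation.
#' @return A `hotspot_set` in file order.
#' @export
read_hotspots <- function(path, genome) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) > 0 && grepl("^chrom\t", lines[1])) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(hotspot_set())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4)) {
    stop("malformed hotspot line ", which(nf != 4)[1],
         ": expected 4 tab-separated fields")
  }
  m <- do.call(rbind, fields)
  center <- suppressWarnings(as.numeric(m[, 2]))
  heat <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(center) || anyNA(heat)) {
    stop("malformed hotspot line ", which(is.na(center) | is.na(heat))[1],
         ": non-numeric center or heat")
  }
  hs <- hotspot_set(m[, 1], center, heat, m[, 4], genome = genome)
  ds_log("read ", nrow(hs), " hotspots from ", path)
  hs
}

#' Write a hotspot catalog
#'
#' `write_hotspots()` writes the TSV form (chrom, center, heat, class);
#' `write_hotspots_bed()` writes BED intervals `center +/- halfwidth`
#' (0-based half-open, clipped at 0).
#'
#' @param hotspots A `hotspot_set`.
#' @param path Output file path.
#' @param halfwidth Interval halfwidth in bp for the BED form.
#' @return The path, invisibly.
#' @export
write_hotspots <- function(hotspots, path) {
  df <- as.data.frame(hotspots)
  df$center <- format(df$center, scientific = FALSE, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = c("chrom", "center",
                                               "heat", "class"))
  invisible(path)
}

#' @rdname write_hotspots
#' @export
write_hotspots_bed <- function(hotspots, path, halfwidth = 1000) {
  start <- pmax(hotspots$center - halfwidth, 0)
  end <- hotspots$center + halfwidth
  df <- data.frame(chrom = hotspots$chrom,
                   start = format(start, scientific = FALSE, trim = TRUE),
                   end = format(end, scientific = FALSE, trim = TRUE),
                   name = hotspots$hclass,
                   score = hotspots$heat)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
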
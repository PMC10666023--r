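# Shared builders and independent oracles for the test suite.

tiny_genome <- function(len = 1e6, par = NULL) {
  genome_spec(c(chr1 = len), par = par)
}

two_chrom_genome <- function() {
  genome_spec(c(chr1 = 2e6, chr2 = 1e6))
}

# A combined co-oriented profile built directly from a distance -> value map
# (everything else zero). Used to probe the resection extraction in
# isolation from the averaging machinery.
toy_profile <- function(at = numeric(), value = numeric(),
                        flank = 5000, bin = 1) {
  d <- seq(-flank, flank, by = bin)
  v <- numeric(length(d))
  v[match(at, d)] <- value
  structure(list(distances = d, values = v, top = v / 2,
                 bottom_flipped = v / 2, n_hotspots = 1L, n_skipped = 0L,
                 combined = TRUE, normalized = FALSE, per_hotspot = NULL,
                 bin_size = bin),
            class = c("cooriented_profile"))
}

# Brute-force Hann smoothing: explicit weighted sum with reflected indices.
oracle_hann <- function(x, M) {
  if (M == 1) return(x)
  n <- length(x)
  k <- 0:(M - 1)
  w <- 0.5 * (1 - cos(2 * pi * k / (M - 1)))
  w <- w / sum(w)
  h <- (M - 1) / 2
  reflect <- function(i) {
    if (i < 1) 2 - i else if (i > n) 2 * n - i else i
  }
  vapply(seq_len(n), function(i) {
    sum(vapply(-h:h, function(j) w[j + h + 1] * x[reflect(i + j)],
               numeric(1)))
  }, numeric(1))
}

# Brute-force co-oriented average: plain double loop over hotspots and
# offsets, indexing the per-chromosome vectors one element at a time.
oracle_cooriented <- function(track, hotspots, flank) {
  bin <- track$bin_size
  fb <- flank %/% bin
  offs <- -fb:fb
  acc_top <- numeric(length(offs))
  acc_bot <- numeric(length(offs))
  used <- 0
  for (i in seq_len(nrow(hotspots))) {
    nm <- hotspots$chrom[i]
    cb <- floor(hotspots$center[i] / bin)
    nb <- length(track$top[[nm]])
    if (cb - fb < 0 || cb + fb >= nb) next
    used <- used + 1
    for (j in seq_along(offs)) {
      acc_top[j] <- acc_top[j] + track$top[[nm]][cb + offs[j] + 1]
      acc_bot[j] <- acc_bot[j] + track$bottom[[nm]][cb - offs[j] + 1]
    }
  }
  list(top = acc_top / used, bottom_flipped = acc_bot / used,
       n_hotspots = used)
}

# All-pairs interval overlap checker (0-based half-open).
oracle_peak_hits <- function(peaks, hotspots, halfwidth) {
  vapply(seq_len(nrow(peaks)), function(i) {
    hit <- FALSE
    for (j in seq_len(nrow(hotspots))) {
      if (peaks$chrom[i] != hotspots$chrom[j]) next
      hs <- max(hotspots$center[j] - halfwidth, 0)
      he <- hotspots$center[j] + halfwidth
      if (peaks$start[i] < he && hs < peaks$end[i]) hit <- TRUE
    }
    hit
  }, logical(1))
}

# Clopper-Pearson CI by direct inversion of the binomial tail functions.
oracle_cp_ci <- function(k, n, conf = 0.95) {
  alpha <- 1 - conf
  lower <- if (k == 0) 0 else {
    uniroot(function(p) pbinom(k - 1, n, p, lower.tail = FALSE) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  upper <- if (k == n) 1 else {
    uniroot(function(p) pbinom(k, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lower, upper)
}

# One simulated genotype pushed through track -> profile -> distribution.
run_resection_pipeline <- function(genome, hotspots, params,
                                   cfg = analysis_config(),
                                   keep_per_hotspot = FALSE) {
  em <- simulate_end_reads(genome, hotspots, params)
  tr <- rpm_normalize(bin_coverage(em, genome, cfg$profile_bin_bp))
  prof <- cooriented_average(tr, hotspots, cfg,
                             keep_per_hotspot = keep_per_hotspot)
  sm <- smooth_profile(prof, cfg$hann_window_bp)
  sm$per_hotspot <- prof$per_hotspot
  list(profile = sm,
       dist = resection_length_distribution(sm, cfg))
}
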
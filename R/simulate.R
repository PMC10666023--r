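#' Simulate strand-specific resected-DSB end reads
#'
#' Generates an [end_map()] with the statistical structure the downstream
#' analysis assumes. Each read is assigned to a category — PRDM9-directed
#' hotspot, default hotspot, or uniform background — by the fractions in
#' `params`. A hotspot-assigned read picks a hotspot with probability
#' proportional to heat (PAR hotspots boosted by `par_boost`), and a DSB
#' center is drawn as the hotspot center plus Gaussian jitter. With
#' probability `frac_central` the read reports a recombination intermediate
#' (strand fair-coin, uniform within `central_halfwidth` of the center);
#' otherwise it is a resection endpoint: strand fair-coin, length
#' `l ~ Gamma(resection_shape, scale = resection_scale)`, position
#' `center + l` on the top strand or `center - l` on the bottom strand.
#' Background reads are uniform over the genome. Positions are clipped to
#' chromosome bounds. The output is deterministic for a fixed seed.
#'
#' @param genome A [genome_spec()].
#' @param hotspots A `hotspot_set`; may be empty only when
#'   `frac_background = 1`.
#' @param params A [genotype_params()] bundle.
#' @param keep_truth If `TRUE`, attach the generative truth (category,
#'   assigned hotspot row, DSB center, signed end offset) as extra columns.
#'   These columns exist only in memory; BED output carries none of them.
#'
#' @return An `end_map` with `params$total_reads` records.
#' @examples
#' g <- genome_spec(c(chr1 = 1e6))
#' hs <- simulate_hotspots(g, 10, hclass = "prdm9", min_spacing = 5e4,
#'                         seed = 2)
#' pars <- genotype_preset("wildtype", total_reads = 1000,
#'                         frac_prdm9 = 0.8, frac_default = 0)
#' em <- simulate_end_reads(g, hs, pars)
#' @export
simulate_end_reads <- function(genome, hotspots, params,
                               keep_truth = FALSE) {
  validate_genotype_params(params)
  if (nrow(hotspots) == 0 && params$frac_background < 1) {
    stop("hotspot set may be empty only when frac_background = 1")
  }
  if (params$frac_prdm9 > 0 && !any(hotspots$hclass == "prdm9")) {
    stop("frac_prdm9 > 0 but no prdm9-class hotspots supplied")
  }
  if (params$frac_default > 0 && !any(hotspots$hclass == "default")) {
    stop("frac_default > 0 but no default-class hotspots supplied")
  }
  n <- params$total_reads
  if (n == 0) return(end_map())

  with_seed(params$seed, {
    counts <- as.vector(rmultinom(1, n, prob = c(params$frac_prdm9,
                                                 params$frac_default,
                                                 params$frac_background)))
    names(counts) <- c("prdm9", "default", "background")

    boost <- ifelse(in_par(genome, hotspots$chrom, hotspots$center),
                    params$par_boost, 1)
    parts <- list()
    for (cls in c("prdm9", "default")) {
      k <- counts[[cls]]
      if (k == 0) next
      rows <- which(hotspots$hclass == cls)
      w <- hotspots$heat[rows] * boost[rows]
      if (sum(w) <= 0) {
        stop("all ", cls, " hotspot weights are zero but frac_", cls,
             " > 0")
      }
      pick <- rows[sample.int(length(rows), k, replace = TRUE, prob = w)]
      center <- hotspots$center[pick] +
        round(rnorm(k, 0, params$dsb_jitter_sd))
      central <- runif(k) < params$frac_central
      strand <- sample(c("top", "bottom"), k, replace = TRUE)
      off <- numeric(k)
      nc <- sum(central)
      if (nc > 0) {
        off[central] <- round(runif(nc, -params$central_halfwidth,
                                    params$central_halfwidth))
      }
      nr <- k - nc
      if (nr > 0) {
        len <- rgamma(nr, shape = params$resection_shape,
                      scale = params$resection_scale)
        off[!central] <- ifelse(strand[!central] == "top", 1, -1) *
          round(len)
      }
      part <- data.frame(chrom = hotspots$chrom[pick], pos = center + off,
                         strand = strand, stringsAsFactors = FALSE)
      if (keep_truth) {
        part$category <- cls
        part$hotspot <- pick
        part$dsb_center <- center
        part$is_central <- central
      }
      parts[[cls]] <- part
    }
    kb <- counts[["background"]]
    if (kb > 0) {
      lens <- genome$chroms
      chrom <- names(lens)[sample.int(length(lens), kb, replace = TRUE,
                                      prob = lens / sum(lens))]
      pos <- floor(runif(kb, 0, lens[chrom]))
      part <- data.frame(chrom = chrom, pos = pos,
                         strand = sample(c("top", "bottom"), kb,
                                         replace = TRUE),
                         stringsAsFactors = FALSE)
      if (keep_truth) {
        part$category <- "background"
        part$hotspot <- NA_integer_
        part$dsb_center <- NA_real_
        part$is_central <- NA
      }
      parts[["background"]] <- part
    }
    rec <- do.call(rbind, parts)
    rownames(rec) <- NULL
    # clip hotspot-derived positions that jitter/resection pushed past the ends
    rec$pos <- pmin(pmax(rec$pos, 0), genome$chroms[rec$chrom] - 1)
    em <- end_map(rec$chrom, rec$pos, rec$strand, genome = genome)
    if (keep_truth) {
      em$category <- rec$category
      em$hotspot <- rec$hotspot
      em$dsb_center <- rec$dsb_center
      em$is_central <- rec$is_central
    }
    ds_log("simulated ", nrow(em), " end reads (",
           paste(names(counts), counts, sep = "=", collapse = ", "), ")")
    em
  })
}
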
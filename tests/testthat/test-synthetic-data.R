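test_that("simulate_hotspots honors count, spacing, and determinism", {
  g <- genome_spec(c(chr1 = 1e7))

  expect_equal(nrow(simulate_hotspots(g, 0, seed = 1)), 0)

  hs <- simulate_hotspots(g, 100, heat_shape = 2.5, hclass = "prdm9",
                          min_spacing = 1e4, seed = 3)
  expect_equal(nrow(hs), 100)
  # sort-and-scan spacing check per chromosome
  for (nm in unique(hs$chrom)) {
    ctr <- sort(hs$center[hs$chrom == nm])
    if (length(ctr) > 1) expect_true(min(diff(ctr)) >= 1e4)
  }
  expect_true(all(hs$center >= 0 & hs$center < 1e7))
  expect_true(all(hs$heat >= 0))

  expect_identical(hs, simulate_hotspots(g, 100, heat_shape = 2.5,
                                         hclass = "prdm9",
                                         min_spacing = 1e4, seed = 3))
  hs2 <- simulate_hotspots(g, 100, heat_shape = 2.5, hclass = "prdm9",
                           min_spacing = 1e4, seed = 4)
  expect_false(identical(hs$center, hs2$center))

  expect_error(simulate_hotspots(g, 2000, min_spacing = 1e4, seed = 1),
               "genome too small")
})

test_that("hotspot heats follow the gamma heat spectrum", {
  g <- genome_spec(c(chr1 = 5e7))
  hs <- simulate_hotspots(g, 10000, heat_shape = 2.5, hclass = "prdm9",
                          min_spacing = 100, seed = 5)
  # law of large numbers: gamma(shape 2.5, scale 1) has mean 2.5
  expect_lt(abs(mean(hs$heat) - 2.5) / 2.5, 0.05)
})

test_that("background-only reads are uniform with balanced strands", {
  g <- two_chrom_genome()
  params <- genotype_preset("spo11_null", total_reads = 10000, seed = 1)
  em <- simulate_end_reads(g, hotspot_set(), params)
  expect_equal(nrow(em), 10000)

  # chi-square GOF against the uniform across 30 equal-width genome bins
  gpos <- ifelse(em$chrom == "chr1", em$pos, 2e6 + em$pos)
  obs <- table(cut(gpos, breaks = seq(0, 3e6, length.out = 31)))
  gof <- suppressWarnings(chisq.test(as.vector(obs)))
  expect_gt(gof$p.value, 0.01)

  frac_top <- mean(em$strand == "top")
  expect_lt(abs(frac_top - 0.5), 0.02)
})

test_that("a near-deterministic resection length pins endpoints at center + 500", {
  g <- tiny_genome(1e6)
  hs <- hotspot_set(rep("chr1", 4), c(2e5, 4e5, 6e5, 8e5), rep(1, 4),
                    rep("prdm9", 4))
  # shape -> large with scale set so the mean stays 500 and variance -> 0
  params <- genotype_params(total_reads = 2000, frac_prdm9 = 1,
                            frac_default = 0, frac_background = 0,
                            frac_central = 0,
                            resection_shape = 1e8,
                            resection_scale = 500 / 1e8,
                            dsb_jitter_sd = 0, seed = 9)
  em <- simulate_end_reads(g, hs, params, keep_truth = TRUE)
  off <- em$pos - em$dsb_center
  expect_true(all(abs(off[em$strand == "top"] - 500) <= 1))
  expect_true(all(abs(off[em$strand == "bottom"] + 500) <= 1))
})

test_that("simulated resection lengths converge to shape * scale", {
  g <- tiny_genome(2e7)
  hs <- simulate_hotspots(g, 200, hclass = "prdm9", min_spacing = 5e4,
                          seed = 4)
  params <- genotype_params(total_reads = 1e5, frac_prdm9 = 1,
                            frac_default = 0, frac_background = 0,
                            frac_central = 0, resection_shape = 16,
                            resection_scale = 50, dsb_jitter_sd = 0,
                            seed = 13)
  em <- simulate_end_reads(g, hs, params, keep_truth = TRUE)
  top <- em$strand == "top" & !em$is_central
  mean_len <- mean(em$pos[top] - em$dsb_center[top])
  expect_lt(abs(mean_len - 800) / 800, 0.02)

  # strand balance among resection reads: |n_top - n_bottom| < 3*sqrt(n)/2
  n <- sum(!em$is_central)
  expect_lt(abs(sum(top) - sum(!top & !em$is_central)), 3 * sqrt(n) / 2)
})

test_that("read categories follow the multinomial fractions", {
  g <- tiny_genome(2e7)
  hs <- rbind(simulate_hotspots(g, 100, hclass = "prdm9",
                                min_spacing = 5e4, seed = 6),
              simulate_hotspots(g, 100, hclass = "default",
                                min_spacing = 5e4, seed = 7))
  class(hs) <- c("hotspot_set", "data.frame")
  params <- genotype_params(total_reads = 1e5, frac_prdm9 = 0.6,
                            frac_default = 0.25, frac_background = 0.15,
                            seed = 21)
  em <- simulate_end_reads(g, hs, params, keep_truth = TRUE)
  obs <- table(factor(em$category,
                      levels = c("prdm9", "default", "background")))
  gof <- chisq.test(as.vector(obs), p = c(0.6, 0.25, 0.15))
  expect_gt(gof$p.value, 0.001)
})

test_that("end-read simulation is seed-deterministic", {
  g <- tiny_genome(1e6)
  hs <- simulate_hotspots(g, 20, hclass = "prdm9", min_spacing = 2e4,
                          seed = 8)
  params <- genotype_preset("wildtype", total_reads = 5000,
                            frac_prdm9 = 0.8, frac_default = 0, seed = 33)
  em1 <- simulate_end_reads(g, hs, params)
  em2 <- simulate_end_reads(g, hs, params)
  expect_identical(em1, em2)

  params2 <- genotype_preset("wildtype", total_reads = 5000,
                             frac_prdm9 = 0.8, frac_default = 0, seed = 34)
  expect_false(identical(em1, simulate_end_reads(g, hs, params2)))
})

test_that("invalid generator inputs fail before sampling", {
  g <- tiny_genome(1e6)
  expect_error(genotype_params(frac_prdm9 = 0.5, frac_default = 0.5,
                               frac_background = 0.5),
               "must equal 1")
  expect_error(genotype_params(frac_prdm9 = -0.1, frac_default = 0.9,
                               frac_background = 0.2),
               "fractions")
  hs <- simulate_hotspots(g, 5, hclass = "prdm9", min_spacing = 1e5,
                          seed = 1)
  p <- genotype_preset("wildtype", total_reads = 100, frac_prdm9 = 0.8,
                       frac_default = 0)
  expect_error(simulate_end_reads(g, hotspot_set(), p),
               "empty only when frac_background")
})

test_that("genotype presets encode the genotype contrasts", {
  expect_equal(genotype_preset("spo11_null")$frac_background, 1)

  wt <- genotype_preset("wildtype")
  nul <- genotype_preset("ankrd31_null_like")
  expect_equal(wt$resection_shape * wt$resection_scale, 800)
  expect_equal(nul$resection_shape * nul$resection_scale, 700)
  expect_equal(wt$resection_shape * wt$resection_scale -
                 nul$resection_shape * nul$resection_scale, 100)

  expect_equal(nul$par_boost, 0)
  expect_gt(wt$par_boost, 1)
  expect_gt(nul$frac_default, wt$frac_default)

  expect_error(genotype_preset("nonsense"), "wildtype.*spo11_null")
})
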
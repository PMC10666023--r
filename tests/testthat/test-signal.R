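test_that("bin_coverage conserves read mass in the right bins", {
  g <- two_chrom_genome()

  tr0 <- bin_coverage(end_map(), g, 10)
  expect_equal(sum(unlist(tr0$top)) + sum(unlist(tr0$bottom)), 0)
  expect_equal(length(tr0$top$chr1), 2e5)

  tr <- bin_coverage(end_map("chr1", 1000, "top"), g, 40)
  expect_equal(tr$top$chr1[26], 1)  # floor(1000/40) = 25, 1-based bin 26
  expect_equal(sum(unlist(tr$top)), 1)

  hs <- simulate_hotspots(g, 20, hclass = "prdm9", min_spacing = 2e4,
                          seed = 3)
  em <- simulate_end_reads(g, hs,
                           genotype_preset("wildtype", total_reads = 5000,
                                           frac_prdm9 = 0.8,
                                           frac_default = 0, seed = 4))
  tr2 <- bin_coverage(em, g, 7)
  expect_equal(sum(unlist(tr2$top)) + sum(unlist(tr2$bottom)), nrow(em))
  expect_equal(tr2$n_mapped, nrow(em))
})

test_that("RPM normalization scales bins and refuses to run twice", {
  g <- tiny_genome(1000)
  em <- end_map(rep("chr1", 10), 0:9, rep(c("top", "bottom"), 5))
  tr <- rpm_normalize(bin_coverage(em, g, 1))
  expect_equal(sum(unlist(tr$top)) + sum(unlist(tr$bottom)), 1e6)
  expect_equal(tr$top$chr1[1], 1e5)  # one read among ten
  expect_error(rpm_normalize(tr), "already")
  expect_error(rpm_normalize(bin_coverage(end_map(), g, 1)), "0 reads")

  # scale invariance: doubling counts and depth leaves RPM unchanged
  em2 <- end_map(rep("chr1", 20), rep(0:9, 2),
                 rep(c("top", "bottom"), 10))
  tr2 <- rpm_normalize(bin_coverage(em2, g, 1))
  expect_equal(tr2$top, tr$top)
  expect_equal(tr2$bottom, tr$bottom)
})

test_that("hann_smooth matches its definition and the brute-force oracle", {
  x <- c(2, 5, 1, 7, 7, 3, 0, 4, 9, 2, 6)
  expect_identical(hann_smooth(x, 1), x)

  expect_equal(hann_smooth(rep(3.7, 50), 11), rep(3.7, 50))

  # unit impulse -> the unit-sum Hann-5 weights centered at the impulse
  imp <- c(0, 0, 0, 0, 1, 0, 0, 0, 0)
  w5 <- 0.5 * (1 - cos(2 * pi * (0:4) / 4))
  w5 <- w5 / sum(w5)
  expect_equal(hann_smooth(imp, 5)[3:7], w5, tolerance = 1e-12)

  set.seed(17)
  for (M in c(3, 5, 51)) {
    y <- rnorm(200)
    expect_equal(hann_smooth(y, M), oracle_hann(y, M), tolerance = 1e-9)
  }

  # interior mass is conserved to 0.1% when edges carry <1% of the mass
  z <- c(numeric(50), rexp(100), numeric(50))
  expect_equal(sum(hann_smooth(z, 21)), sum(z), tolerance = 1e-3)

  expect_error(hann_smooth(x, 4), "odd")
  expect_error(hann_smooth(x, 13), "exceeds")
})

test_that("cooriented_average places, flips, and averages correctly", {
  g <- tiny_genome(1e5)
  cfg <- analysis_config(profile_flank_bp = 2500,
                         background_offset_bp = 2500)
  hs <- hotspot_set("chr1", 50000, 1, "prdm9")

  # a single top read at center + 500 puts all profile mass at d = +500
  tr <- bin_coverage(end_map("chr1", 50500, "top"), g, 1)
  prof <- cooriented_average(tr, hs, cfg)
  expect_equal(sum(prof$values), 1)
  expect_equal(prof$values[match(500, prof$distances)], 1)

  # strand-mirrored reads: flipped bottom equals top exactly
  offs <- c(120, 340, 800, 1500)
  em <- end_map(rep("chr1", 8), c(50000 + offs, 50000 - offs),
                rep(c("top", "bottom"), each = 4))
  prof2 <- cooriented_average(bin_coverage(em, g, 1), hs, cfg)
  expect_identical(prof2$top, prof2$bottom_flipped)
  expect_equal(prof2$values, prof2$top * 2)
})

test_that("cooriented_average matches the brute-force loop oracle", {
  g <- two_chrom_genome()
  cfg <- analysis_config(profile_flank_bp = 3000,
                         background_offset_bp = 2500)
  hs <- rbind(simulate_hotspots(g, 30, hclass = "prdm9",
                                min_spacing = 2e4, seed = 5),
              simulate_hotspots(g, 15, hclass = "default",
                                min_spacing = 2e4, seed = 6))
  class(hs) <- c("hotspot_set", "data.frame")
  em <- simulate_end_reads(g, hs,
                           genotype_preset("wildtype", total_reads = 20000,
                                           frac_prdm9 = 0.6,
                                           frac_default = 0.2,
                                           frac_background = 0.2,
                                           seed = 7))
  tr <- rpm_normalize(bin_coverage(em, g, 1))
  prof <- cooriented_average(tr, hs, cfg)
  oracle <- oracle_cooriented(tr, hs, 3000)
  expect_equal(prof$n_hotspots, oracle$n_hotspots)
  expect_equal(prof$top, oracle$top, tolerance = 1e-9)
  expect_equal(prof$bottom_flipped, oracle$bottom_flipped,
               tolerance = 1e-9)
})

test_that("edge hotspots are skipped, not zero-padded", {
  g <- tiny_genome(1e4)
  cfg <- analysis_config(profile_flank_bp = 3000,
                         background_offset_bp = 2500)
  hs <- hotspot_set(c("chr1", "chr1"), c(1000, 5000), c(1, 1),
                    c("prdm9", "prdm9"))  # first window runs past the start
  tr <- bin_coverage(end_map("chr1", 5500, "top"), g, 1)
  prof <- cooriented_average(tr, hs, cfg)
  expect_equal(prof$n_hotspots, 1)
  expect_equal(prof$n_skipped, 1)
  expect_error(cooriented_average(tr, hotspot_set("chr1", 100, 1, "prdm9"),
                                  cfg),
               "no usable hotspots")
})

test_that("peak normalization rescales to the resection maximum", {
  cfg <- analysis_config()

  expect_error(normalize_to_resection_peak(toy_profile(), cfg),
               "no resection signal")

  # triangular profile peaking at +800, hitting zero at 2500
  d <- seq(-5000, 5000)
  v <- pmax(0, 1 - abs(d - 800) / 1700)
  prof <- toy_profile()
  prof$values <- v
  out <- normalize_to_resection_peak(prof, cfg)
  expect_equal(out$values[match(800, out$distances)], 1)
  expect_equal(out$values[match(2500, out$distances)], 0)
  expect_equal(max(out$values[out$distances > 100 &
                                out$distances <= 2500]), 1)
  expect_true(all(out$values >= 0))
  expect_true(out$normalized)
})
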
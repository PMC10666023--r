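---
title: "Mapping meiotic DSB ends and estimating resection lengths with dsbend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping meiotic DSB ends and estimating resection lengths with dsbend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbend)
```

## The assay and the analysis problem

Meiotic recombination starts with programmed DNA double-strand breaks
(DSBs) made by SPO11 at narrow genomic hotspots. Each break is then
resected 5'→3', producing 3' single-stranded tails whose endpoints lie
hundreds of nucleotides from the break. End-mapping assays blunt the
resected ends with single-strand exonucleases, ligate adapters, and
sequence: a read mapped to the top strand marks a rightward resection
endpoint, a bottom-strand read a leftward one. In addition to the two
resection flanks, reads accumulate directly at the hotspot center,
derived from recombination intermediates rather than resection endpoints.

dsbend turns a set of mapped end positions plus a hotspot catalog into:

1. strand-specific coverage tracks in reads per million mapped reads (RPM);
2. a hotspot-centered, *co-oriented* average profile — bottom-strand
   signal is flipped across the hotspot center so both resection
   directions superimpose on one positive-distance axis;
3. a resection-length distribution and its mean;
4. DSB peak calls and their overlap with PRDM9-directed versus "default"
   (promoter/CpG-island) hotspot classes;
5. interval summaries such as total signal in the X–Y pseudoautosomal
   region (PAR).

A seeded synthetic generator produces read ends with exactly this
structure, so the entire pipeline is exercised, end to end, with no
external data.

## The resection estimation procedure

Given an RPM track at 1-bp bins and a hotspot catalog, the estimator is:

1. **Co-oriented averaging.** For each hotspot, take top-strand values at
   offsets $d \in [-L, +L]$ from the center and bottom-strand values at
   $-d$; average across hotspots (unweighted by default) and sum the two
   components. Hotspot windows that would run past a chromosome end are
   skipped and counted, never zero-padded, because padding would dilute
   the average for edge hotspots.
2. **Smoothing.** The averaged profile is smoothed with a 151-bp Hann
   (raised-cosine) window. The window is rescaled to unit sum so that it
   preserves the local mean, and edges are handled by reflection padding
   so that a constant profile passes through unchanged. Display tracks in
   coarser bins (10 bp for hotspot close-ups, 40 bp for PAR-scale views)
   use a 51-bin Hann window instead.
3. **Background subtraction.** The profile value at +2,500 bp from the
   center — far outside the resection range — estimates the uniform
   sequencing background and is subtracted. Using the single smoothed
   value at exactly +2,500 bp (rather than averaging a flank window) is
   the default; the smoothing has already averaged ~150 bp of signal into
   that value.
4. **Core exclusion.** Offsets at or below 100 bp are zeroed: the central
   recombination-intermediate signal lives there and is not a resection
   endpoint. Offsets beyond 2,500 bp are likewise zeroed. Remaining
   negative values are clamped to 0.
5. **Fraction histogram.** Remaining signal is summed into 100-bp bins
   over (100, 2500] and divided by its total. The **mean resection
   length** is the bin-midpoint weighted mean of this histogram (the
   midpoint of $(a, a+100]$ is $a+50$). This midpoint convention is a
   choice: the mean could equally be taken on the unbinned profile; the
   histogram definition is used because the histogram is the object the
   analysis reports.

For cross-genotype display, `normalize_to_resection_peak()` applies the
same background subtraction and rescales so the maximum over
(100, 2500] is 1 — absolute signal levels vary with library composition
for reasons unrelated to genotype, so only the spatial pattern is
comparable.

```{r worked-example}
genome <- genome_spec(c(chr1 = 10e6))
hotspots <- simulate_hotspots(genome, n = 500, heat_shape = 2.5,
                              hclass = "prdm9", min_spacing = 1.5e4,
                              seed = 11)
cfg <- analysis_config()
params <- genotype_preset("wildtype", total_reads = 1e5,
                          frac_prdm9 = 0.8, frac_default = 0, seed = 7)
ends <- simulate_end_reads(genome, hotspots, params)
track <- rpm_normalize(bin_coverage(ends, genome, 1))
prof <- smooth_profile(cooriented_average(track, hotspots, cfg), 151)
dist <- resection_length_distribution(prof, cfg)
mean_resection_length(dist)  # generative mean is 800 nt
```

## The synthetic generator

`simulate_end_reads()` emulates the generative structure the estimator
assumes:

* **Read categories.** Each read is multinomially assigned to a
  PRDM9-directed hotspot, a default hotspot, or uniform genome-wide
  background, by the `frac_*` probabilities.
* **Hotspot choice.** Hotspot-assigned reads pick a hotspot with
  probability proportional to its heat; hotspots inside the PAR have
  their heat multiplied by `par_boost`. Heats are gamma(shape 2.5,
  scale 1): hotspot heat spectra are heavy-tailed, and any positive
  distribution satisfies the downstream contracts.
* **DSB placement.** The break center is the hotspot center plus Gaussian
  jitter (sd 50 bp by default), reflecting within-hotspot dispersion of
  cleavage positions.
* **Resection endpoints.** With probability `1 - frac_central` the read
  is an endpoint: strand by fair coin, length drawn from a gamma
  distribution (lengths in nt), position `center + length` (top) or
  `center - length` (bottom). The gamma family is a modeling choice —
  endpoint distributions are unimodal and right-skewed, and gamma with
  mean 800 nt (shape 16, scale 50) matches published mammalian resection
  scales; no particular family is implied by the data the package
  emulates.
* **Central signal.** With probability `frac_central` (default 0.15) the
  read instead reports a recombination intermediate: uniform within
  ±100 bp of the DSB center, strand by fair coin.

The four presets of `genotype_preset()` encode the contrasts the
pipeline is designed to resolve: `wildtype` (low default-hotspot usage,
`par_boost = 8`, resection mean 800 nt), `ankrd31_null_like` (elevated
default usage, `par_boost = 0`, mean 700 nt — a 100-nt shortening),
`ea_like` (wild-type-like with an intermediate PAR boost, modelling a
partial-loss-of-interaction allele), and `spo11_null` (pure background —
the no-DSB control). The 100-nt shift between the first two presets is
the package's calibration target: only the mean shift is calibrated, not
the full endpoint shape.

What the generator does **not** model: sequence-level reads (no FASTQ or
alignment), PCR duplicates, mappability, chromatin accessibility,
replicate correlation beyond independent seeds, or per-hotspot resection
heterogeneity. Passing tests therefore demonstrate that the estimator
recovers the generative truth under these idealized conditions, not that
it is robust to every artifact of real libraries.

## Peak calling and overlap accounting

No specific peak caller is canonical for this assay, so dsbend ships a
minimal, fully specified one: combined-strand counts in sliding windows
(1,000 bp, stepped by half a window) are tested against a Poisson null
with rate equal to the genome-wide mean density times the window size;
p-values are Benjamini–Hochberg adjusted across all windows; windows with
adjusted p < 0.01 within 500 bp of each other are merged. The caller is
deliberately simple — a global (not local) background, no duplicate
modeling — and is replaceable behind the `call_peaks()` contract. Its FDR
behaviour is property-tested on background-only simulations.

`overlap_with_hotspots()` counts peaks touching PRDM9-directed and
default hotspot intervals (`center ± 1,000 bp`; SPO11-oligo hotspots are
typically 1–2 kb wide). A peak may overlap both classes, so both counts
are reported together with the intersection, and
`n_prdm9 + n_default - n_both + n_neither = n_peaks` holds exactly.

## Numerical and degenerate-input choices

* **Hann window.** Unit-sum normalization and reflection padding are
  chosen so smoothing preserves constants and local means; `window = 1`
  is the identity; even windows are an error, not silently adjusted.
* **RPM idempotence.** Re-normalizing an RPM track is an error, never a
  silent rescale.
* **Degenerate resection distributions.** A profile with no resection
  signal yields an all-zero distribution flagged `degenerate`, not an
  error, so pipelines over genotype panels that include a DSB-null
  control run to completion. Because sampling noise always leaves a small
  positive residue after clamping, strict zero-total is not a usable
  criterion; instead the distribution is flagged degenerate when the
  resection-window maximum is below 3× the background estimate. The
  margin on both sides is wide: background-only profiles sit near 1.2–1.8×,
  DSB-proficient profiles above 10×.
* **Ties and bounds.** Percentages round half away from zero (8/9 → 89%,
  27/59 → 46%); confidence intervals are exact Clopper–Pearson from beta
  quantiles.
* **Determinism.** Every sampling function takes an explicit seed and
  restores the caller's RNG state; identical seeds give byte-identical
  outputs. The run manifest records seeds and an MD5 hash of the
  configuration.

## Known limitations

* The central-signal exclusion is geometric (≤100 bp), and with 50-bp DSB
  jitter roughly a third of central mass lands just beyond the cutoff.
  At the default `frac_central = 0.15` this biases the estimated mean by
  roughly 10–15 nt (about 30 nt at `frac_central = 0.3`) — small relative
  to the 100-nt genotype contrast the pipeline is built to resolve, but
  not zero. A deconvolution of the central signal is out of scope.
* Smoothing before distribution extraction leaks a little mass across
  100-bp bin edges; an unsmoothed path is available by simply not calling
  `smooth_profile()` before `resection_length_distribution()`.
* The bootstrap CI in `compare_resection()` resamples hotspots, the
  natural unit of replication; it does not capture between-animal or
  between-library variance components.
* Estimated means carry a small negative bias (~10 nt at the defaults)
  from the interplay of core exclusion, background subtraction, and
  binning; comparisons between genotypes, which share the bias, are
  unaffected (the 100-nt generative shift is recovered to within a few
  nt).

## Problem sizes used by the test suite

The packaged tests and the reproduction script run on toy genomes of
10–30 Mb with 300–2,000 hotspots and 20k–500k reads per sample. These
sizes were chosen because the estimator's sampling error at 2,000
hotspots × 200k reads is already far below the effects being measured
(the mean-shift recovery is reproducible to ±3 nt across seeds);
real-genome scale adds nothing but runtime to the properties under test.
```
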
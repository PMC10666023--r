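#' Analysis configuration
#'
#' Holds the constants of the end-signal analysis. Defaults follow the
#' standard conventions for resected-DSB end mapping: 1-bp profile bins
#' smoothed with a 151-bp Hann window (151 bins at 1 bp), background
#' estimated 2,500 bp from the hotspot center, the central
#' recombination-intermediate signal excluded within 100 bp of the center,
#' resection fractions tallied every 100 bp, and profiles extending 5,000 bp
#' to either side of the center.
#'
#' @param hann_window_bp Odd smoothing window (bp) for 1-bp profiles.
#' @param hann_window_bins Odd smoothing window (bins) for display tracks
#'   binned at `display_bin_bp`.
#' @param profile_bin_bp Bin size (bp) of the profile track; must match the
#'   track handed to [cooriented_average()].
#' @param display_bin_bp Bin size (bp) for display tracks (10 bp for
#'   default-hotspot close-ups, 40 bp for PAR-scale views).
#' @param background_offset_bp Distance (bp) from the hotspot center at
#'   which background is estimated and subtracted.
#' @param core_exclusion_bp Distance (bp) below which signal is excluded as
#'   central/recombination-intermediate.
#' @param resection_bin_bp Width (bp) of resection-fraction bins; must
#'   divide `background_offset_bp - core_exclusion_bp`.
#' @param profile_flank_bp Profile half-width (bp).
#' @param hotspot_halfwidth_bp Hotspot interval halfwidth (bp) used for
#'   peak-overlap counting.
#'
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(hann_window_bp = 151,
                            hann_window_bins = 51,
                            profile_bin_bp = 1,
                            display_bin_bp = 10,
                            background_offset_bp = 2500,
                            core_exclusion_bp = 100,
                            resection_bin_bp = 100,
                            profile_flank_bp = 5000,
                            hotspot_halfwidth_bp = 1000) {
  cfg <- list(hann_window_bp = hann_window_bp,
              hann_window_bins = hann_window_bins,
              profile_bin_bp = profile_bin_bp,
              display_bin_bp = display_bin_bp,
              background_offset_bp = background_offset_bp,
              core_exclusion_bp = core_exclusion_bp,
              resection_bin_bp = resection_bin_bp,
              profile_flank_bp = profile_flank_bp,
              hotspot_halfwidth_bp = hotspot_halfwidth_bp)
  if (cfg$hann_window_bp %% 2 == 0 || cfg$hann_window_bp < 3 ||
      cfg$hann_window_bins %% 2 == 0 || cfg$hann_window_bins < 3) {
    stop("Hann window lengths must be odd and >= 3")
  }
  if (!(cfg$core_exclusion_bp > 0 &&
        cfg$core_exclusion_bp < cfg$background_offset_bp &&
        cfg$background_offset_bp <= cfg$profile_flank_bp)) {
    stop("require 0 < core_exclusion_bp < background_offset_bp <= ",
         "profile_flank_bp")
  }
  if ((cfg$background_offset_bp - cfg$core_exclusion_bp) %%
      cfg$resection_bin_bp != 0) {
    stop("resection_bin_bp must divide ",
         "background_offset_bp - core_exclusion_bp")
  }
  structure(cfg, class = "analysis_config")
}

#' Read or write an analysis configuration
#'
#' The on-disk form is a flat `key: value` file. Unknown keys are an error,
#' guarding against silent typos; omitted keys take their defaults.
#'
#' @param cfg An `analysis_config`.
#' @param path File path.
#' @return `read_analysis_config()` returns an `analysis_config`.
#' @export
write_analysis_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(analysis_config, vals)
}
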
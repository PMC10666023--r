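#' Run the full end-mapping analysis pipeline
#'
#' Executes simulate (optional) -> coverage -> profile -> resection ->
#' peaks -> overlap for every declared sample and writes all outputs plus
#' a machine-readable run manifest into `run_dir`. Replicate libraries are
#' RPM-normalized individually and then averaged; peak calling pools the
#' raw replicate reads. A sample whose profile carries no resection signal
#' (for example a DSB-null background control) gets an all-zero resection
#' distribution flagged degenerate and no peak-normalized profile.
#'
#' The configuration is a YAML file (or an equivalent list) with keys:
#' \describe{
#'   \item{genome}{`chroms` (name: length map) and optional `par`
#'     (`chrom`, `start`, `end`).}
#'   \item{config}{Optional [analysis_config()] overrides.}
#'   \item{hotspots}{`prdm9` and/or `default`, each either simulation
#'     parameters (`n`, `heat_shape`, `min_spacing`, `seed`) or a `path`
#'     to a hotspot TSV.}
#'   \item{samples}{List of samples: `name`, `preset` (see
#'     [genotype_preset()]), optional `overrides` of genotype parameters,
#'     and `replicate_seeds` (one simulated library per seed) or
#'     `ends_paths` (pre-mapped BED6 files).}
#'   \item{peaks}{Optional `window`, `q_threshold`, `merge_gap`.}
#' }
#'
#' @param config Path to a YAML config file, or a list with the same
#'   structure.
#' @param run_dir Output directory (created if needed).
#' @return The manifest (a list), invisibly; also written as
#'   `manifest.json` in `run_dir`.
#' @export
run_pipeline <- function(config, run_dir) {
  if (is.character(config)) {
    config_text <- readLines(config)
    config <- yaml::read_yaml(config)
  } else {
    config_text <- strsplit(yaml::as.yaml(config), "\n")[[1]]
  }
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  tf <- tempfile(); writeLines(config_text, tf)
  config_hash <- unname(tools::md5sum(tf)); unlink(tf)

  cfg <- do.call(analysis_config, as.list(config$config))
  genome <- genome_spec(unlist(config$genome$chroms),
                        par = config$genome$par)

  hs <- list(prdm9 = hotspot_set(), default = hotspot_set())
  for (cls in c("prdm9", "default")) {
    hc <- config$hotspots[[cls]]
    if (is.null(hc)) next
    hs[[cls]] <- if (!is.null(hc$path)) {
      read_hotspots(hc$path, genome)
    } else {
      simulate_hotspots(genome, n = hc$n,
                        heat_shape = hc$heat_shape %||% 2.5,
                        hclass = cls,
                        min_spacing = hc$min_spacing %||% 1000,
                        seed = hc$seed %||% 1)
    }
  }
  all_hs <- hotspot_set(c(hs$prdm9$chrom, hs$default$chrom),
                        c(hs$prdm9$center, hs$default$center),
                        c(hs$prdm9$heat, hs$default$heat),
                        c(hs$prdm9$hclass, hs$default$hclass))
  pk <- config$peaks
  samples <- config$samples
  manifest <- list(config_hash = config_hash,
                   genome = list(chroms = as.list(genome$chroms),
                                 par = genome$par),
                   n_hotspots = list(prdm9 = nrow(hs$prdm9),
                                     default = nrow(hs$default)),
                   analysis_config = unclass(cfg),
                   samples = list())
  if (length(samples) == 0) {
    write_manifest(manifest, run_dir)
    return(invisible(manifest))
  }

  for (sm in samples) {
    name <- sm$name
    sdir <- file.path(run_dir, name)
    dir.create(sdir, showWarnings = FALSE)
    entry <- list(name = name, preset = sm$preset %||% NA)

    ends_list <- pipeline_stage("input", name, {
      if (!is.null(sm$ends_paths)) {
        entry$inputs <- sm$ends_paths
        lapply(sm$ends_paths, read_endmap_bed, genome = genome)
      } else {
        seeds <- sm$replicate_seeds %||% 1
        entry$seeds <- seeds
        lapply(seeds, function(s) {
          params <- do.call(genotype_preset,
                            c(list(name = sm$preset),
                              as.list(sm$overrides), list(seed = s)))
          simulate_end_reads(genome, all_hs, params)
        })
      }
    })
    entry$n_reads_per_replicate <- vapply(ends_list, nrow, integer(1))

    tracks <- pipeline_stage("coverage", name, {
      lapply(ends_list, function(e) {
        rpm_normalize(bin_coverage(e, genome, cfg$profile_bin_bp))
      })
    })
    avg <- average_tracks(tracks)
    write_bedgraph(avg, "top", file.path(sdir, "top.bedgraph"))
    write_bedgraph(avg, "bottom", file.path(sdir, "bottom.bedgraph"))

    prof <- pipeline_stage("profile", name, {
      p <- cooriented_average(avg, all_hs, cfg, combine = TRUE)
      smooth_profile(p, cfg$hann_window_bp)
    })
    entry$n_hotspots_used <- prof$n_hotspots
    entry$n_hotspots_skipped <- prof$n_skipped
    write_profile_tsv(prof, file.path(sdir, "profile.tsv"))
    norm <- tryCatch(normalize_to_resection_peak(prof, cfg),
                     error = function(e) NULL)
    if (!is.null(norm)) {
      write_profile_tsv(norm, file.path(sdir, "profile_normalized.tsv"))
    }

    dist <- pipeline_stage("resection", name, {
      resection_length_distribution(prof, cfg)
    })
    entry$resection_degenerate <- dist$degenerate
    entry$mean_resection_nt <- if (dist$degenerate) NA else
      mean_resection_length(dist)
    write_resection_tsv(dist, file.path(sdir, "resection.tsv"))

    peaks <- pipeline_stage("peaks", name, {
      pooled <- do.call(rbind, ends_list)
      call_peaks(bin_coverage(end_map(pooled$chrom, pooled$pos,
                                      pooled$strand),
                              genome, cfg$display_bin_bp),
                 window = pk$window %||% 1000,
                 q_threshold = pk$q_threshold %||% 0.01,
                 merge_gap = pk$merge_gap %||% 500)
    })
    entry$n_peaks <- nrow(peaks)
    write_peaks_bed(peaks, file.path(sdir, "peaks.bed"))

    ov <- pipeline_stage("overlap", name, {
      overlap_with_hotspots(peaks, hs$prdm9, hs$default,
                            halfwidth = cfg$hotspot_halfwidth_bp,
                            genotype = name)
    })
    write.table(ov, file.path(sdir, "overlap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    entry$overlap <- as.list(ov[1, ])

    manifest$samples[[name]] <- entry
  }
  write_manifest(manifest, run_dir)
  invisible(manifest)
}

#' @noRd
pipeline_stage <- function(stage, sample, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed for sample '", sample, "': ",
         conditionMessage(e), call. = FALSE)
  })
}

#' @noRd
write_manifest <- function(manifest, run_dir) {
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
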
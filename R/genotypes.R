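#' Construct generator parameters for one genotype
#'
#' Bundles everything the read-end generator needs: how reads split between
#' PRDM9-directed hotspots, default hotspots and uniform background; how
#' much hotspot signal is central (recombination-intermediate) rather than
#' resection-endpoint; the gamma resection-length distribution; DSB-center
#' jitter; and the PAR heat boost.
#'
#' @param total_reads Total number of read ends to generate.
#' @param frac_prdm9,frac_default,frac_background Read-category
#'   probabilities; must sum to 1.
#' @param frac_central Probability that a hotspot-assigned read reports a
#'   recombination intermediate near the DSB center instead of a resection
#'   endpoint.
#' @param resection_shape,resection_scale Gamma parameters for resection
#'   lengths in nt (mean = shape * scale).
#' @param dsb_jitter_sd Gaussian sd (bp) of DSB-center placement around the
#'   hotspot center.
#' @param central_halfwidth Halfwidth (bp) of the uniform central signal.
#' @param par_boost Multiplicative heat factor applied to hotspots inside
#'   the PAR (0 silences the PAR entirely).
#' @param seed Integer seed for the generator.
#'
#' @return An object of class `genotype_params`.
#' @seealso [genotype_preset()] for ready-made parameter bundles.
#' @export
genotype_params <- function(total_reads = 500000,
                            frac_prdm9 = 0.75,
                            frac_default = 0.05,
                            frac_background = 0.2,
                            frac_central = 0.15,
                            resection_shape = 16,
                            resection_scale = 50,
                            dsb_jitter_sd = 50,
                            central_halfwidth = 100,
                            par_boost = 1,
                            seed = 1) {
  p <- list(total_reads = total_reads,
            frac_prdm9 = frac_prdm9, frac_default = frac_default,
            frac_background = frac_background, frac_central = frac_central,
            resection_shape = resection_shape,
            resection_scale = resection_scale,
            dsb_jitter_sd = dsb_jitter_sd,
            central_halfwidth = central_halfwidth,
            par_boost = par_boost, seed = seed)
  validate_genotype_params(p)
  structure(p, class = "genotype_params")
}

#' @noRd
validate_genotype_params <- function(p) {
  fr <- c(p$frac_prdm9, p$frac_default, p$frac_background)
  if (any(fr < 0) || any(fr > 1) || p$frac_central < 0 || p$frac_central > 1) {
    stop("all fractions must lie in [0, 1]")
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("frac_prdm9 + frac_default + frac_background must equal 1 ",
         "(got ", format(sum(fr), digits = 12), ")")
  }
  if (!is_positive_scalar(p$resection_shape) ||
      !is_positive_scalar(p$resection_scale)) {
    stop("resection_shape and resection_scale must be > 0")
  }
  if (!is_count(p$total_reads)) stop("total_reads must be a count >= 0")
  if (p$dsb_jitter_sd < 0 || p$central_halfwidth < 0 || p$par_boost < 0) {
    stop("dsb_jitter_sd, central_halfwidth and par_boost must be >= 0")
  }
  invisible(TRUE)
}

#' Ready-made genotype parameter bundles
#'
#' Four presets span the genotype contrasts the pipeline is designed to
#' resolve:
#' \describe{
#'   \item{wildtype}{PRDM9-directed landscape, low default-hotspot usage,
#'     strong PAR signal (`par_boost = 8`), mean resection 800 nt
#'     (gamma shape 16, scale 50).}
#'   \item{ankrd31_null_like}{Elevated default-hotspot usage, no PAR signal
#'     (`par_boost = 0`), mean resection shortened by 100 nt to 700 nt
#'     (shape 14, scale 50).}
#'   \item{ea_like}{Wild-type-like landscape with an intermediate PAR
#'     boost, modelling a partial-loss-of-interaction allele.}
#'   \item{spo11_null}{No programmed DSBs: pure uniform background.}
#' }
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [genotype_params()] fields.
#' @return A `genotype_params` object.
#' @examples
#' genotype_preset("spo11_null")$frac_background  # 1
#' @export
genotype_preset <- function(name, ...) {
  presets <- list(
    wildtype = list(frac_prdm9 = 0.75, frac_default = 0.05,
                    frac_background = 0.2, frac_central = 0.15,
                    resection_shape = 16, resection_scale = 50,
                    par_boost = 8),
    ankrd31_null_like = list(frac_prdm9 = 0.45, frac_default = 0.35,
                             frac_background = 0.2, frac_central = 0.15,
                             resection_shape = 14, resection_scale = 50,
                             par_boost = 0),
    ea_like = list(frac_prdm9 = 0.72, frac_default = 0.08,
                   frac_background = 0.2, frac_central = 0.15,
                   resection_shape = 16, resection_scale = 50,
                   par_boost = 5),
    spo11_null = list(frac_prdm9 = 0, frac_default = 0,
                      frac_background = 1, frac_central = 0,
                      par_boost = 0)
  )
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(presets)) {
    stop("unknown genotype preset '", paste(name, collapse = ","),
         "'; valid names: ", paste(names(presets), collapse = ", "))
  }
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(genotype_params, args)
}

#' Read or write genotype parameters as a flat key: value file
#'
#' @param params A `genotype_params` object.
#' @param path File path.
#' @return `write_genotype_params()` returns the path invisibly;
#'   `read_genotype_params()` returns a `genotype_params`.
#' @export
write_genotype_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_genotype_params
#' @export
read_genotype_params <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(genotype_params))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown genotype parameter key(s): ", paste(bad, collapse = ", "))
  }
  do.call(genotype_params, vals)
}
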
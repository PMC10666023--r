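#' Define a genome for the analysis
#'
#' A genome specification holds named chromosome lengths and, optionally, a
#' pseudoautosomal region (PAR) interval. All coordinates downstream are
#' 0-based; intervals are half-open `[start, end)`.
#'
#' @param chroms Named numeric vector of chromosome lengths in bp. All
#'   lengths must be positive.
#' @param par Optional PAR interval as a list with elements `chrom`,
#'   `start`, `end` (0-based half-open). Must lie within its chromosome.
#'
#' @return An object of class `genome_spec`.
#' @examples
#' genome_spec(c(chr1 = 2e7, chrX = 1e7),
#'             par = list(chrom = "chrX", start = 9.3e6, end = 1e7))
#' @export
genome_spec <- function(chroms, par = NULL) {
  if (is.null(names(chroms)) || any(!nzchar(names(chroms)))) {
    stop("`chroms` must be a named vector of chromosome lengths")
  }
  if (anyDuplicated(names(chroms))) {
    stop("duplicate chromosome names in `chroms`")
  }
  chroms <- vapply(chroms, as.numeric, numeric(1))
  if (any(!is.finite(chroms)) || any(chroms <= 0)) {
    stop("all chromosome lengths must be positive and finite")
  }
  if (!is.null(par)) {
    if (!all(c("chrom", "start", "end") %in% names(par))) {
      stop("`par` must have elements chrom, start, end")
    }
    if (!par$chrom %in% names(chroms)) {
      stop("PAR chromosome '", par$chrom, "' not in genome")
    }
    if (par$start < 0 || par$end > chroms[[par$chrom]] ||
        par$start >= par$end) {
      stop("PAR interval must lie within chromosome '", par$chrom, "'")
    }
    par <- list(chrom = par$chrom,
                start = as.numeric(par$start), end = as.numeric(par$end))
  }
  structure(list(chroms = chroms, par = par), class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("genome_spec:", length(x$chroms), "chromosome(s),",
      format(sum(x$chroms), big.mark = ","), "bp total\n")
  for (nm in names(x$chroms)) {
    cat(" ", nm, format(x$chroms[[nm]], big.mark = ","), "bp\n")
  }
  if (!is.null(x$par)) {
    cat("  PAR:", x$par$chrom,
        format(x$par$start, big.mark = ","), "-",
        format(x$par$end, big.mark = ","), "\n")
  }
  invisible(x)
}

#' @noRd
genome_length <- function(genome) sum(genome$chroms)

#' @noRd
check_chrom <- function(genome, chrom) {
  bad <- setdiff(unique(chrom), names(genome$chroms))
  if (length(bad) > 0) {
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' @noRd
#' TRUE for hotspots whose center lies inside the genome's PAR.
in_par <- function(genome, chrom, pos) {
  if (is.null(genome$par)) return(rep(FALSE, length(chrom)))
  chrom == genome$par$chrom & pos >= genome$par$start & pos < genome$par$end
}
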
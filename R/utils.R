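#' @noRd
#' Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

#' @noRd
#' Lightweight stage logging, gated by options(dsbend.log_level = ...).
ds_log <- function(..., level = "info") {
  threshold <- getOption("dsbend.log_level", "warn")
  if (log_levels[[level]] >= log_levels[[threshold]]) {
    message("[dsbend] ", ...)
  }
  invisible(NULL)
}

#' @noRd
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

#' @noRd
is_positive_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
}

#' @noRd
#' Round half away from zero to the nearest integer.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
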
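#' Construct an end map
#'
#' The raw input of the pipeline: mapped, blunted DNA-end records. Each
#' record is a chromosome, a 0-based position, and a strand (`top` reads
#' mark rightward resection endpoints, `bottom` leftward).
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Numeric vector of 0-based positions.
#' @param strand Character vector, each `"top"` or `"bottom"`.
#' @param genome Optional [genome_spec()] to validate positions against.
#' @return A data frame of class `end_map` with columns `chrom`, `pos`,
#'   `strand`; `nrow()` is the mapped-read count.
#' @export
end_map <- function(chrom = character(), pos = numeric(),
                    strand = character(), genome = NULL) {
  em <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (nrow(em) > 0) {
    if (any(!em$strand %in% c("top", "bottom"))) {
      stop("strand must be 'top' or 'bottom'")
    }
    if (!is.null(genome)) {
      check_chrom(genome, em$chrom)
      lens <- genome$chroms[em$chrom]
      bad <- which(em$pos < 0 | em$pos >= lens)
      if (length(bad) > 0) {
        stop("end position out of bounds: ", em$chrom[bad[1]], ":",
             em$pos[bad[1]])
      }
    }
  }
  class(em) <- c("end_map", "data.frame")
  em
}

#' Read an end map from BED6
#'
#' BED6 columns: chrom, start, end, name, score, strand. Each record is a
#' single blunted end at `start` (0-based); strand `+` is the top strand,
#' `-` the bottom strand.
#'
#' @param path Path to the BED6 file.
#' @param genome A [genome_spec()]; positions are validated against it.
#' @return An `end_map`.
#' @export
read_endmap_bed <- function(path, genome) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines_keep <- nzchar(lines)
  if (!any(lines_keep)) return(end_map())
  idx <- which(lines_keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    bad <- idx[which(nf < 6)[1]]
    stop("malformed BED6 line ", bad, ": expected >= 6 tab-separated fields")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  pos <- suppressWarnings(as.numeric(m[, 2]))
  if (anyNA(pos)) {
    stop("malformed BED6 line ", idx[which(is.na(pos))[1]],
         ": non-numeric start")
  }
  sbed <- m[, 6]
  if (any(!sbed %in% c("+", "-"))) {
    stop("malformed BED6 line ", idx[which(!sbed %in% c("+", "-"))[1]],
         ": strand must be '+' or '-'")
  }
  em <- end_map(m[, 1], pos, ifelse(sbed == "+", "top", "bottom"),
                genome = genome)
  ds_log("read ", nrow(em), " end records from ", path)
  em
}

#' Write an end map as BED6
#'
#' Each end becomes a width-1 interval `[pos, pos + 1)` with name `.`,
#' score 0, and strand `+` (top) or `-` (bottom).
#'
#' @param ends An `end_map`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_endmap_bed <- function(ends, path) {
  if (nrow(ends) == 0) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(
    chrom = ends$chrom,
    start = format(ends$pos, scientific = FALSE, trim = TRUE),
    end = format(ends$pos + 1, scientific = FALSE, trim = TRUE),
    name = ".", score = 0L,
    strand = ifelse(ends$strand == "top", "+", "-")
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
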
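#' Construct and validate a peak table
#'
#' Peaks are BED-like records with an absolute summit coordinate and a
#' significance score (a -log10 FDR-like quantity from the peak caller).
#' All coordinates are 0-based half-open: `start <= summit < end`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open interval bounds.
#' @param name Peak identifiers; defaults to `peak_1..n`.
#' @param score Non-negative numeric significance scores.
#' @param strand One of `"+"`, `"-"`, `"*"` per peak.
#' @param summit Absolute 0-based summit coordinate; defaults to the
#'   interval midpoint.
#' @return A `data.frame` with columns `chrom, start, end, name, score,
#'   strand, summit`.
#' @export
#' @examples
#' peak_table("chr1", 100, 300, score = 10, summit = 180)
peak_table <- function(chrom, start, end, name = NULL, score = 0,
                       strand = "*", summit = NULL) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name %||% paste0("peak_", seq_len(max(n, length(start))))),
    score = as.numeric(score),
    strand = as.character(strand),
    summit = as.integer(summit %||% ((as.integer(start) + as.integer(end)) %/% 2L)),
    stringsAsFactors = FALSE
  )
  validate_peaks(df)
}

#' Validate a peak table
#'
#' Checks the interval and summit invariants and returns the table invisibly
#' unchanged so it can be used in pipelines.
#'
#' @param df A peak `data.frame` as produced by [peak_table()] or [read_peaks()].
#' @return The validated `data.frame`.
#' @export
validate_peaks <- function(df) {
  req <- c("chrom", "start", "end", "name", "score", "strand", "summit")
  miss <- setdiff(req, names(df))
  if (length(miss)) stopf("peak table missing columns: %s", paste(miss, collapse = ", "))
  if (any(df$chrom == "" | is.na(df$chrom))) stopf("peak table has empty chromosome names")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) stopf("invalid interval at row %d: need 0 <= start < end", bad[1])
  bad <- which(!(df$summit >= df$start & df$summit < df$end))
  if (length(bad)) stopf("summit outside interval at row %d", bad[1])
  if (any(df$score < 0)) stopf("peak scores must be >= 0")
  df
}

#' Construct a transcript-unit table
#'
#' A transcript unit is an actively transcribed interval with a strand; its
#' TSS is always the 5' end (`start` for `+` transcripts, `end - 1` for `-`).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end 0-based half-open genomic span of the unit.
#' @param id Transcript identifiers.
#' @param strand `"+"` or `"-"` per transcript.
#' @return A `data.frame` with columns `chrom, start, end, id, strand, tss`.
#' @export
transcript_table <- function(chrom, start, end, id = NULL, strand = "+") {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    id = as.character(id %||% paste0("tx_", seq_along(start))),
    strand = as.character(strand),
    stringsAsFactors = FALSE
  )
  if (any(!df$strand %in% c("+", "-"))) stopf("transcripts must be stranded (+/-)")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) stopf("invalid transcript interval at row %d", bad[1])
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df
}

#' Widen peaks to fixed summit-centered windows
#'
#' Replaces each peak interval by `[summit - flank, summit + flank)`, clipped
#' to chromosome bounds. This is the standard preparation for comparing
#' narrow summit-resolution peak sets against broad tiling-array peaks,
#' where summits are extended (typically by 100 nt each side) before
#' summit-distance matching.
#'
#' @param peaks Peak `data.frame`.
#' @param flank Bases added on each side of the summit; must be >= 1 so the
#'   resulting interval is non-empty.
#' @param seqlengths Optional named integer vector of chromosome lengths used
#'   for right-side clipping.
#' @return Peak `data.frame` with replaced `start`/`end`.
#' @export
extend_summits <- function(peaks, flank, seqlengths = NULL) {
  assert_scalar_num(flank, "flank", min = 0)
  if (flank < 1) stopf("'flank' must be >= 1: a zero-width interval is not a valid peak")
  peaks$start <- pmax(0L, peaks$summit - as.integer(flank))
  peaks$end <- peaks$summit + as.integer(flank)
  if (!is.null(seqlengths)) {
    len <- seqlengths[peaks$chrom]
    if (any(is.na(len))) stopf("seqlengths missing chromosome '%s'",
                               peaks$chrom[which(is.na(len))[1]])
    peaks$end <- pmin(peaks$end, as.integer(len))
  }
  validate_peaks(peaks)
}
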
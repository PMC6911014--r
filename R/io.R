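#' Read peaks from a BED6+1 file
#'
#' Expected columns: chrom, start, end, name, score, strand and a seventh
#' column holding the summit as an offset relative to `start` (the MACS2
#' convention), converted to an absolute coordinate on read.
#'
#' @param path Path to a tab-separated BED file without header.
#' @return A validated peak `data.frame` (see [peak_table()]).
#' @export
read_peaks <- function(path) {
  df <- read_bedlike(path, min_cols = 7L)
  peaks <- data.frame(
    chrom = df[[1]], start = as.integer(df[[2]]), end = as.integer(df[[3]]),
    name = df[[4]], score = as.numeric(df[[5]]), strand = df[[6]],
    summit = as.integer(df[[2]]) + as.integer(df[[7]]),
    stringsAsFactors = FALSE
  )
  validate_peaks(peaks)
}

#' Write peaks as BED6+1
#'
#' Inverse of [read_peaks()]; the summit is stored as offset from `start`.
#'
#' @param peaks Peak `data.frame`.
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  validate_peaks(peaks)
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    peaks$score, peaks$strand, peaks$summit - peaks$start)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcript units from BED6
#'
#' Column 5 (score) is ignored; strand is required.
#'
#' @param path Path to a BED6 file.
#' @return A transcript `data.frame` (see [transcript_table()]).
#' @export
read_transcripts <- function(path) {
  df <- read_bedlike(path, min_cols = 6L)
  transcript_table(df[[1]], as.integer(df[[2]]), as.integer(df[[3]]),
                   id = df[[4]], strand = df[[6]])
}

#' Write transcript units as BED6
#' @param tx Transcript `data.frame`.
#' @param path Output path.
#' @export
write_transcripts <- function(tx, path) {
  out <- data.frame(tx$chrom, tx$start, tx$end, tx$id, 0L, tx$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_bedlike <- function(path, min_cols) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      colClasses = "character", quote = ""),
    error = function(e) stopf("cannot parse '%s': %s", path, conditionMessage(e))
  )
  if (ncol(df) < min_cols)
    stopf("'%s' has %d columns, need >= %d", path, ncol(df), min_cols)
  for (j in 2:3) {
    v <- suppressWarnings(as.integer(df[[j]]))
    if (anyNA(v)) stopf("'%s' line %d: non-integer coordinate", path, which(is.na(v))[1])
    df[[j]] <- v
  }
  df
}

#' Read a genome from FASTA
#'
#' @param path Path to a (multi-)FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write a genome to FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
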
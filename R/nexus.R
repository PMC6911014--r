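#' Preprocess ChIP-nexus reads
#'
#' Collapses molecular duplicates on the key (chrom, position, strand,
#' random barcode), strips both barcodes, and discards reads shorter than
#' `min_len` nucleotides. The first occurrence of each duplicate key is
#' kept. Applied to already-processed reads the function is the identity.
#'
#' @param reads `data.frame` with columns `chrom`, `pos`, `strand`,
#'   `length`, and `fixed_bc`/`random_bc`. Without a `random_bc` column the
#'   input is taken to be already collapsed (molecular identity is no
#'   longer recoverable) and only the length filter applies, so re-running
#'   the function on its own output is the identity.
#' @param min_len Minimum retained read length in nucleotides (default 22).
#' @return A list with `reads` (the retained records, barcode columns
#'   dropped) and `stats` (named counts: `input`, `duplicates_removed`,
#'   `short_removed`, `retained`).
#' @export
preprocess_reads <- function(reads, min_len = 22) {
  n_in <- nrow(reads)
  if ("random_bc" %in% names(reads)) {
    key <- paste(reads$chrom, reads$pos, reads$strand, reads$random_bc,
                 sep = "\r")
    uniq <- !duplicated(key)
    n_dup <- sum(!uniq)
    reads <- reads[uniq, , drop = FALSE]
  } else {
    n_dup <- 0L
  }
  long_enough <- reads$length >= min_len
  n_short <- sum(!long_enough)
  reads <- reads[long_enough, , drop = FALSE]
  reads$fixed_bc <- NULL
  reads$random_bc <- NULL
  rownames(reads) <- NULL
  list(reads = reads,
       stats = c(input = n_in, duplicates_removed = n_dup,
                 short_removed = n_short, retained = nrow(reads)))
}

#' Strand-wise read counts around a peak summit
#'
#' Sums per-base 5'-end counts on each strand within
#' `[summit - window, summit + window)`.
#'
#' @param cov A `stranded_coverage`.
#' @param peak Single-row peak `data.frame` (or a list with `chrom` and
#'   `summit`).
#' @param window Half-width in bases.
#' @return Named numeric vector `c(forward = ..., reverse = ...)`.
#' @export
strand_counts <- function(cov, peak, window = 100) {
  if (window <= 0) stopf("window must be > 0")
  ch <- as.character(peak$chrom[1])
  if (!ch %in% names(cov$plus)) stopf("peak chromosome '%s' not in coverage", ch)
  L <- length(cov$plus[[ch]])
  lo <- max(0L, peak$summit[1] - as.integer(window))
  hi <- min(L, peak$summit[1] + as.integer(window))
  if (lo >= L || hi <= 0) stopf("peak summit outside coverage on '%s'", ch)
  idx <- (lo + 1L):hi
  c(forward = sum(cov$plus[[ch]][idx]), reverse = sum(cov$minus[[ch]][idx]))
}

#' Orientation index of strand-resolved read counts
#'
#' `OI = max(forward, reverse) / (forward + reverse)`, ranging from 0.5
#' (perfectly strand-symmetric binding, as for homodimers centered on a
#' palindrome) to 1 (all reads on one strand, the signature of an
#' asymmetric, directional footprint). Vectorized over its arguments.
#'
#' @param forward,reverse Non-negative read counts.
#' @return Numeric vector of OI values in `[0.5, 1]`.
#' @export
#' @examples
#' orientation_index(10, 10) # 0.5
#' orientation_index(10, 0)  # 1
orientation_index <- function(forward, reverse) {
  if (any(forward < 0 | reverse < 0)) stopf("read counts must be >= 0")
  tot <- forward + reverse
  if (any(tot == 0)) stopf("orientation index undefined when both counts are 0")
  pmax(forward, reverse) / tot
}

#' Orientation indexes for the top motif-containing peaks
#'
#' Filters peaks to motif-positive ones, keeps the `n` highest-scoring
#' (all, with a warning, if fewer are available), and computes per-peak
#' forward/reverse 5'-end counts and the orientation index in a
#' summit-centered window. Peaks with zero reads in the window are
#' excluded with a warning stating how many were dropped.
#'
#' @param peaks Peak `data.frame`.
#' @param cov A `stranded_coverage` of ChIP-nexus 5'-end counts.
#' @param presence Logical motif-presence vector aligned with `peaks`.
#' @param n Number of top peaks to keep (default 500).
#' @param window Half-width of the counting window in bases.
#' @return `data.frame` with `name`, `score`, `forward`, `reverse`, `oi`.
#' @export
oi_for_top_peaks <- function(peaks, cov, presence, n = 500, window = 100) {
  if (n < 1) stopf("n must be >= 1")
  stopifnot(length(presence) == nrow(peaks))
  sel <- peaks[presence, , drop = FALSE]
  if (!nrow(sel)) stopf("no motif-containing peaks to rank")
  sel <- sel[order(sel$score, decreasing = TRUE, method = "radix"), , drop = FALSE]
  if (nrow(sel) < n)
    warnf("only %d motif-containing peaks available (requested top %d)", nrow(sel), n)
  sel <- utils::head(sel, n)
  fw <- rv <- numeric(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    cnt <- strand_counts(cov, sel[i, ], window = window)
    fw[i] <- cnt[["forward"]]; rv[i] <- cnt[["reverse"]]
  }
  keep <- fw + rv > 0
  if (any(!keep)) warnf("excluded %d peak(s) with zero reads in the OI window", sum(!keep))
  data.frame(name = sel$name[keep], score = sel$score[keep],
             forward = fw[keep], reverse = rv[keep],
             oi = orientation_index(fw[keep], rv[keep]),
             stringsAsFactors = FALSE)
}

#' Require peaks to be supported by both assays
#'
#' Retains ChIP-nexus peaks whose summit lies within `max_dist` of a
#' ChIP-seq peak summit, yielding the high-confidence binding sites used by
#' the insulation analysis.
#'
#' @param nexus_peaks,chipseq_peaks Peak `data.frame`s.
#' @param max_dist Summit-distance threshold in bases (default 50).
#' @return The retained subset of `nexus_peaks`.
#' @export
require_dual_support <- function(nexus_peaks, chipseq_peaks, max_dist = 50) {
  if (!nrow(nexus_peaks)) stopf("nexus peak set is empty")
  if (!nrow(chipseq_peaks)) stopf("ChIP-seq peak set is empty")
  res <- match_by_summit(nexus_peaks, chipseq_peaks, max_dist)
  out <- nexus_peaks[nexus_peaks$name %in% res$pairs$a_name, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read ChIP-nexus reads from TSV
#'
#' Columns: chrom, pos, strand, length, fixed_bc, random_bc (header line).
#'
#' @param path Input path.
#' @return Read `data.frame`.
#' @export
read_nexus_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "character",
                                   "integer", "character", "character"),
                    stringsAsFactors = FALSE)
}

#' Write ChIP-nexus reads as TSV
#' @param reads Read `data.frame`.
#' @param path Output path.
#' @export
write_nexus_tsv <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
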
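# IUPAC code -> base set; N is kept out of the other codes' classes so an
# N in the scanned sequence only ever matches the pattern code N.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Define a consensus motif
#'
#' @param name Motif identifier.
#' @param consensus IUPAC consensus string (e.g. `"CCAATAAG"`).
#' @param class `"symmetric"` (palindromic site bound by homodimers) or
#'   `"asymmetric"` (directional site bound by the heterotrimeric complex).
#' @param scan_both_strands Whether [scan_consensus()] also reports reverse
#'   strand matches.
#' @return A list of class `motif_spec`.
#' @export
motif_spec <- function(name, consensus,
                       class = c("symmetric", "asymmetric"),
                       scan_both_strands = TRUE) {
  consensus <- toupper(consensus)
  if (!nzchar(consensus)) stopf("consensus must be non-empty")
  bad <- setdiff(strsplit(consensus, "")[[1]], names(IUPAC_SETS))
  if (length(bad)) stopf("invalid IUPAC code(s) in consensus: %s",
                         paste(unique(bad), collapse = ", "))
  structure(list(name = name, consensus = consensus,
                 class = match.arg(class),
                 scan_both_strands = isTRUE(scan_both_strands)),
            class = "motif_spec")
}

#' Built-in Insv/ELBA motif definitions
#'
#' The palindromic symmetric site recognized by BEN-solo homodimers
#' (core `CCAATTGG`, full site `TCCAATTGGA`, degenerate `TCYAATHRGAA`)
#' and the asymmetric `CCAATAAG` site bound by the ELBA heterotrimer.
#'
#' @return Named list of `motif_spec` objects: `symmetric`,
#'   `symmetric_core`, and `asymmetric`.
#' @export
builtin_motifs <- function() {
  list(
    symmetric = motif_spec("symmetric", "TCYAATHRGAA", "symmetric",
                           scan_both_strands = TRUE),
    symmetric_core = motif_spec("symmetric_core", "CCAATTGG", "symmetric",
                                scan_both_strands = FALSE),
    asymmetric = motif_spec("asymmetric", "CCAATAAG", "asymmetric",
                            scan_both_strands = TRUE)
  )
}

#' Reverse-complement an IUPAC consensus string
#' @param consensus IUPAC string.
#' @return The reverse complement, with ambiguity codes mapped correctly.
#' @export
revcomp_consensus <- function(consensus) {
  ch <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(ch, names(IUPAC_COMPLEMENT))
  if (length(bad)) stopf("invalid IUPAC code(s): %s", paste(unique(bad), collapse = ", "))
  paste(rev(IUPAC_COMPLEMENT[ch]), collapse = "")
}

iupac_regex <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]], function(code) {
    set <- IUPAC_SETS[[code]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

scan_one_strand <- function(seq, consensus) {
  # lookahead so overlapping matches are all reported
  pat <- paste0("(?=", iupac_regex(consensus), ")")
  hits <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L
}

#' Scan a sequence for a consensus motif
#'
#' Reports every position where the IUPAC pattern matches, including
#' overlapping occurrences. Reverse-strand matches (when enabled in the
#' spec) are found by scanning the forward sequence with the
#' reverse-complemented consensus. `N` in the sequence matches only the
#' pattern code `N`.
#'
#' @param seq A single sequence over `ACGTN` (character scalar).
#' @param spec A `motif_spec`.
#' @return `data.frame` with 0-based half-open `start`, `end`, `strand`,
#'   `motif` columns, sorted by `start` then strand.
#' @export
scan_consensus <- function(seq, spec) {
  stopifnot(inherits(spec, "motif_spec"))
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad)) stopf("sequence contains non-ACGTN letters: %s",
                         paste(bad, collapse = ", "))
  w <- nchar(spec$consensus)
  fwd <- scan_one_strand(seq, spec$consensus)
  out <- data.frame(start = fwd, end = fwd + w,
                    strand = rep("+", length(fwd)),
                    motif = rep(spec$name, length(fwd)),
                    stringsAsFactors = FALSE)
  if (spec$scan_both_strands) {
    rev <- scan_one_strand(seq, revcomp_consensus(spec$consensus))
    # drop reverse hits that duplicate a forward hit of a palindromic pattern
    rev <- setdiff(rev, fwd)
    out <- rbind(out, data.frame(start = rev, end = rev + w,
                                 strand = rep("-", length(rev)),
                                 motif = rep(spec$name, length(rev)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a whole genome for a consensus motif
#'
#' @param genome Named character vector of chromosome sequences.
#' @param spec A `motif_spec`.
#' @return `data.frame` with `chrom`, `start`, `end`, `strand`, `motif`.
#' @export
scan_genome <- function(genome, spec) {
  res <- lapply(names(genome), function(ch) {
    m <- scan_consensus(genome[[ch]], spec)
    if (nrow(m)) cbind(chrom = ch, m, stringsAsFactors = FALSE) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), motif = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(res, make.row.names = FALSE))
}

#' Motif presence within a summit-centered window
#'
#' A peak is motif-positive if at least one consensus match starts inside
#' `[summit - flank, summit + flank)`. Windows running off a sequence end
#' are clipped with a warning.
#'
#' @param peaks Peak `data.frame`.
#' @param genome Named character vector of sequences.
#' @param spec A `motif_spec`.
#' @param flank Half-width of the presence window in bases.
#' @return Logical vector, one element per peak.
#' @export
peak_motif_presence <- function(peaks, genome, spec, flank = 250) {
  miss <- setdiff(unique(peaks$chrom), names(genome))
  if (length(miss)) stopf("genome lacks chromosome(s): %s", paste(miss, collapse = ", "))
  matches <- scan_genome(genome, spec)
  clipped <- FALSE
  out <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    lo <- peaks$summit[i] - flank
    hi <- peaks$summit[i] + flank
    L <- nchar(genome[[peaks$chrom[i]]])
    if (lo < 0 || hi > L) { clipped <- TRUE; lo <- max(lo, 0); hi <- min(hi, L) }
    sel <- matches$chrom == peaks$chrom[i] & matches$start >= lo & matches$start < hi
    out[i] <- any(sel)
  }
  if (clipped) warnf("some presence windows were clipped at sequence ends")
  out
}

#' Fraction of motif-containing peaks per score bin
#'
#' Peaks are ranked by score and split into near-equal bins from highest to
#' lowest score (any remainder goes to the top bins); the fraction of
#' motif-positive peaks is reported per bin. A rising trend indicates that
#' motif occurrence correlates with binding strength.
#'
#' @param peaks Peak `data.frame`.
#' @param presence Logical vector from [peak_motif_presence()].
#' @param n_bins Number of score bins (default 10).
#' @return `data.frame` with `bin` (1 = highest scores), `n`, and `fraction`.
#' @export
motif_fraction_by_score_bin <- function(peaks, presence, n_bins = 10) {
  if (n_bins < 1) stopf("n_bins must be >= 1")
  n <- nrow(peaks)
  if (n < n_bins) stopf("need at least as many peaks (%d) as bins (%d)", n, n_bins)
  stopifnot(length(presence) == n)
  ord <- order(peaks$score, decreasing = TRUE)
  base <- n %/% n_bins
  sizes <- rep.int(base, n_bins)
  extra <- n - base * n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- rep(seq_len(n_bins), times = sizes)
  p <- presence[ord]
  data.frame(bin = seq_len(n_bins), n = sizes,
             fraction = as.numeric(tapply(p, bin, mean)))
}

#' Summit-centered motif coverage profile
#'
#' For each offset in `-window..+window` relative to the peak summit, the
#' mean over peaks of the indicator that the base is covered by a motif
#' match ("motif per base"). Sharp profiles indicate motif-anchored,
#' summit-resolved binding.
#'
#' @param peaks Peak `data.frame`.
#' @param matches Motif match `data.frame` from [scan_genome()].
#' @param window Half-width in bases.
#' @return `data.frame` with `offset` and `coverage` columns.
#' @export
motif_per_base_profile <- function(peaks, matches, window = 500) {
  if (window <= 0) stopf("window must be > 0")
  offs <- seq.int(-window, window)
  acc <- numeric(length(offs))
  for (ch in unique(peaks$chrom)) {
    mm <- matches[matches$chrom == ch, , drop = FALSE]
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    if (!nrow(mm) || !nrow(pk)) next
    cov_pos <- unique(unlist(lapply(seq_len(nrow(mm)), function(i)
      seq.int(mm$start[i], mm$end[i] - 1L))))
    for (i in seq_len(nrow(pk))) {
      acc <- acc + as.numeric((pk$summit[i] + offs) %in% cov_pos)
    }
  }
  data.frame(offset = offs, coverage = acc / max(nrow(peaks), 1L))
}
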
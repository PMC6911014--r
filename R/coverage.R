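#' Construct a stranded per-base coverage object
#'
#' Holds dense per-chromosome arrays of read 5'-end counts for each strand,
#' the library size, and a flag marking whether the values have been scaled
#' to reads per million (RPM).
#'
#' @param plus,minus Named lists of non-negative numeric vectors, one per
#'   chromosome, both over the same chromosome set and lengths.
#' @param library_size Total mapped reads; defaults to the sum of all counts.
#' @param normalized Logical; `TRUE` once values are RPM-scaled.
#' @return An object of class `stranded_coverage`.
#' @export
stranded_coverage <- function(plus, minus, library_size = NULL, normalized = FALSE) {
  if (!identical(sort(names(plus)), sort(names(minus))))
    stopf("plus and minus tracks cover different chromosome sets")
  for (ch in names(plus)) {
    if (length(plus[[ch]]) != length(minus[[ch]]))
      stopf("strand arrays differ in length on '%s'", ch)
    if (any(plus[[ch]] < 0) || any(minus[[ch]] < 0))
      stopf("negative coverage on '%s'", ch)
  }
  obj <- list(
    plus = plus[sort(names(plus))],
    minus = minus[sort(names(minus))],
    seqlengths = vapply(plus[sort(names(plus))], length, integer(1)),
    library_size = library_size %||%
      (sum(vapply(plus, sum, numeric(1))) + sum(vapply(minus, sum, numeric(1)))),
    normalized = isTRUE(normalized)
  )
  class(obj) <- "stranded_coverage"
  obj
}

#' @export
print.stranded_coverage <- function(x, ...) {
  cat(sprintf("stranded_coverage: %d chromosome(s), library_size=%g, %s\n",
              length(x$seqlengths), x$library_size,
              if (x$normalized) "RPM" else "raw counts"))
  invisible(x)
}

#' Build stranded coverage from read 5'-end positions
#'
#' @param reads `data.frame` with columns `chrom`, `pos` (0-based 5' end)
#'   and `strand` (`"+"`/`"-"`).
#' @param seqlengths Named integer vector of chromosome lengths.
#' @return A raw-count `stranded_coverage`.
#' @export
coverage_from_reads <- function(reads, seqlengths) {
  mk <- function(str) {
    lapply(stats::setNames(names(seqlengths), names(seqlengths)), function(ch) {
      v <- numeric(seqlengths[[ch]])
      sel <- reads$chrom == ch & reads$strand == str
      if (any(sel)) {
        tab <- table(reads$pos[sel] + 1L)
        idx <- as.integer(names(tab))
        if (any(idx < 1L | idx > length(v))) stopf("read position outside '%s'", ch)
        v[idx] <- as.numeric(tab)
      }
      v
    })
  }
  stranded_coverage(mk("+"), mk("-"), library_size = nrow(reads))
}

#' Scale coverage to reads per million
#'
#' Multiplies every per-base count by `1e6 / library_size` and sets the
#' normalized flag. Calling it twice is an error: the transform is not
#' meant to be stacked.
#'
#' @param cov A raw-count `stranded_coverage`.
#' @return The RPM-scaled `stranded_coverage`.
#' @export
rpm_normalize <- function(cov) {
  stopifnot(inherits(cov, "stranded_coverage"))
  if (cov$normalized) stopf("coverage is already RPM-normalized")
  if (!cov$library_size > 0) stopf("library_size must be > 0 to normalize")
  f <- 1e6 / cov$library_size
  cov$plus <- lapply(cov$plus, function(v) v * f)
  cov$minus <- lapply(cov$minus, function(v) v * f)
  cov$normalized <- TRUE
  cov
}

#' Per-base log2 ratio between two coverage tracks
#'
#' Computes `log2((wt + pseudocount) / (mut + pseudocount))` per base on the
#' strand-summed signal, the standard differential track for wild-type vs
#' mutant ChIP comparisons. Both inputs must be RPM-normalized and cover the
#' same chromosomes.
#'
#' @param wt,mut RPM-normalized `stranded_coverage` objects.
#' @param pseudocount Added to both tracks before the ratio (RPM units).
#' @return Named list of per-base numeric vectors (class `ratio_track`).
#' @export
log2_ratio_track <- function(wt, mut, pseudocount = 1) {
  stopifnot(inherits(wt, "stranded_coverage"), inherits(mut, "stranded_coverage"))
  if (!wt$normalized || !mut$normalized)
    stopf("both tracks must be RPM-normalized before taking a log2 ratio")
  if (!identical(names(wt$plus), names(mut$plus)))
    stopf("chromosome sets differ between the two tracks")
  out <- lapply(stats::setNames(names(wt$plus), names(wt$plus)), function(ch) {
    a <- wt$plus[[ch]] + wt$minus[[ch]]
    b <- mut$plus[[ch]] + mut$minus[[ch]]
    if (length(a) != length(b)) stopf("chromosome '%s' lengths differ", ch)
    log2((a + pseudocount) / (b + pseudocount))
  })
  class(out) <- "ratio_track"
  out
}

#' Anchor-centered signal matrix
#'
#' Extracts the track value at every offset in `-window..+window` around each
#' anchor position, the building block for summit- or TSS-centered heatmaps
#' and average profiles. Out-of-bounds cells are `NA` and are excluded from
#' column means.
#'
#' @param track A `ratio_track` (from [log2_ratio_track()]), a plain named
#'   list of per-base vectors, or a `stranded_coverage` (strands summed).
#' @param anchors `data.frame` with columns `chrom` and `pos` (0-based).
#' @param window Half-width in bases.
#' @param order_by Optional numeric ranking vector (rows sorted decreasing).
#' @return Numeric matrix, one row per anchor, `2 * window + 1` columns named
#'   by offset.
#' @export
anchored_matrix <- function(track, anchors, window = 1000, order_by = NULL) {
  if (inherits(track, "stranded_coverage"))
    track <- mapply(`+`, track$plus, track$minus, SIMPLIFY = FALSE)
  if (nrow(anchors) == 0L) stopf("no anchors supplied")
  offs <- seq.int(-window, window)
  m <- matrix(NA_real_, nrow = nrow(anchors), ncol = length(offs),
              dimnames = list(NULL, offs))
  for (i in seq_len(nrow(anchors))) {
    v <- track[[anchors$chrom[i]]]
    if (is.null(v)) stopf("anchor chromosome '%s' not in track", anchors$chrom[i])
    pos <- anchors$pos[i] + offs
    ok <- pos >= 0L & pos < length(v)
    m[i, ok] <- v[pos[ok] + 1L]
  }
  if (!is.null(order_by)) m <- m[order(order_by, decreasing = TRUE), , drop = FALSE]
  m
}

#' Write stranded coverage as a bedGraph file pair
#'
#' Runs of equal non-zero values are merged into single bedGraph intervals;
#' zero runs are implicit. Two files are written, suffixed `.plus.bedgraph`
#' and `.minus.bedgraph`.
#'
#' @param cov A `stranded_coverage`.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_bedgraph_pair <- function(cov, prefix) {
  stopifnot(inherits(cov, "stranded_coverage"))
  paths <- paste0(prefix, c(".plus.bedgraph", ".minus.bedgraph"))
  for (k in 1:2) {
    tracks <- if (k == 1) cov$plus else cov$minus
    con <- file(paths[k], open = "wt")
    for (ch in names(tracks)) {
      r <- rle(tracks[[ch]])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- r$values != 0
      if (any(keep)) {
        writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                           format(r$values[keep], trim = TRUE, scientific = FALSE)),
                   con)
      }
    }
    close(con)
  }
  invisible(paths)
}

#' Read a stranded bedGraph file pair
#'
#' @param plus_path,minus_path Paths to the two per-strand bedGraph files.
#' @param seqlengths Named integer vector of chromosome lengths; if `NULL`,
#'   each chromosome length is inferred as the maximum interval end seen.
#' @param library_size Total mapped reads; defaults to the sum of counts.
#' @param normalized Whether the stored values are already RPM.
#' @return A `stranded_coverage`.
#' @export
read_bedgraph_pair <- function(plus_path, minus_path, seqlengths = NULL,
                               library_size = NULL, normalized = FALSE) {
  parse_one <- function(path) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(list())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 4L)) stopf("'%s' line %d: expected 4 fields", path, which(nf != 4L)[1])
    df <- data.frame(
      chrom = vapply(parts, `[[`, "", 1L),
      start = suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L))),
      end = suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L))),
      value = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L))),
      stringsAsFactors = FALSE
    )
    bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$value) | df$start >= df$end)
    if (length(bad)) stopf("'%s' line %d: malformed interval", path, bad[1])
    ord <- order(df$chrom, df$start)
    df <- df[ord, ]
    same <- df$chrom[-1] == df$chrom[-nrow(df)]
    if (nrow(df) > 1 && any(same & df$start[-1] < df$end[-nrow(df)])) {
      i <- which(same & df$start[-1] < df$end[-nrow(df)])[1]
      stopf("'%s': overlapping intervals on %s near base %d", path,
            df$chrom[i + 1], df$start[i + 1])
    }
    split(df, df$chrom)
  }
  p <- parse_one(plus_path)
  m <- parse_one(minus_path)
  chroms <- sort(union(names(p), names(m)))
  if (is.null(seqlengths)) {
    seqlengths <- vapply(stats::setNames(chroms, chroms), function(ch) {
      max(c(0L, p[[ch]]$end, m[[ch]]$end))
    }, integer(1))
  }
  fill <- function(parsed) {
    lapply(stats::setNames(chroms, chroms), function(ch) {
      v <- numeric(seqlengths[[ch]])
      df <- parsed[[ch]]
      if (!is.null(df)) {
        if (any(df$end > length(v))) stopf("interval beyond chromosome end on '%s'", ch)
        for (i in seq_len(nrow(df))) v[(df$start[i] + 1L):df$end[i]] <- df$value[i]
      }
      v
    })
  }
  stranded_coverage(fill(p), fill(m), library_size = library_size,
                    normalized = normalized)
}
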
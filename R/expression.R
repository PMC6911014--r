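#' Counts-per-million normalization
#'
#' Scales each column (library) of a gene-by-sample count matrix so it sums
#' to one million.
#'
#' @param counts Numeric matrix, genes in rows and samples in columns.
#' @return CPM matrix with the same dimensions.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) stopf("library with zero total counts cannot be CPM-scaled")
  sweep(counts, 2L, lib, "/") * 1e6
}

#' Annotate genes with their best binding peak
#'
#' A gene is a direct target (bound) if a peak summit lies within
#' `max_tss_dist` of its TSS; the best peak is the highest-scoring such
#' peak, and the gene inherits that peak's motif status.
#'
#' @param genes Transcript `data.frame` (see [transcript_table()]).
#' @param peaks Peak `data.frame`.
#' @param presence Logical motif-presence vector aligned with `peaks`.
#' @param max_tss_dist Maximum summit-to-TSS distance in bases.
#' @return `data.frame` with `gene`, `bound`, `score` (best peak score,
#'   `NA` if unbound), `peak` (its name), `motif`.
#' @export
annotate_targets <- function(genes, peaks, presence, max_tss_dist = 1000) {
  stopifnot(length(presence) == nrow(peaks))
  out <- data.frame(gene = genes$id, bound = FALSE, score = NA_real_,
                    peak = NA_character_, motif = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(genes))) {
    sel <- which(peaks$chrom == genes$chrom[i] &
                   abs(peaks$summit - genes$tss[i]) <= max_tss_dist)
    if (length(sel)) {
      best <- sel[order(peaks$score[sel], peaks$name[sel],
                        decreasing = c(TRUE, FALSE), method = "radix")[1]]
      out$bound[i] <- TRUE
      out$score[i] <- peaks$score[best]
      out$peak[i] <- peaks$name[best]
      out$motif[i] <- presence[best]
    }
  }
  out
}

#' Assemble a gene expression table for the de-repression contrast
#'
#' Computes CPM from raw counts and the per-gene mutant vs wild-type log2
#' fold change, joined with the binding annotation.
#'
#' @param counts Matrix or `data.frame` with columns for the two genotypes,
#'   rows named (or a `gene` column) matching the annotation.
#' @param wt,mutant Column names of the two genotypes.
#' @param annotation Output of [annotate_targets()].
#' @param pseudocount Added to CPM before the log ratio (default 0.5).
#' @return `data.frame` with `gene`, `log2fc`, `bound`, `score`, `motif`.
#' @export
expression_table <- function(counts, wt, mutant, annotation, pseudocount = 0.5) {
  if (is.data.frame(counts) && "gene" %in% names(counts)) {
    rn <- counts$gene
    counts <- as.matrix(counts[, setdiff(names(counts), "gene"), drop = FALSE])
    rownames(counts) <- rn
  }
  x <- cpm(counts)
  if (!all(c(wt, mutant) %in% colnames(x)))
    stopf("counts must have columns '%s' and '%s'", wt, mutant)
  df <- data.frame(gene = rownames(x),
                   log2fc = log2((x[, mutant] + pseudocount) /
                                   (x[, wt] + pseudocount)),
                   stringsAsFactors = FALSE, row.names = NULL)
  m <- match(df$gene, annotation$gene)
  if (anyNA(m)) stopf("annotation missing %d gene(s)", sum(is.na(m)))
  cbind(df, annotation[m, c("bound", "score", "motif")], row.names = NULL)
}

#' Three-group de-repression contrast of direct targets
#'
#' Compares the mutant-vs-wt log2 fold changes of three target groups:
#' the top `top_n` bound genes that carry the motif (ranked by best peak
#' score, ties broken by gene id), all bound genes with the motif (a
#' superset of the first group), and bound genes without the motif.
#' Pairwise two-tailed Welch t-tests are Bonferroni-adjusted over the
#' three comparisons. De-repression of direct targets appears as group
#' means ordered top-n > with-motif > without-motif.
#'
#' @param table Expression table from [expression_table()] (columns
#'   `gene`, `log2fc`, `bound`, `score`, `motif`).
#' @param top_n Size of the top-bound group (default 200); a smaller
#'   available pool triggers a warning.
#' @return List with `groups` (per-group n and mean log2fc) and `tests`
#'   (pairwise `p` and Bonferroni `p_adj`; `NA` for untestable cells).
#' @export
three_group_contrast <- function(table, top_n = 200) {
  bm <- table[table$bound & table$motif, , drop = FALSE]
  bn <- table[table$bound & !table$motif, , drop = FALSE]
  if (nrow(bm) < top_n)
    warnf("only %d bound motif-carrying genes available (requested top %d)",
          nrow(bm), top_n)
  ord <- order(bm$score, bm$gene, decreasing = c(TRUE, FALSE), method = "radix")
  top <- utils::head(bm[ord, , drop = FALSE], top_n)
  groups <- list(top_bound_motif = top$log2fc,
                 all_bound_motif = bm$log2fc,
                 bound_no_motif = bn$log2fc)
  gsum <- data.frame(group = names(groups),
                     n = vapply(groups, length, integer(1)),
                     mean_log2fc = vapply(groups, function(v)
                       if (length(v)) mean(v) else NA_real_, numeric(1)),
                     row.names = NULL, stringsAsFactors = FALSE)
  cmp <- utils::combn(names(groups), 2L)
  tests <- data.frame(group_a = cmp[1, ], group_b = cmp[2, ],
                      p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(cmp))) {
    a <- groups[[cmp[1, k]]]; b <- groups[[cmp[2, k]]]
    if (length(a) >= 2 && length(b) >= 2 &&
        (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      tests$p[k] <- stats::t.test(a, b, alternative = "two.sided")$p.value
    }
  }
  tests$p_adj <- pmin(1, tests$p * nrow(tests))
  list(groups = gsum, tests = tests,
       note = "all_bound_motif includes the top_bound_motif genes")
}
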
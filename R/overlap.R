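#' Match two peak sets by summit distance
#'
#' Greedy one-to-one matching of summits within `max_dist` bases, per
#' chromosome. Candidate pairs are taken in order of ascending distance;
#' ties are broken by the leftmost A summit, then the leftmost B summit.
#' Each peak participates in at most one matched pair, which makes the
#' result deterministic and independent of the input row order.
#'
#' @param A,B Peak `data.frame`s (see [peak_table()]).
#' @param max_dist Maximum allowed `|summit_A - summit_B|` in bases.
#' @return A list of class `overlap_result`: `pairs` (`data.frame` with
#'   `a_name`, `b_name`, `distance`), and counts `overlapped_a`,
#'   `overlapped_b`, `total_a`, `total_b`.
#' @export
match_by_summit <- function(A, B, max_dist) {
  assert_scalar_num(max_dist, "max_dist", min = 0)
  pairs_list <- list()
  for (ch in intersect(unique(A$chrom), unique(B$chrom))) {
    ai <- which(A$chrom == ch)
    bi <- which(B$chrom == ch)
    sb <- B$summit[bi]
    ob <- order(sb)
    sb_sorted <- sb[ob]
    cand_a <- integer(0); cand_b <- integer(0)
    for (i in ai) {
      lo <- findInterval(A$summit[i] - max_dist - 1L, sb_sorted) + 1L
      hi <- findInterval(A$summit[i] + max_dist, sb_sorted)
      if (lo <= hi) {
        cand_a <- c(cand_a, rep.int(i, hi - lo + 1L))
        cand_b <- c(cand_b, bi[ob[lo:hi]])
      }
    }
    if (!length(cand_a)) next
    d <- abs(A$summit[cand_a] - B$summit[cand_b])
    ord <- order(d, A$summit[cand_a], B$summit[cand_b])
    used_a <- logical(nrow(A)); used_b <- logical(nrow(B))
    keep <- logical(length(ord))
    for (k in ord) {
      if (!used_a[cand_a[k]] && !used_b[cand_b[k]]) {
        used_a[cand_a[k]] <- TRUE
        used_b[cand_b[k]] <- TRUE
        keep[k] <- TRUE
      }
    }
    if (any(keep)) {
      pairs_list[[ch]] <- data.frame(
        a_name = A$name[cand_a[keep]], b_name = B$name[cand_b[keep]],
        distance = d[keep], stringsAsFactors = FALSE
      )
    }
  }
  pairs <- if (length(pairs_list)) do.call(rbind, c(pairs_list, make.row.names = FALSE))
           else data.frame(a_name = character(0), b_name = character(0),
                           distance = integer(0), stringsAsFactors = FALSE)
  out <- list(pairs = pairs,
              overlapped_a = nrow(pairs), overlapped_b = nrow(pairs),
              total_a = nrow(A), total_b = nrow(B))
  class(out) <- "overlap_result"
  out
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: %d/%d A peaks matched to %d/%d B peaks\n",
              x$overlapped_a, x$total_a, x$overlapped_b, x$total_b))
  invisible(x)
}

#' Overlap fraction between two peak sets
#'
#' The number of summit-matched peak pairs divided by the size of the
#' smaller set, so identical sets score 1 and the measure is symmetric.
#'
#' @inheritParams match_by_summit
#' @return A fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(A, B, max_dist) {
  if (nrow(A) == 0L) stopf("peak set A is empty")
  if (nrow(B) == 0L) stopf("peak set B is empty")
  res <- match_by_summit(A, B, max_dist)
  nrow(res$pairs) / min(nrow(A), nrow(B))
}

#' Partition anchor peaks by four-factor co-occupancy
#'
#' Assigns each peak of the anchor factor to exactly one co-occupancy
#' category from pairwise summit matches against the other factors. With
#' the canonical factor roster (`elba1`, `elba2`, `elba3`, `insv`) the
#' categories are: `all_four`, `elba_not_insv` (the three ELBA subunits
#' without Insv), `elba3_and_insv_only`, the anchor-unique category
#' (`elba3_unique` / `insv_unique`), and `other` for remaining combinations.
#'
#' @param peak_sets Named list of peak `data.frame`s, one per factor.
#' @param anchor Name of the factor whose peaks are partitioned.
#' @param max_dist Summit-distance threshold (bases).
#' @return `data.frame` with one row per anchor peak: `name`, one logical
#'   column per co-factor, and `category`.
#' @export
venn_partition <- function(peak_sets, anchor, max_dist = 50) {
  if (length(peak_sets) < 2L) stopf("need at least two factors to partition")
  if (!anchor %in% names(peak_sets)) stopf("anchor '%s' not in peak_sets", anchor)
  ap <- peak_sets[[anchor]]
  others <- setdiff(names(peak_sets), anchor)
  hit <- matrix(FALSE, nrow(ap), length(others), dimnames = list(ap$name, others))
  for (f in others) {
    res <- match_by_summit(ap, peak_sets[[f]], max_dist)
    hit[match(res$pairs$a_name, ap$name), f] <- TRUE
  }
  bound <- lapply(seq_len(nrow(hit)),
                  function(i) sort(c(anchor, others[hit[i, ]])))
  categ <- vapply(bound, function(b) {
    if (setequal(b, c("elba1", "elba2", "elba3", "insv"))) "all_four"
    else if (setequal(b, c("elba1", "elba2", "elba3"))) "elba_not_insv"
    else if (setequal(b, c("elba3", "insv"))) "elba3_and_insv_only"
    else if (identical(b, anchor)) paste0(anchor, "_unique")
    else "other"
  }, character(1))
  data.frame(name = ap$name, hit, category = categ,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify wild-type peaks by retention in mutant genotypes
#'
#' A wild-type peak is independent of a genotype if a peak called in that
#' genotype's set lies within `max_dist` of its summit; otherwise it is
#' dependent. The joint Elba1/2 classification requires retention in *both*
#' the `elba1` and the `elba2` mutant sets for independence.
#'
#' @param wt_peaks Wild-type peak `data.frame` (typically the Elba3 set).
#' @param mutant_peaks Named list of peak `data.frame`s keyed by genotype.
#' @param max_dist Summit-distance threshold (bases).
#' @return `data.frame` with one row per wt peak: `name`, one logical
#'   `independent_<genotype>` column per genotype, and (when both `elba1`
#'   and `elba2` are present) an `elba12` factor with levels
#'   `dependent`/`independent`.
#' @export
classify_dependency <- function(wt_peaks, mutant_peaks, max_dist = 50) {
  if (!length(mutant_peaks)) stopf("mutant_peaks is empty")
  out <- data.frame(name = wt_peaks$name, stringsAsFactors = FALSE)
  for (g in names(mutant_peaks)) {
    res <- match_by_summit(wt_peaks, mutant_peaks[[g]], max_dist)
    out[[paste0("independent_", g)]] <- out$name %in% res$pairs$a_name
  }
  if (all(c("elba1", "elba2") %in% names(mutant_peaks))) {
    ind <- out$independent_elba1 & out$independent_elba2
    out$elba12 <- factor(ifelse(ind, "independent", "dependent"),
                         levels = c("dependent", "independent"))
  }
  out
}
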
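#' Quantify promoter-proximal and gene-body nascent transcription
#'
#' For each transcript unit the promoter (pausing) window runs from the
#' TSS to 200 nt downstream and the gene-body window from 400 nt
#' downstream to the transcript end, both strand-aware (downstream means
#' decreasing coordinate for `-` transcripts). Reads are summed on the
#' transcript's strand. Transcripts are retained when their promoter
#' expression exceeds `tpm_min` transcripts per million in the reference
#' genotype. Transcripts shorter than 400 nt get a missing body value with
#' a warning.
#'
#' @param transcripts Transcript `data.frame` (see [transcript_table()]).
#' @param cov_by_genotype Named list of RPM-normalized `stranded_coverage`
#'   objects, one per genotype.
#' @param reference Genotype used for the TPM retention filter (default
#'   `"wt"`).
#' @param tpm_min TPM threshold; transcripts with reference promoter TPM
#'   strictly greater are retained (default 1).
#' @return `data.frame` with one row per transcript: coordinates, windows,
#'   `retained`, and per-genotype `promoter_rpm_*`, `promoter_tpm_*`,
#'   `body_rpm_*` columns.
#' @export
quantify_promoters <- function(transcripts, cov_by_genotype, reference = "wt",
                               tpm_min = 1) {
  if (!reference %in% names(cov_by_genotype))
    stopf("reference genotype '%s' not in coverage list", reference)
  tx <- transcripts
  dir <- ifelse(tx$strand == "+", 1L, -1L)
  prom_lo <- ifelse(dir == 1L, tx$tss, tx$tss - 199L)
  prom_hi <- prom_lo + 200L
  len <- tx$end - tx$start
  short <- len <= 400L
  if (any(short)) warnf("%d transcript(s) shorter than 400 nt: body window empty",
                        sum(short))
  body_lo <- ifelse(dir == 1L, tx$tss + 400L, tx$start)
  body_hi <- ifelse(dir == 1L, tx$end, tx$tss - 399L)

  out <- data.frame(id = tx$id, chrom = tx$chrom, strand = tx$strand,
                    tss = tx$tss, promoter_start = prom_lo,
                    promoter_end = prom_hi, stringsAsFactors = FALSE)
  window_sum <- function(cov, chrom, strand, lo, hi) {
    vapply(seq_along(chrom), function(i) {
      v <- if (strand[i] == "+") cov$plus[[chrom[i]]] else cov$minus[[chrom[i]]]
      if (is.null(v)) stopf("coverage missing chromosome '%s'", chrom[i])
      a <- max(lo[i], 0L) + 1L; b <- min(hi[i], length(v))
      if (a > b) return(NA_real_)
      sum(v[a:b])
    }, numeric(1))
  }
  for (g in names(cov_by_genotype)) {
    cov <- cov_by_genotype[[g]]
    if (!cov$normalized) stopf("coverage for genotype '%s' is not RPM-normalized", g)
    prm <- window_sum(cov, tx$chrom, tx$strand, prom_lo, prom_hi - 1L)
    prm[is.na(prm)] <- 0
    rpk <- prm / 0.2
    out[[paste0("promoter_rpm_", g)]] <- prm
    out[[paste0("promoter_tpm_", g)]] <-
      if (sum(rpk) > 0) rpk / sum(rpk) * 1e6 else rpk
    bod <- window_sum(cov, tx$chrom, tx$strand, body_lo, body_hi - 1L)
    bod[short] <- NA_real_
    out[[paste0("body_rpm_", g)]] <- bod
  }
  out$retained <- out[[paste0("promoter_tpm_", reference)]] > tpm_min
  out
}

#' Promoter quantification from simulated count tables
#'
#' Converts the generator's per-genotype promoter/body count table into the
#' same shape as [quantify_promoters()], normalizing counts to RPM within
#' each genotype's library. This is the count-table entry point to the
#' insulation analysis when per-base coverage is not needed.
#'
#' @param bundle A `sim_bundle` with `expression`.
#' @param reference Reference genotype for the TPM filter.
#' @param tpm_min TPM retention threshold (default 1).
#' @return A quantification `data.frame` as from [quantify_promoters()].
#' @export
promoter_quants_from_counts <- function(bundle, reference = "wt", tpm_min = 1) {
  if (is.null(bundle$expression)) stopf("bundle has no expression table")
  tx <- bundle$transcripts
  out <- data.frame(id = tx$id, chrom = tx$chrom, strand = tx$strand,
                    tss = tx$tss, stringsAsFactors = FALSE)
  for (g in unique(bundle$expression$genotype)) {
    cnt <- bundle$expression[bundle$expression$genotype == g, ]
    cnt <- cnt[match(tx$id, cnt$transcript_id), ]
    lib <- sum(cnt$promoter_count) + sum(cnt$body_count)
    out[[paste0("promoter_rpm_", g)]] <- cnt$promoter_count / lib * 1e6
    rpk <- cnt$promoter_count / 0.2
    out[[paste0("promoter_tpm_", g)]] <-
      if (sum(rpk) > 0) rpk / sum(rpk) * 1e6 else rpk
    out[[paste0("body_rpm_", g)]] <- cnt$body_count / lib * 1e6
  }
  out$retained <- out[[paste0("promoter_tpm_", reference)]] > tpm_min
  out
}

#' Classify the configuration of an adjacent promoter pair
#'
#' Given the strands of the left and right transcript (ordered by genomic
#' coordinate): `+`/`-` is convergent (transcribing toward each other),
#' `-`/`+` divergent, and equal strands tandem. Vectorized.
#'
#' @param left_strand,right_strand Strand characters (`"+"`/`"-"`).
#' @return Character vector of labels.
#' @export
classify_configuration <- function(left_strand, right_strand) {
  if (any(!left_strand %in% c("+", "-")) || any(!right_strand %in% c("+", "-")))
    stopf("promoter strands must be '+' or '-'")
  ifelse(left_strand == "+" & right_strand == "-", "convergent",
  ifelse(left_strand == "-" & right_strand == "+", "divergent", "tandem"))
}

# per-chromosome lookup of retained promoters, sorted by TSS
flank_lookup <- function(quants) {
  q <- quants[quants$retained, , drop = FALSE]
  lapply(split(q, q$chrom), function(df) df[order(df$tss), , drop = FALSE])
}

# left/right retained-promoter indices for summits on one chromosome
flank_indices <- function(sorted_q, summits) {
  i <- findInterval(summits - 1L, sorted_q$tss) # promoters with tss < summit
  left <- ifelse(i >= 1L, i, NA_integer_)
  right <- ifelse(i + 1L <= nrow(sorted_q) &
                    sorted_q$tss[pmin(i + 1L, nrow(sorted_q))] > summits,
                  i + 1L, NA_integer_)
  data.frame(left = left, right = right)
}

#' Find adjacent promoter pairs flanking binding sites
#'
#' For each peak, the nearest retained promoter on each side (by TSS, on
#' the same chromosome) forms a pair; by construction no other retained
#' promoter lies between the two. Peaks lacking a promoter on either side
#' are skipped and counted; when several peaks fall between the same two
#' promoters the pair is reported once for the leftmost peak.
#'
#' @param quants Quantification `data.frame` from [quantify_promoters()] or
#'   [promoter_quants_from_counts()].
#' @param peaks Peak `data.frame` of high-confidence binding sites.
#' @return `data.frame` of pairs (`pair_id`, `chrom`, `left_id`,
#'   `right_id`, `peak`, `peak_summit`, `configuration`), with the number
#'   of skipped peaks in attribute `"n_skipped"`.
#' @export
find_flanked_pairs <- function(quants, peaks) {
  lookup <- flank_lookup(quants)
  rows <- list()
  n_skipped <- 0L
  for (ch in unique(peaks$chrom)) {
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    pk <- pk[order(pk$summit), , drop = FALSE]
    q <- lookup[[ch]]
    if (is.null(q) || nrow(q) < 2L) { n_skipped <- n_skipped + nrow(pk); next }
    fi <- flank_indices(q, pk$summit)
    ok <- !is.na(fi$left) & !is.na(fi$right)
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    rows[[ch]] <- data.frame(
      chrom = ch,
      left_id = q$id[fi$left[ok]], right_id = q$id[fi$right[ok]],
      left_strand = q$strand[fi$left[ok]], right_strand = q$strand[fi$right[ok]],
      peak = pk$name[ok], peak_summit = pk$summit[ok],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(pair_id = character(0), chrom = character(0),
                      left_id = character(0), right_id = character(0),
                      left_strand = character(0), right_strand = character(0),
                      peak = character(0), peak_summit = integer(0),
                      configuration = character(0), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out <- out[!duplicated(paste(out$left_id, out$right_id)), , drop = FALSE]
  out$pair_id <- paste(out$left_id, out$right_id, sep = "__")
  out$configuration <- classify_configuration(out$left_strand, out$right_strand)
  out <- out[, c("pair_id", "chrom", "left_id", "right_id", "left_strand",
                 "right_strand", "peak", "peak_summit", "configuration")]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Absolute log2 expression difference of a promoter pair
#'
#' `|log2((left + pseudocount) / (right + pseudocount))|`, the insulation
#' statistic for one adjacent pair; symmetric in its arguments. Vectorized.
#'
#' @param left_rpm,right_rpm Promoter expression of the two members (RPM).
#' @param pseudocount Added to both members (default 0.1 RPM).
#' @return Non-negative numeric vector.
#' @export
pair_abs_log2fc <- function(left_rpm, right_rpm, pseudocount = 0.1) {
  abs(log2((left_rpm + pseudocount) / (right_rpm + pseudocount)))
}

#' Per-genotype pair fold-change table
#'
#' Attaches `fc_<genotype>` columns (absolute promoter log2 differences) to
#' a pair table.
#'
#' @param pairs Pair `data.frame` from [find_flanked_pairs()].
#' @param quants Quantification `data.frame`.
#' @param genotypes Genotypes to evaluate; defaults to every genotype with
#'   a `promoter_rpm_*` column.
#' @param pseudocount Pseudocount in RPM (default 0.1).
#' @param metric `"promoter"` (default) or `"body"` expression.
#' @return The pair `data.frame` with added `fc_*` columns.
#' @export
pair_fc_table <- function(pairs, quants, genotypes = NULL, pseudocount = 0.1,
                          metric = c("promoter", "body")) {
  metric <- match.arg(metric)
  prefix <- if (metric == "promoter") "promoter_rpm_" else "body_rpm_"
  if (is.null(genotypes)) {
    genotypes <- sub(prefix, "", grep(paste0("^", prefix), names(quants),
                                      value = TRUE))
  }
  li <- match(pairs$left_id, quants$id)
  ri <- match(pairs$right_id, quants$id)
  for (g in genotypes) {
    col <- paste0(prefix, g)
    if (!col %in% names(quants)) stopf("no %s expression for genotype '%s'", metric, g)
    pairs[[paste0("fc_", g)]] <-
      pair_abs_log2fc(quants[[col]][li], quants[[col]][ri], pseudocount)
  }
  pairs
}

#' Insulation contrast between wild type and mutants
#'
#' Pairs are stratified by their wild-type absolute log2 difference at
#' `fourfold_split` (default 2 in log2, i.e. fourfold). Within each
#' (mutant, configuration, stratum) cell a two-tailed t-test compares the
#' wild-type and mutant absolute log2 differences; p-values are
#' Bonferroni-adjusted by `family_size` (default: number of mutants times
#' number of configurations). Loss of insulation shows up as a positive
#' mean reduction with small adjusted p in the `>fourfold` stratum.
#'
#' @param fc Pair `data.frame` with `configuration` and `fc_*` columns
#'   (see [pair_fc_table()]).
#' @param wt Name of the reference genotype column (default `"wt"`).
#' @param mutants Mutant genotype names; defaults to all `fc_*` columns
#'   except the reference.
#' @param fourfold_split Stratification threshold on the wt statistic, in
#'   log2 units (default 2).
#' @param paired Use a paired t-test (the same pairs are measured in both
#'   genotypes); default `FALSE` (Welch).
#' @param family_size Bonferroni family size; `NULL` for the default.
#' @return `data.frame` with one row per (mutant, configuration, stratum):
#'   sample size, means, `mean_reduction` (wt minus mutant), `p`, `p_adj`,
#'   and `testable`.
#' @export
insulation_contrast <- function(fc, wt = "wt", mutants = NULL,
                                fourfold_split = 2, paired = FALSE,
                                family_size = NULL) {
  wt_col <- paste0("fc_", wt)
  if (!wt_col %in% names(fc)) stopf("no fc column for reference '%s'", wt)
  if (is.null(mutants)) {
    mutants <- setdiff(sub("^fc_", "", grep("^fc_", names(fc), value = TRUE)), wt)
  }
  configs <- sort(unique(fc$configuration))
  family <- family_size %||% (length(mutants) * length(configs))
  strata <- c(">fourfold", "<=fourfold")
  res <- list()
  for (m in mutants) {
    m_col <- paste0("fc_", m)
    if (!m_col %in% names(fc)) stopf("no fc column for mutant '%s'", m)
    for (cf in configs) {
      for (s in strata) {
        sel <- fc$configuration == cf &
          (if (s == ">fourfold") fc[[wt_col]] > fourfold_split
           else fc[[wt_col]] <= fourfold_split)
        x <- fc[[wt_col]][sel]; y <- fc[[m_col]][sel]
        testable <- sum(sel) >= 2 && (stats::sd(x) > 0 || stats::sd(y) > 0)
        p <- NA_real_
        if (testable) {
          p <- stats::t.test(x, y, paired = paired,
                             alternative = "two.sided")$p.value
        }
        res[[length(res) + 1L]] <- data.frame(
          mutant = m, configuration = cf, stratum = s, n = sum(sel),
          mean_wt = if (sum(sel)) mean(x) else NA_real_,
          mean_mutant = if (sum(sel)) mean(y) else NA_real_,
          mean_reduction = if (sum(sel)) mean(x) - mean(y) else NA_real_,
          p = p, p_adj = if (is.na(p)) NA_real_ else min(1, family * p),
          testable = testable, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  attr(out, "family_size") <- family
  out
}

#' Monte-Carlo placement null for the insulation statistic
#'
#' Places the same number of regions with the same lengths as the observed
#' peaks uniformly at random on the same chromosomes, recomputes the
#' flanked adjacent pairs and their absolute log2 differences, and compares
#' the per-iteration summary (mean, or median) with the observed one. The
#' empirical p-value per genotype is the fraction of iterations whose
#' random summary exceeds the observed summary. An iteration yielding no
#' pairs is redrawn once and, if still empty, counted as non-exceeding with
#' a warning.
#'
#' @param pairs_fc Observed pair table with `fc_*` columns.
#' @param peaks Observed peak `data.frame` (provides lengths/chromosomes).
#' @param quants Quantification `data.frame` (retained promoters and their
#'   per-genotype expression).
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param genotypes Genotypes to evaluate; defaults to all `fc_*` columns.
#' @param iterations Number of random placements (default 2000).
#' @param seed Integer seed; results are bit-reproducible given the seed.
#' @param summary_fun `"mean"` (default) or `"median"`.
#' @param pseudocount Pseudocount in RPM for the pair statistic.
#' @param metric `"promoter"` or `"body"` expression.
#' @return `data.frame` with one row per genotype: `observed`, `p`,
#'   `iterations`.
#' @export
montecarlo_null <- function(pairs_fc, peaks, quants, seqlengths,
                            genotypes = NULL, iterations = 2000, seed = 1,
                            summary_fun = c("mean", "median"),
                            pseudocount = 0.1,
                            metric = c("promoter", "body")) {
  summary_fun <- match.arg(summary_fun)
  metric <- match.arg(metric)
  sfun <- if (summary_fun == "mean") mean else stats::median
  if (iterations < 1) stopf("iterations must be >= 1")
  if (is.null(genotypes)) {
    genotypes <- sub("^fc_", "", grep("^fc_", names(pairs_fc), value = TRUE))
  }
  prefix <- if (metric == "promoter") "promoter_rpm_" else "body_rpm_"
  set.seed(as.integer(seed))
  lookup <- flank_lookup(quants)
  widths <- peaks$end - peaks$start
  off <- peaks$summit - peaks$start
  chrom <- peaks$chrom
  maxstart <- as.numeric(seqlengths[chrom]) - widths
  if (any(is.na(maxstart) | maxstart < 0))
    stopf("peaks longer than their chromosome or on unknown chromosomes")

  observed <- vapply(genotypes, function(g) sfun(pairs_fc[[paste0("fc_", g)]]),
                     numeric(1))
  rpm <- lapply(stats::setNames(genotypes, genotypes), function(g) {
    stats::setNames(quants[[paste0(prefix, g)]], quants$id)
  })

  iter_summary <- function() {
    starts <- floor(stats::runif(length(widths)) * (maxstart + 1))
    summits <- as.integer(starts) + off
    li <- character(0); ri <- character(0)
    for (ch in unique(chrom)) {
      q <- lookup[[ch]]
      if (is.null(q) || nrow(q) < 2L) next
      s <- summits[chrom == ch]
      fi <- flank_indices(q, s)
      ok <- !is.na(fi$left) & !is.na(fi$right)
      li <- c(li, q$id[fi$left[ok]]); ri <- c(ri, q$id[fi$right[ok]])
    }
    if (!length(li)) return(NULL)
    keep <- !duplicated(paste(li, ri))
    li <- li[keep]; ri <- ri[keep]
    vapply(genotypes, function(g)
      sfun(pair_abs_log2fc(rpm[[g]][li], rpm[[g]][ri], pseudocount)),
      numeric(1))
  }

  exceed <- stats::setNames(numeric(length(genotypes)), genotypes)
  n_empty <- 0L
  for (it in seq_len(iterations)) {
    s <- iter_summary()
    if (is.null(s)) s <- iter_summary()
    if (is.null(s)) { n_empty <- n_empty + 1L; next }
    exceed <- exceed + as.numeric(s[genotypes] > observed)
  }
  if (n_empty > 0)
    warnf("%d iteration(s) yielded no pairs even after redraw; counted as non-exceeding",
          n_empty)
  data.frame(genotype = genotypes, observed = unname(observed),
             p = unname(exceed) / iterations, iterations = iterations,
             stringsAsFactors = FALSE, row.names = NULL)
}
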
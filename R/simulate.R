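#' Simulation configuration
#'
#' Parameterizes the synthetic data generator that emulates the study
#' design: motif-anchored insulator binding sites with controlled
#' symmetric/asymmetric strand profiles, four-factor peak sets with
#' designed co-occupancy and genotype dependency, and adjacent
#' transcript pairs whose expression difference collapses when the
#' separating site is lost.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bases.
#' @param n_transcripts Number of background (non-paired) transcripts.
#' @param n_insulated_pairs Adjacent pairs *per configuration class*
#'   (convergent, divergent, tandem), each with a separating binding site.
#' @param insulated_fraction Fraction of pairs whose separating site is
#'   functional (truth label `insulated`); non-insulated pairs keep their
#'   expression difference in mutants up to noise (default 1).
#' @param wt_logfc_mean,wt_logfc_sd Wild-type pair |log2 expression
#'   difference| is drawn as `|N(mean, sd)|`.
#' @param mutant_shrink Multiplier in `[0, 1]` applied to an insulated
#'   pair's log2 difference in a loss-of-insulation genotype.
#' @param shrink_min_wt_lfc Insulation loss is applied only to pairs whose
#'   wild-type |log2FC| exceeds this threshold (default 0: all insulated
#'   pairs shrink).
#' @param noise_sd SD of the Gaussian noise added to mutant latent log2
#'   differences and to non-insulated expression.
#' @param nexus_depth ChIP-nexus reads generated per binding site.
#' @param strand_bias Probability in `[0.5, 1]` that a read from an
#'   asymmetric-mode site falls on the factor's preferred strand.
#' @param duplicate_rate Fraction of per-site reads that are exact
#'   molecular duplicates of another read.
#' @param background_rate Background ChIP-nexus reads per kilobase of genome.
#' @param motif_score_coupling Logistic slope linking a site's peak score
#'   to its probability of carrying a motif (0 = no coupling, flat 0.5).
#' @param baseline_log2_mean,baseline_log2_sd Log-normal latent expression
#'   baseline (log2 scale) per transcript.
#' @param min_gap Minimum intergenic gap in bases so promoter windows of
#'   distinct units never collide.
#' @param seed Integer seed; identical configurations give bit-identical
#'   output bundles.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2, chrom_length = 300000L,
                       n_transcripts = 20, n_insulated_pairs = 8,
                       insulated_fraction = 1,
                       wt_logfc_mean = 3.2, wt_logfc_sd = 0.8,
                       mutant_shrink = 0.5, shrink_min_wt_lfc = 0,
                       noise_sd = 0.3, nexus_depth = 500,
                       strand_bias = 0.95, duplicate_rate = 0.1,
                       background_rate = 5, motif_score_coupling = 1,
                       baseline_log2_mean = 6, baseline_log2_sd = 1,
                       min_gap = 2000L, seed = 1L) {
  assert_scalar_num(n_chromosomes, "n_chromosomes", min = 1)
  assert_scalar_num(chrom_length, "chrom_length", min = 1000)
  assert_scalar_num(n_transcripts, "n_transcripts", min = 0)
  assert_scalar_num(n_insulated_pairs, "n_insulated_pairs", min = 0)
  assert_scalar_num(insulated_fraction, "insulated_fraction", min = 0, max = 1)
  assert_scalar_num(mutant_shrink, "mutant_shrink", min = 0, max = 1)
  assert_scalar_num(noise_sd, "noise_sd", min = 0)
  assert_scalar_num(nexus_depth, "nexus_depth", min = 0)
  assert_scalar_num(strand_bias, "strand_bias", min = 0.5, max = 1)
  assert_scalar_num(duplicate_rate, "duplicate_rate", min = 0, max = 1)
  assert_scalar_num(background_rate, "background_rate", min = 0)
  assert_scalar_num(min_gap, "min_gap", min = 400)
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_transcripts = as.integer(n_transcripts),
              n_insulated_pairs = as.integer(n_insulated_pairs),
              insulated_fraction = insulated_fraction,
              wt_logfc_mean = wt_logfc_mean, wt_logfc_sd = wt_logfc_sd,
              mutant_shrink = mutant_shrink,
              shrink_min_wt_lfc = shrink_min_wt_lfc,
              noise_sd = noise_sd, nexus_depth = as.integer(nexus_depth),
              strand_bias = strand_bias, duplicate_rate = duplicate_rate,
              background_rate = background_rate,
              motif_score_coupling = motif_score_coupling,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              min_gap = as.integer(min_gap), seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

SIM_GENOTYPES <- c("wt", "elba1", "elba2", "elba3", "insv")
SIM_FACTORS <- c("elba1", "elba2", "elba3", "insv")
SYMMETRIC_SITE <- "TCCAATTGGA"
ASYMMETRIC_SITE <- "CCAATAAG"
FIXED_BARCODE <- "CTGAC"

random_sequence <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

embed_motif <- function(genome, chrom, start, motif) {
  # 0-based start
  substr(genome[[chrom]], start + 1L, start + nchar(motif)) <- motif
  genome
}

#' Simulate a genome with transcripts and insulator sites
#'
#' Lays out non-overlapping, strand-labeled transcription units on random
#' sequence. For every insulated pair (one per requested configuration
#' class: convergent, divergent, tandem) a binding site with an embedded
#' consensus motif -- the palindromic symmetric site or the asymmetric
#' `CCAATAAG`, per the drawn truth label -- is placed strictly between the
#' two promoters.
#'
#' @param config A `sim_config`.
#' @return A list of class `sim_bundle` with elements `genome` (named
#'   character vector), `seqlengths`, `transcripts`, `sites`, and
#'   `truth$pairs`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genome"))
  classes <- c("convergent", "divergent", "tandem")
  units <- c(rep(classes, each = config$n_insulated_pairs),
             rep("single", config$n_transcripts))
  if (length(units)) units <- sample(units)

  tx_rows <- list(); site_rows <- list(); pair_rows <- list()
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  chrom_idx <- 1L
  cursor <- config$min_gap
  tx_i <- 0L; pair_i <- 0L; site_i <- 0L

  for (u in units) {
    L1 <- sample(1000:3000, 1)
    if (u == "single") {
      width <- L1
    } else {
      L2 <- sample(1000:3000, 1)
      inner <- sample(1800:2400, 1)
      width <- L1 + inner + L2
    }
    while (cursor + width + config$min_gap > config$chrom_length) {
      chrom_idx <- chrom_idx + 1L
      cursor <- config$min_gap
      if (chrom_idx > config$n_chromosomes) {
        stopf("chromosomes too short: need at least %d more bases to place all units",
              width + 2L * config$min_gap)
      }
    }
    ch <- chrom_names[chrom_idx]
    if (u == "single") {
      tx_i <- tx_i + 1L
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        chrom = ch, start = cursor, end = cursor + L1,
        id = sprintf("tx_%03d", tx_i),
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
    } else {
      pair_i <- pair_i + 1L; site_i <- site_i + 1L
      strands <- switch(u,
        convergent = c("+", "-"),
        divergent = c("-", "+"),
        tandem = rep(sample(c("+", "-"), 1), 2))
      aL <- cursor; bL <- cursor + L1 + inner
      left_id <- sprintf("tx_%03d", tx_i + 1L)
      right_id <- sprintf("tx_%03d", tx_i + 2L)
      tx_i <- tx_i + 2L
      tx_rows[[length(tx_rows) + 1L]] <- data.frame(
        chrom = ch, start = c(aL, bL), end = c(aL + L1, bL + L2),
        id = c(left_id, right_id), strand = strands, stringsAsFactors = FALSE)
      motif_class <- sample(c("symmetric", "asymmetric"), 1)
      motif <- if (motif_class == "symmetric") SYMMETRIC_SITE else ASYMMETRIC_SITE
      mstart <- aL + L1 + inner %/% 2L - nchar(motif) %/% 2L
      site_id <- sprintf("site_%03d", site_i)
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        site_id = site_id, chrom = ch,
        summit = mstart + nchar(motif) %/% 2L,
        motif_start = mstart, motif_class = motif_class,
        pair_id = sprintf("pair_%03d", pair_i), stringsAsFactors = FALSE)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        pair_id = sprintf("pair_%03d", pair_i), chrom = ch,
        left_id = left_id, right_id = right_id, site_id = site_id,
        configuration = u,
        insulated = stats::runif(1) < config$insulated_fraction,
        stringsAsFactors = FALSE)
    }
    cursor <- cursor + width + config$min_gap + sample(0:500, 1)
  }

  empty_tx <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), id = character(0),
                         strand = character(0), stringsAsFactors = FALSE)
  tx <- if (length(tx_rows)) do.call(rbind, tx_rows) else empty_tx
  if (nrow(tx)) {
    tx <- tx[order(tx$chrom, tx$start), , drop = FALSE]
    tx <- transcript_table(tx$chrom, tx$start, tx$end, tx$id, tx$strand)
  } else tx$tss <- integer(0)
  sites <- if (length(site_rows)) do.call(rbind, c(site_rows, make.row.names = FALSE))
           else data.frame(site_id = character(0), chrom = character(0),
                           summit = integer(0), motif_start = integer(0),
                           motif_class = character(0), pair_id = character(0),
                           stringsAsFactors = FALSE)
  pairs <- if (length(pair_rows)) do.call(rbind, c(pair_rows, make.row.names = FALSE))
           else data.frame(pair_id = character(0), chrom = character(0),
                           left_id = character(0), right_id = character(0),
                           site_id = character(0), configuration = character(0),
                           insulated = logical(0), stringsAsFactors = FALSE)

  genome <- vapply(chrom_names, function(ch) random_sequence(config$chrom_length),
                   character(1))
  for (i in seq_len(nrow(sites))) {
    motif <- if (sites$motif_class[i] == "symmetric") SYMMETRIC_SITE else ASYMMETRIC_SITE
    genome <- embed_motif(genome, sites$chrom[i], sites$motif_start[i], motif)
  }

  bundle <- list(config = config, genome = genome,
                 seqlengths = stats::setNames(rep(config$chrom_length,
                                                  config$n_chromosomes), chrom_names),
                 transcripts = tx, sites = sites,
                 truth = list(pairs = pairs))
  class(bundle) <- "sim_bundle"
  bundle
}

#' Simulate four-factor peak sets with designed co-occupancy
#'
#' Realizes a co-occupancy design over binding sites: the pair-separating
#' insulator sites are bound by all four factors; additional sites are
#' assigned to the co-occupancy categories by the design proportions, with
#' any unassigned remainder also bound by all four. Peak scores follow a
#' decreasing (exponential) distribution; motif presence per site is drawn
#' with probability `plogis(motif_score_coupling * z)` of the standardized
#' score, and present motifs are embedded into the genome at the summit.
#' Mutant peak sets realize the genotype dependency of the heterotrimer:
#' Elba1/Elba2 peaks vanish in any `elba*` mutant; Elba3 retains a designed
#' fraction of its sites in `elba1`/`elba2` mutants (the Elba1/2-independent
#' sites); each factor vanishes in its own mutant; Insv is unaffected by
#' `elba*` mutants and vice versa.
#'
#' @param bundle A `sim_bundle` from [simulate_genome()].
#' @param config The `sim_config`.
#' @param design List with `proportions` (named fractions over the five
#'   co-occupancy categories, summing to at most 1), `n_extra_sites`,
#'   `frac_promoter_sites` (fraction of extra sites placed promoter-proximal
#'   to a transcript), `elba3_independent_frac`, and `summit_jitter`.
#' @return The bundle with `peak_sets` (`factor -> genotype -> peaks`) and
#'   `truth$peaks` added; the genome gains embedded motifs.
#' @export
simulate_peak_sets <- function(bundle, config, design = list()) {
  stopifnot(inherits(bundle, "sim_bundle"))
  d <- utils::modifyList(list(
    proportions = c(all_four = 0.4, elba_not_insv = 0.2,
                    elba3_and_insv_only = 0.15, elba3_unique = 0.15,
                    insv_unique = 0.1),
    n_extra_sites = 60, frac_promoter_sites = 0.4,
    elba3_independent_frac = 0.5, summit_jitter = 5), design)
  if (sum(d$proportions) > 1 + 1e-9)
    stopf("co-occupancy proportions sum to %.3f > 1", sum(d$proportions))
  set.seed(stage_seed(config$seed, "peaks"))

  # site pool: insulator (pair) sites are all-four; extra sites by design
  n_extra <- d$n_extra_sites
  cats <- names(d$proportions)
  n_per <- floor(d$proportions * n_extra)
  extra_cat <- rep(cats, times = n_per)
  if (length(extra_cat) < n_extra)
    extra_cat <- c(extra_cat, rep("all_four", n_extra - length(extra_cat)))
  extra_cat <- if (n_extra) sample(extra_cat) else character(0)

  # keep sites >= 500 bp apart so summit matching across factors is 1-1
  place_extra <- function(n) {
    if (!n) return(data.frame(chrom = character(0), summit = integer(0)))
    taken <- split(bundle$sites$summit, bundle$sites$chrom)
    near_tss <- stats::runif(n) < d$frac_promoter_sites & nrow(bundle$transcripts) > 0
    chrom <- character(n); summit <- integer(n)
    for (i in seq_len(n)) {
      for (try in 1:100) {
        if (near_tss[i]) {
          j <- sample(nrow(bundle$transcripts), 1)
          ch <- bundle$transcripts$chrom[j]
          s <- bundle$transcripts$tss[j] + sample(-100:100, 1)
        } else {
          ch <- sample(names(bundle$seqlengths), 1)
          s <- sample(200:(bundle$seqlengths[[ch]] - 200L), 1)
        }
        if (!length(taken[[ch]]) || min(abs(taken[[ch]] - s)) >= 500L) break
      }
      chrom[i] <- ch; summit[i] <- s
      taken[[ch]] <- c(taken[[ch]], s)
    }
    data.frame(chrom = chrom, summit = summit, stringsAsFactors = FALSE)
  }
  extra <- place_extra(n_extra)

  n_pair <- nrow(bundle$sites)
  site_tab <- data.frame(
    site_id = c(bundle$sites$site_id,
                sprintf("xsite_%03d", seq_len(n_extra))),
    chrom = c(bundle$sites$chrom, extra$chrom),
    summit = c(bundle$sites$summit, extra$summit),
    category = c(rep("all_four", n_pair), extra_cat),
    pair_site = c(rep(TRUE, n_pair), rep(FALSE, n_extra)),
    stringsAsFactors = FALSE
  )
  site_tab$score <- 1 + stats::rexp(nrow(site_tab), rate = 0.05)
  z <- as.numeric(scale(site_tab$score))
  if (all(is.na(z))) z <- rep(0, nrow(site_tab))
  p_motif <- stats::plogis(config$motif_score_coupling * z)
  site_tab$motif_class <- c(bundle$sites$motif_class,
                            sample(c("symmetric", "asymmetric"), n_extra,
                                   replace = TRUE))
  site_tab$motif <- site_tab$pair_site | (stats::runif(nrow(site_tab)) < p_motif)
  site_tab$elba12_independent <- stats::runif(nrow(site_tab)) < d$elba3_independent_frac

  genome <- bundle$genome
  for (i in which(site_tab$motif & !site_tab$pair_site)) {
    motif <- if (site_tab$motif_class[i] == "symmetric") SYMMETRIC_SITE else ASYMMETRIC_SITE
    start <- site_tab$summit[i] - nchar(motif) %/% 2L
    genome <- embed_motif(genome, site_tab$chrom[i], start, motif)
  }

  member <- list(
    all_four = SIM_FACTORS,
    elba_not_insv = c("elba1", "elba2", "elba3"),
    elba3_and_insv_only = c("elba3", "insv"),
    elba3_unique = "elba3",
    insv_unique = "insv"
  )
  present <- vapply(SIM_FACTORS, function(f)
    vapply(site_tab$category, function(cat) f %in% member[[cat]], logical(1)),
    logical(nrow(site_tab)))
  if (is.null(dim(present))) present <- matrix(present, nrow = nrow(site_tab),
                                               dimnames = list(NULL, SIM_FACTORS))

  mk_peaks <- function(f, rows, jitter) {
    if (!length(rows)) {
      return(peak_table(character(0), integer(0), integer(0),
                        name = character(0), score = numeric(0),
                        strand = character(0), summit = integer(0)))
    }
    s <- site_tab$summit[rows] + sample(seq.int(-jitter, jitter), length(rows),
                                        replace = TRUE)
    peak_table(site_tab$chrom[rows], pmax(0L, s - 150L), s + 150L,
               name = paste0(f, "_", site_tab$site_id[rows]),
               score = site_tab$score[rows] * stats::runif(length(rows), 0.8, 1.2),
               strand = "*", summit = s)
  }

  retained <- function(f, genotype) {
    rows <- which(present[, f])
    keep <- switch(genotype,
      wt = rep(TRUE, length(rows)),
      elba1 = ,
      elba2 = if (f %in% c("elba1", "elba2")) rep(FALSE, length(rows))
              else if (f == "elba3") site_tab$elba12_independent[rows]
              else rep(TRUE, length(rows)),
      elba3 = if (f %in% c("elba1", "elba2", "elba3")) rep(FALSE, length(rows))
              else rep(TRUE, length(rows)),
      insv = if (f == "insv") rep(FALSE, length(rows)) else rep(TRUE, length(rows)),
      stopf("unknown genotype '%s'", genotype))
    rows[keep]
  }

  peak_sets <- lapply(stats::setNames(SIM_FACTORS, SIM_FACTORS), function(f) {
    lapply(stats::setNames(SIM_GENOTYPES, SIM_GENOTYPES), function(g) {
      mk_peaks(f, retained(f, g), if (g == "wt") d$summit_jitter else 10L)
    })
  })

  bundle$genome <- genome
  bundle$peak_sets <- peak_sets
  bundle$truth$peaks <- site_tab
  bundle
}

#' Simulate per-genotype promoter and gene-body read counts
#'
#' Latent log2 expression per transcript is log-normal; each insulated
#' pair's members are offset symmetrically so the wild-type pair
#' |log2 difference| equals the drawn `|N(wt_logfc_mean, wt_logfc_sd)|`
#' value. In a loss-of-insulation genotype (any non-wt genotype here),
#' an insulated pair's log2 difference with wild-type value above
#' `shrink_min_wt_lfc` is multiplied by `mutant_shrink` plus
#' `N(0, noise_sd)` noise, truncated at 0; other pairs and singleton
#' transcripts change only by noise. Observed counts are Poisson draws
#' from the latent expression.
#'
#' @param bundle A `sim_bundle` (needs `truth$pairs`).
#' @param config The `sim_config`.
#' @param genotypes Character vector of genotype names; must contain
#'   `"wt"` and only names from the known roster.
#' @return The bundle with `expression` (`counts` long `data.frame`:
#'   `transcript_id`, `genotype`, `promoter_count`, `body_count`) and
#'   `truth$latents` / `truth$pair_lfc` added.
#' @export
simulate_expression <- function(bundle, config, genotypes = SIM_GENOTYPES) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (!"wt" %in% genotypes) stopf("genotypes must include 'wt'")
  unknown <- setdiff(genotypes, SIM_GENOTYPES)
  if (length(unknown)) stopf("unknown genotype name(s): %s",
                             paste(unknown, collapse = ", "))
  set.seed(stage_seed(config$seed, "expression"))
  tx <- bundle$transcripts
  pairs <- bundle$truth$pairs
  n <- nrow(tx)
  baseline <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  names(baseline) <- tx$id

  wt_lfc <- abs(stats::rnorm(nrow(pairs), config$wt_logfc_mean, config$wt_logfc_sd))
  lfc_sign <- sample(c(-1, 1), nrow(pairs), replace = TRUE)
  pair_mid <- stats::rnorm(nrow(pairs), config$baseline_log2_mean,
                           config$baseline_log2_sd)

  latents <- list(); lfc_rows <- list(); count_rows <- list()
  for (g in genotypes) {
    lat <- baseline
    if (g != "wt") lat <- lat + stats::rnorm(n, 0, config$noise_sd)
    lfc_g <- wt_lfc
    if (nrow(pairs)) {
      if (g != "wt") {
        shrinkable <- pairs$insulated & wt_lfc > config$shrink_min_wt_lfc
        noise <- stats::rnorm(nrow(pairs), 0, config$noise_sd)
        lfc_g <- ifelse(shrinkable,
                        pmax(0, wt_lfc * config$mutant_shrink + noise),
                        pmax(0, wt_lfc + noise))
      }
      lat[pairs$left_id] <- pair_mid + lfc_sign * lfc_g / 2
      lat[pairs$right_id] <- pair_mid - lfc_sign * lfc_g / 2
      lfc_rows[[g]] <- data.frame(pair_id = pairs$pair_id, genotype = g,
                                  true_abs_lfc = lfc_g, stringsAsFactors = FALSE)
    }
    latents[[g]] <- data.frame(transcript_id = tx$id, genotype = g,
                               latent_log2 = unname(lat), stringsAsFactors = FALSE)
    body_len <- pmax(0L, (tx$end - tx$start) - 400L)
    count_rows[[g]] <- data.frame(
      transcript_id = tx$id, genotype = g,
      promoter_count = stats::rpois(n, 2^lat),
      body_count = stats::rpois(n, 2^lat * body_len / 200 * 0.5),
      stringsAsFactors = FALSE)
  }
  bundle$expression <- do.call(rbind, c(count_rows, make.row.names = FALSE))
  bundle$truth$latents <- do.call(rbind, c(latents, make.row.names = FALSE))
  bundle$truth$pair_lfc <- if (length(lfc_rows))
    do.call(rbind, c(lfc_rows, make.row.names = FALSE)) else NULL
  bundle
}

#' Simulate ChIP-nexus reads for one factor
#'
#' Generates `nexus_depth` reads per wild-type binding site of the factor.
#' In asymmetric modes a read falls on the preferred strand with
#' probability `strand_bias` (symmetric mode: 50/50); 5' ends sit at the
#' motif flanks (upstream of the summit for `+` reads, downstream for `-`
#' reads), emulating exonuclease stop positions. A `duplicate_rate`
#' fraction of each site's reads are exact molecular duplicates (same
#' position, strand, and random barcode); strand-balanced uniform
#' background reads are added genome-wide at `background_rate` per kb.
#' Site reads are made key-unique by construction so the generator's
#' unique-read count is an exact deduplication oracle.
#'
#' @param bundle A `sim_bundle` with `peak_sets`.
#' @param config The `sim_config`.
#' @param factor One of `elba1`, `elba2`, `elba3`, `insv`.
#' @param mode `"symmetric"`, `"asymmetric_plus"`, or `"asymmetric_minus"`.
#' @return List with `reads` (`data.frame`: `chrom`, `pos`, `strand`,
#'   `length`, `fixed_bc`, `random_bc`) and `truth` (counts: `n_total`,
#'   `n_site_unique`, `n_duplicates`, `n_background`, `n_unique_keys`).
#' @export
simulate_nexus_reads <- function(bundle, config, factor,
                                 mode = c("symmetric", "asymmetric_plus",
                                          "asymmetric_minus")) {
  mode <- match.arg(mode)
  if (is.null(bundle$peak_sets[[factor]]))
    stopf("no peak set for factor '%s'; run simulate_peak_sets first", factor)
  set.seed(stage_seed(config$seed, "nexus") +
             match(factor, SIM_FACTORS) * 7L + match(mode, c(
               "symmetric", "asymmetric_plus", "asymmetric_minus")) * 3L)
  sites <- bundle$peak_sets[[factor]]$wt
  depth <- config$nexus_depth
  n_dup_per <- round(config$duplicate_rate * depth)
  n_u_per <- depth - n_dup_per
  p_plus <- switch(mode, symmetric = 0.5,
                   asymmetric_plus = config$strand_bias,
                   asymmetric_minus = 1 - config$strand_bias)

  rand_bc <- function(k) {
    if (!k) return(character(0))
    apply(matrix(sample(c("A", "C", "G", "T"), 4L * k, replace = TRUE), nrow = k),
          1L, paste, collapse = "")
  }

  site_reads <- list(); dup_reads <- list()
  for (i in seq_len(nrow(sites))) {
    if (n_u_per == 0L) next
    strand <- ifelse(stats::runif(n_u_per) < p_plus, "+", "-")
    off <- sample(3:20, n_u_per, replace = TRUE)
    pos <- ifelse(strand == "+", sites$summit[i] - off, sites$summit[i] + off)
    df <- data.frame(chrom = sites$chrom[i], pos = as.integer(pos),
                     strand = strand,
                     length = sample(25:40, n_u_per, replace = TRUE),
                     fixed_bc = FIXED_BARCODE, random_bc = rand_bc(n_u_per),
                     stringsAsFactors = FALSE)
    # enforce key-uniqueness of the site's molecules
    for (tries in 1:50) {
      key <- paste(df$pos, df$strand, df$random_bc)
      dupd <- duplicated(key)
      if (!any(dupd)) break
      df$random_bc[dupd] <- rand_bc(sum(dupd))
    }
    site_reads[[i]] <- df
    if (n_dup_per > 0L)
      dup_reads[[i]] <- df[sample(n_u_per, n_dup_per, replace = TRUE), , drop = FALSE]
  }
  site_df <- if (length(site_reads)) do.call(rbind, c(site_reads, make.row.names = FALSE)) else NULL
  dup_df <- if (length(dup_reads)) do.call(rbind, c(dup_reads, make.row.names = FALSE)) else NULL

  genome_kb <- sum(as.numeric(bundle$seqlengths)) / 1000
  n_bg <- round(config$background_rate * genome_kb)
  bg_df <- NULL
  if (n_bg > 0) {
    chrom <- sample(names(bundle$seqlengths), n_bg, replace = TRUE,
                    prob = as.numeric(bundle$seqlengths))
    pos <- vapply(chrom, function(ch) sample.int(bundle$seqlengths[[ch]], 1) - 1L,
                  integer(1))
    bg_df <- data.frame(chrom = chrom, pos = as.integer(pos),
                        strand = sample(c("+", "-"), n_bg, replace = TRUE),
                        length = sample(25:40, n_bg, replace = TRUE),
                        fixed_bc = FIXED_BARCODE, random_bc = rand_bc(n_bg),
                        stringsAsFactors = FALSE)
  }
  parts <- Filter(Negate(is.null), list(site_df, dup_df, bg_df))
  reads <- if (length(parts)) do.call(rbind, c(parts, make.row.names = FALSE)) else NULL
  if (is.null(reads))
    reads <- data.frame(chrom = character(0), pos = integer(0),
                        strand = character(0), length = integer(0),
                        fixed_bc = character(0), random_bc = character(0),
                        stringsAsFactors = FALSE)
  key <- paste(reads$chrom, reads$pos, reads$strand, reads$random_bc)
  list(reads = reads,
       truth = list(
         factor = factor, mode = mode,
         n_total = nrow(reads),
         n_site_unique = if (is.null(site_df)) 0L else nrow(site_df),
         n_duplicates = if (is.null(dup_df)) 0L else nrow(dup_df),
         n_background = if (is.null(bg_df)) 0L else nrow(bg_df),
         n_unique_keys = length(unique(key))))
}

#' Build stranded PRO-seq-like coverage from simulated counts
#'
#' Distributes each transcript's promoter reads over its promoter window
#' (TSS to +200, strand-aware) and its body reads over the body window
#' (+400 to the transcript end) on the transcript's strand, by multinomial
#' sampling.
#'
#' @param bundle A `sim_bundle` with `expression`.
#' @param genotype Genotype whose counts are converted.
#' @return A raw-count `stranded_coverage`.
#' @export
simulate_proseq_coverage <- function(bundle, genotype) {
  if (is.null(bundle$expression)) stopf("run simulate_expression first")
  cnt <- bundle$expression[bundle$expression$genotype == genotype, , drop = FALSE]
  if (!nrow(cnt)) stopf("unknown genotype '%s' in expression table", genotype)
  set.seed(stage_seed(bundle$config$seed, "proseq") +
             match(genotype, SIM_GENOTYPES))
  tx <- bundle$transcripts
  cnt <- cnt[match(tx$id, cnt$transcript_id), ]
  pos_list <- list(); str_list <- list(); chr_list <- list()
  for (i in seq_len(nrow(tx))) {
    dir <- if (tx$strand[i] == "+") 1L else -1L
    prom <- tx$tss[i] + dir * (0:199)
    len <- tx$end[i] - tx$start[i]
    body <- if (len > 400L) tx$tss[i] + dir * (400:(len - 1L)) else integer(0)
    np <- cnt$promoter_count[i]
    nb <- if (length(body)) cnt$body_count[i] else 0L
    p <- c(if (np > 0) sample(prom, np, replace = TRUE),
           if (nb > 0) sample(body, nb, replace = TRUE))
    if (length(p)) {
      pos_list[[i]] <- p
      str_list[[i]] <- rep(tx$strand[i], length(p))
      chr_list[[i]] <- rep(tx$chrom[i], length(p))
    }
  }
  reads <- data.frame(chrom = unlist(chr_list) %||% character(0),
                      pos = as.integer(unlist(pos_list) %||% integer(0)),
                      strand = unlist(str_list) %||% character(0),
                      stringsAsFactors = FALSE)
  coverage_from_reads(reads, bundle$seqlengths)
}

#' Simulate RNA-seq-like gene counts with planted de-repression
#'
#' Wild-type counts are Poisson draws from the latent baseline; mutant
#' counts receive a log2 de-repression effect that scales with the bound
#' peak's score for motif-carrying targets (`effect * score/max_score`),
#' a quarter of that for bound targets without motif, and zero for
#' unbound genes -- the ordering the three-group contrast is designed to
#' detect.
#'
#' @param bundle A `sim_bundle`.
#' @param annotation Binding annotation from [annotate_targets()], one row
#'   per transcript.
#' @param effect Maximum planted log2 fold change (default 1.5).
#' @return `data.frame` with `gene`, `wt_count`, `mut_count`, and the
#'   planted `true_log2fc`.
#' @export
simulate_rnaseq_counts <- function(bundle, annotation, effect = 1.5) {
  set.seed(stage_seed(bundle$config$seed, "rnaseq"))
  n <- nrow(annotation)
  base <- 2^stats::rnorm(n, bundle$config$baseline_log2_mean,
                         bundle$config$baseline_log2_sd)
  smax <- max(c(annotation$score, 1), na.rm = TRUE)
  rel <- ifelse(is.na(annotation$score), 0, annotation$score / smax)
  planted <- ifelse(!annotation$bound, 0,
                    ifelse(annotation$motif, effect * rel, 0.25 * effect * rel))
  data.frame(gene = annotation$gene,
             wt_count = stats::rpois(n, base),
             mut_count = stats::rpois(n, base * 2^planted),
             true_log2fc = planted, stringsAsFactors = FALSE)
}

#' Run the full generator
#'
#' Convenience wrapper chaining [simulate_genome()], [simulate_peak_sets()]
#' and [simulate_expression()].
#'
#' @param config A `sim_config`.
#' @param genotypes Genotype roster passed to [simulate_expression()].
#' @param design Co-occupancy design passed to [simulate_peak_sets()].
#' @return A populated `sim_bundle`.
#' @export
simulate_bundle <- function(config, genotypes = SIM_GENOTYPES, design = list()) {
  bundle <- simulate_genome(config)
  bundle <- simulate_peak_sets(bundle, config, design)
  simulate_expression(bundle, config, genotypes)
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("sim_bundle: %d chromosome(s) x %d bp, %d transcripts, %d insulated pairs\n",
              length(x$genome), x$config$chrom_length, nrow(x$transcripts),
              nrow(x$truth$pairs)))
  invisible(x)
}
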
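tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2, chrom_length = 150000L, n_transcripts = 6,
         n_insulated_pairs = 3, nexus_depth = 200, background_rate = 2),
    list(...))
  do.call(sim_config, args)
}

test_that("identical seeds give byte-identical FASTA and BED outputs", {
  out <- lapply(1:2, function(k) {
    b <- simulate_bundle(tiny_cfg(seed = 7))
    fa <- withr::local_tempfile(fileext = ".fa")
    bed <- withr::local_tempfile(fileext = ".bed")
    write_fasta(b$genome, fa)
    write_transcripts(b$transcripts, bed)
    c(tools::md5sum(fa), tools::md5sum(bed))
  })
  expect_identical(unname(out[[1]]), unname(out[[2]]))
})

test_that("zero insulated pairs still yields transcripts and no sites", {
  b <- simulate_genome(tiny_cfg(n_insulated_pairs = 0, seed = 2))
  expect_equal(nrow(b$sites), 0L)
  expect_equal(nrow(b$truth$pairs), 0L)
  expect_equal(nrow(b$transcripts), 6L)
})

test_that("transcripts are sorted, non-overlapping, and sites sit between promoters", {
  b <- simulate_genome(tiny_cfg(seed = 11))
  tx <- b$transcripts
  for (ch in unique(tx$chrom)) {
    t <- tx[tx$chrom == ch, ]
    expect_true(all(diff(t$start) > 0))
    expect_true(all(t$start[-1] >= t$end[-nrow(t)]))
  }
  # each separating site lies strictly between its pair's two TSSs
  pr <- merge(b$truth$pairs, b$sites, by = c("site_id", "chrom"))
  lt <- tx$tss[match(pr$left_id, tx$id)]
  rt <- tx$tss[match(pr$right_id, tx$id)]
  expect_true(all(pr$summit > lt & pr$summit < rt))
  # and carries the labelled motif in the genome sequence
  for (i in seq_len(nrow(b$sites))) {
    motif <- if (b$sites$motif_class[i] == "symmetric") "TCCAATTGGA" else "CCAATAAG"
    seq <- substr(b$genome[[b$sites$chrom[i]]], b$sites$motif_start[i] + 1,
                  b$sites$motif_start[i] + nchar(motif))
    expect_equal(seq, motif)
  }
})

test_that("pair configurations re-classify correctly from strands (oracle)", {
  b <- simulate_genome(tiny_cfg(n_insulated_pairs = 10, n_transcripts = 0,
                                chrom_length = 300000L, seed = 5))
  pairs <- b$truth$pairs
  expect_equal(as.vector(table(pairs$configuration)[c("convergent", "divergent", "tandem")]),
               rep(10L, 3))
  tx <- b$transcripts
  for (i in seq_len(nrow(pairs))) {
    ls <- tx$strand[tx$id == pairs$left_id[i]]
    rs <- tx$strand[tx$id == pairs$right_id[i]]
    oracle <- if (ls == "+" && rs == "-") "convergent"
              else if (ls == "-" && rs == "+") "divergent" else "tandem"
    expect_equal(pairs$configuration[i], oracle)
  }
})

test_that("sizing errors name the deficit when chromosomes are too short", {
  expect_error(simulate_genome(sim_config(n_chromosomes = 1, chrom_length = 20000L,
                                          n_transcripts = 0, n_insulated_pairs = 10,
                                          seed = 1)),
               "more bases")
})

test_that("expression model: shrink and null behave as designed", {
  # shrink 0.5, no noise: mutant latent |log2FC| is exactly half the wt value
  b <- simulate_expression(simulate_genome(tiny_cfg(seed = 3, noise_sd = 0,
                                                    mutant_shrink = 0.5)),
                           tiny_cfg(seed = 3, noise_sd = 0, mutant_shrink = 0.5),
                           genotypes = c("wt", "elba1"))
  lfc <- b$truth$pair_lfc
  wt <- lfc$true_abs_lfc[lfc$genotype == "wt"]
  mu <- lfc$true_abs_lfc[lfc$genotype == "elba1"]
  expect_equal(mu, wt / 2)
  # shrink 1: latent distributions identical up to noise (here exactly)
  cfg1 <- tiny_cfg(seed = 3, noise_sd = 0, mutant_shrink = 1)
  b1 <- simulate_expression(simulate_genome(cfg1), cfg1,
                            genotypes = c("wt", "elba1"))
  l1 <- b1$truth$pair_lfc
  expect_equal(l1$true_abs_lfc[l1$genotype == "elba1"],
               l1$true_abs_lfc[l1$genotype == "wt"])
  # unknown genotype is a configuration error
  expect_error(simulate_expression(b1, cfg1, genotypes = c("wt", "elbaX")),
               "unknown genotype")
  expect_error(simulate_expression(b1, cfg1, genotypes = "elba1"), "wt")
})

test_that("non-insulated pairs change only by noise between genotypes", {
  cfg <- sim_config(n_chromosomes = 8, chrom_length = 1600000L,
                    n_transcripts = 0, n_insulated_pairs = 334,
                    insulated_fraction = 0, noise_sd = 0.3,
                    mutant_shrink = 0.3, seed = 9)
  b <- simulate_expression(simulate_genome(cfg), cfg, genotypes = c("wt", "elba3"))
  lfc <- b$truth$pair_lfc
  n <- sum(lfc$genotype == "wt")
  expect_gte(n, 1000)
  delta <- lfc$true_abs_lfc[lfc$genotype == "elba3"] -
    lfc$true_abs_lfc[lfc$genotype == "wt"]
  # mean change ~ N(0, noise_sd/sqrt(n)); 4-sigma band
  expect_lt(abs(mean(delta)), 4 * 0.3 / sqrt(n))
})

test_that("nexus reads satisfy conservation and the hash-set dedup oracle", {
  cfg <- tiny_cfg(seed = 13, duplicate_rate = 0.3, nexus_depth = 1000,
                  background_rate = 0, n_insulated_pairs = 1, n_transcripts = 0)
  b <- simulate_peak_sets(simulate_genome(cfg), cfg,
                          design = list(n_extra_sites = 0))
  nx <- simulate_nexus_reads(b, cfg, "elba1", "asymmetric_plus")
  tr <- nx$truth
  expect_equal(tr$n_total, tr$n_site_unique + tr$n_duplicates + tr$n_background)
  # duplicate_rate 0.3 at depth 1000: exactly 700 unique molecules per site
  n_sites <- nrow(b$peak_sets$elba1$wt)
  expect_equal(tr$n_site_unique, 700L * n_sites)
  expect_equal(tr$n_duplicates, 300L * n_sites)
  # independent hash-set oracle over (chrom, pos, strand, barcode)
  key <- paste(nx$reads$chrom, nx$reads$pos, nx$reads$strand, nx$reads$random_bc)
  expect_equal(length(unique(key)), tr$n_unique_keys)
  expect_equal(preprocess_reads(nx$reads)$stats[["retained"]], tr$n_unique_keys)
})

test_that("strand bias boundaries behave: 1.0 is one-sided, 0.5 is balanced", {
  cfg <- tiny_cfg(seed = 17, strand_bias = 1, background_rate = 0,
                  duplicate_rate = 0, nexus_depth = 400,
                  n_insulated_pairs = 2, n_transcripts = 0)
  b <- simulate_peak_sets(simulate_genome(cfg), cfg, design = list(n_extra_sites = 0))
  nx <- simulate_nexus_reads(b, cfg, "elba1", "asymmetric_plus")
  expect_true(all(nx$reads$strand == "+"))
  nx0 <- simulate_nexus_reads(b, cfg, "elba2", "symmetric")
  frac_plus <- mean(nx0$reads$strand == "+")
  n <- nrow(nx0$reads)
  expect_lt(abs(frac_plus - 0.5), 4 * sqrt(0.25 / n)) # binomial 4-sigma
  # degenerate depth 0 yields an empty read list
  cfg0 <- tiny_cfg(seed = 17, nexus_depth = 0, background_rate = 0)
  b0 <- simulate_peak_sets(simulate_genome(cfg0), cfg0)
  expect_equal(nrow(simulate_nexus_reads(b0, cfg0, "insv", "symmetric")$reads), 0L)
})

test_that("peak-set co-occupancy design is realized and invalid designs rejected", {
  cfg <- tiny_cfg(seed = 19)
  b <- simulate_genome(cfg)
  expect_error(simulate_peak_sets(b, cfg, design = list(
    proportions = c(all_four = 0.9, elba_not_insv = 0.3))), "sum")
  # degenerate design: every site bound by all four factors
  b4 <- simulate_peak_sets(b, cfg, design = list(
    proportions = c(all_four = 1), n_extra_sites = 40, frac_promoter_sites = 0))
  v <- venn_partition(lapply(b4$peak_sets, `[[`, "wt"), "elba3", max_dist = 50)
  expect_true(all(v$category == "all_four"))
  # truth labels cover every generated site exactly once
  expect_equal(anyDuplicated(b4$truth$peaks$site_id), 0L)
  expect_setequal(b4$truth$peaks$site_id,
                  sub("^elba3_", "", b4$peak_sets$elba3$wt$name))
})

test_that("designed Elba1/2-independent fraction is recovered downstream", {
  cfg <- sim_config(n_chromosomes = 4, chrom_length = 400000L,
                    n_transcripts = 0, n_insulated_pairs = 10, seed = 23)
  b <- simulate_peak_sets(simulate_genome(cfg), cfg, design = list(
    n_extra_sites = 170, frac_promoter_sites = 0, elba3_independent_frac = 0.5))
  dep <- classify_dependency(b$peak_sets$elba3$wt,
                             list(elba1 = b$peak_sets$elba3$elba1,
                                  elba2 = b$peak_sets$elba3$elba2))
  got <- mean(dep$elba12 == "independent")
  truth <- b$truth$peaks
  present <- truth$category %in% c("all_four", "elba_not_insv",
                                   "elba3_and_insv_only", "elba3_unique")
  expect_equal(got, mean(truth$elba12_independent[present]))
  n <- sum(present)
  expect_lt(abs(got - 0.5), 4 * sqrt(0.25 / n))
})
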
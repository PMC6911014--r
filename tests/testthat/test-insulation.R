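make_cov <- function(reads, seqlengths) rpm_normalize(coverage_from_reads(reads, seqlengths))

test_that("promoter and body windows are strand-aware and TPM-filtered", {
  tx <- transcript_table(c("c1", "c1"), c(1000L, 4000L), c(2000L, 5000L),
                         id = c("plus_tx", "minus_tx"), strand = c("+", "-"))
  # plus_tx: promoter [1000,1200), body [1400,2000)
  # minus_tx: TSS 4999, promoter [4800,5000), body [4000,4600)
  reads <- data.frame(
    chrom = "c1",
    pos = c(1100L, 1150L, 1500L, 4900L, 4950L, 4100L),
    strand = c("+", "+", "+", "-", "-", "-"))
  cov <- make_cov(reads, c(c1 = 6000L))
  q <- quantify_promoters(tx, list(wt = cov), tpm_min = 1)
  expect_equal(q$promoter_start, c(1000L, 4800L))
  expect_equal(q$promoter_end, c(1200L, 5000L))
  rpm1 <- 1e6 / 6 # one read in RPM
  expect_equal(q$promoter_rpm_wt, c(2 * rpm1, 2 * rpm1))
  expect_equal(q$body_rpm_wt, c(rpm1, rpm1))
  expect_true(all(q$retained))
  # a zero-coverage transcript gets TPM 0 and is filtered out
  tx3 <- transcript_table("c1", 100L, 700L, id = "silent", strand = "+")
  q3 <- quantify_promoters(rbind(tx, tx3), list(wt = cov))
  expect_equal(q3$promoter_tpm_wt[q3$id == "silent"], 0)
  expect_false(q3$retained[q3$id == "silent"])
  # transcripts shorter than 400 nt have no body window
  short <- transcript_table("c1", 100L, 450L, id = "short", strand = "+")
  expect_warning(qs <- quantify_promoters(short, list(wt = cov)), "body window")
  expect_true(is.na(qs$body_rpm_wt))
})

test_that("flanked-pair detection picks immediate neighbours and deduplicates", {
  q <- data.frame(id = c("g1", "g2", "g3"), chrom = "c1",
                  strand = c("+", "-", "+"), tss = c(1000L, 9000L, 20000L),
                  promoter_rpm_wt = c(8, 2, 5), retained = TRUE,
                  stringsAsFactors = FALSE)
  pk <- peak_table("c1", c(4900, 5900, 15000), c(5100, 6100, 15200),
                   name = c("pkA", "pkB", "pkC"),
                   summit = c(5000, 6000, 15100))
  pairs <- find_flanked_pairs(q, pk)
  # pkA and pkB sit between the same promoters: one pair, leftmost peak kept
  expect_equal(nrow(pairs), 2L)
  expect_equal(pairs$peak[pairs$left_id == "g1"], "pkA")
  expect_equal(pairs$configuration, c("convergent", "divergent"))
  # a peak beyond the outermost promoter is skipped and counted
  pk_edge <- peak_table("c1", c(100, 5000), c(300, 5200), name = c("out", "in"),
                        summit = c(200, 5100))
  pairs2 <- find_flanked_pairs(q, pk_edge)
  expect_equal(nrow(pairs2), 1L)
  expect_equal(attr(pairs2, "n_skipped"), 1L)
})

test_that("configuration labels follow the strand rules and partition pairs", {
  expect_equal(classify_configuration("+", "-"), "convergent")
  expect_equal(classify_configuration("-", "+"), "divergent")
  expect_equal(classify_configuration(c("+", "-"), c("+", "-")),
               c("tandem", "tandem"))
  expect_error(classify_configuration("*", "+"), "strand")
})

test_that("pair statistic is an absolute, symmetric, pseudocounted log ratio", {
  expect_equal(pair_abs_log2fc(8, 2, pseudocount = 0), 2)
  expect_equal(pair_abs_log2fc(2, 8, pseudocount = 0), 2)
  expect_equal(pair_abs_log2fc(5, 5), 0)
  expect_equal(pair_abs_log2fc(0, 0), 0) # guarded by the pseudocount
})

test_that("insulation contrast recovers a planted effect and stays null otherwise", {
  cfg <- sim_config(n_chromosomes = 4, chrom_length = 800000L, n_transcripts = 10,
                    n_insulated_pairs = 25, mutant_shrink = 0.5, noise_sd = 0.3,
                    seed = 61)
  b <- simulate_bundle(cfg, genotypes = c("wt", "elba1"))
  q <- promoter_quants_from_counts(b)
  site_peaks <- b$peak_sets$elba3$wt[
    b$peak_sets$elba3$wt$name %in% paste0("elba3_", b$sites$site_id), ]
  pairs <- find_flanked_pairs(q, site_peaks)
  expect_gt(nrow(pairs), 60) # nearly all 75 designed pairs recovered
  fc <- pair_fc_table(pairs, q)
  ct <- insulation_contrast(fc)
  hi <- ct[ct$stratum == ">fourfold", ]
  expect_true(all(hi$mean_reduction > 0))
  expect_true(all(hi$p_adj < 0.01))
  # family size default: mutants x configurations
  expect_equal(attr(ct, "family_size"), 3L)

  # null genotype: mutant identical to wt gives mean difference 0 and p = 1
  fc_null <- fc
  fc_null$fc_null <- fc_null$fc_wt
  ct0 <- insulation_contrast(fc_null, mutants = "null")
  expect_true(all(abs(ct0$mean_reduction) < 1e-12))
  expect_true(all(ct0$p[ct0$testable] == 1))
})

test_that("gene-body fold changes agree in contrast direction with promoter ones", {
  cfg <- sim_config(n_chromosomes = 4, chrom_length = 800000L, n_transcripts = 10,
                    n_insulated_pairs = 25, mutant_shrink = 0.5, noise_sd = 0.3,
                    seed = 67)
  b <- simulate_bundle(cfg, genotypes = c("wt", "elba1"))
  q <- promoter_quants_from_counts(b)
  site_peaks <- b$peak_sets$elba3$wt[
    b$peak_sets$elba3$wt$name %in% paste0("elba3_", b$sites$site_id), ]
  pairs <- find_flanked_pairs(q, site_peaks)
  ct_p <- insulation_contrast(pair_fc_table(pairs, q, metric = "promoter"))
  ct_b <- insulation_contrast(pair_fc_table(pairs, q, metric = "body"))
  hi_p <- ct_p[ct_p$stratum == ">fourfold", ]
  hi_b <- ct_b[ct_b$stratum == ">fourfold", ]
  expect_equal(sign(hi_b$mean_reduction), sign(hi_p$mean_reduction))
})

test_that("Monte-Carlo null is seeded, monotone, and extreme when warranted", {
  cfg <- sim_config(n_chromosomes = 4, chrom_length = 800000L, n_transcripts = 30,
                    n_insulated_pairs = 12, seed = 71)
  b <- simulate_bundle(cfg, genotypes = c("wt", "elba1"))
  q <- promoter_quants_from_counts(b)
  site_peaks <- b$peak_sets$elba3$wt[
    b$peak_sets$elba3$wt$name %in% paste0("elba3_", b$sites$site_id), ]
  fc <- pair_fc_table(find_flanked_pairs(q, site_peaks), q)
  mc1 <- montecarlo_null(fc, site_peaks, q, b$seqlengths, iterations = 100, seed = 5)
  mc2 <- montecarlo_null(fc, site_peaks, q, b$seqlengths, iterations = 100, seed = 5)
  expect_identical(mc1, mc2) # bit-reproducible given the seed
  # monotone non-increasing in the observed summary
  fc_hi <- fc; fc_hi$fc_wt <- fc_hi$fc_wt + 10
  mc_hi <- montecarlo_null(fc_hi, site_peaks, q, b$seqlengths,
                           iterations = 100, seed = 5)
  expect_lte(mc_hi$p[mc_hi$genotype == "wt"], mc1$p[mc1$genotype == "wt"])
  expect_equal(mc_hi$p[mc_hi$genotype == "wt"], 0) # larger than every random draw
  # p-values live on the {0, 1/iter, ..., 1} grid
  expect_equal(mc1$p * 100, round(mc1$p * 100))
})
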
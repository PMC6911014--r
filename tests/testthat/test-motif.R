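test_that("consensus scanning matches hand-derived cases", {
  asym <- builtin_motifs()$asymmetric
  m <- scan_consensus("CCAATAAG", asym)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 0L)
  expect_equal(m$strand, "+")
  # reverse complement of CCAATAAG is found on the minus strand
  m2 <- scan_consensus("CTTATTGG", asym)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$strand, "-")
  # full symmetric site TCCAATTGGA (10 nt) does not fit the 11-nt degenerate
  # consensus, but its core CCAATTGG matches at offset 1
  sym11 <- builtin_motifs()$symmetric
  expect_equal(nrow(scan_consensus("TCCAATTGGA", sym11)), 0L)
  core <- builtin_motifs()$symmetric_core
  mc <- scan_consensus("TCCAATTGGA", core)
  expect_equal(mc$start, 1L)
  # degenerate consensus accepts its IUPAC variants
  expect_equal(nrow(scan_consensus("TCCAATTGGAA", sym11)), 1L) # Y=C, H=T, R=G
  expect_equal(nrow(scan_consensus("TCTAATAAGAA", sym11)), 1L) # Y=T, H=A, R=A
})

test_that("N in the sequence never matches a non-N pattern code", {
  asym <- builtin_motifs()$asymmetric
  expect_equal(nrow(scan_consensus("CCANTAAG", asym)), 0L)
  nspec <- motif_spec("anyN", "CCANTAAG", "asymmetric", scan_both_strands = FALSE)
  expect_equal(nrow(scan_consensus("CCANTAAG", nspec)), 1L) # N matches N
  expect_equal(nrow(scan_consensus("CCAGTAAG", nspec)), 1L) # and any base
  expect_error(scan_consensus("CCAATAAG", motif_spec("bad", "CCAAXAAG")), "IUPAC")
  expect_error(scan_consensus("CCAAZAAG", asym), "non-ACGTN")
})

test_that("scanning equals the per-position set-membership oracle on random sequence", {
  set.seed(99)
  for (cons in c("CCAATAAG", "TCYAATHRGAA", "RNCW")) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 10000,
                        replace = TRUE, prob = c(0.24, 0.26, 0.26, 0.23, 0.01)),
                 collapse = "")
    spec <- motif_spec("x", cons, "asymmetric", scan_both_strands = TRUE)
    got <- scan_consensus(seq, spec)
    fwd <- oracle_scan_positions(seq, cons)
    rev <- setdiff(oracle_scan_positions(seq, revcomp_consensus(cons)), fwd)
    expect_equal(got$start[got$strand == "+"], fwd)
    expect_equal(sort(got$start[got$strand == "-"]), sort(rev))
  }
})

test_that("peak motif presence respects the flank window", {
  genome <- c(chr1 = paste0(strrep("A", 500), "CCAATAAG", strrep("G", 500)))
  asym <- builtin_motifs()$asymmetric
  near <- peak_table("chr1", 450, 560, summit = 504) # motif starts at 500
  far <- peak_table("chr1", 100, 300, summit = 200)
  expect_true(peak_motif_presence(near, genome, asym, flank = 50))
  expect_false(peak_motif_presence(far, genome, asym, flank = 50))
  edge <- peak_table("chr1", 0, 40, summit = 10)
  expect_warning(peak_motif_presence(edge, genome, asym, flank = 50), "clipped")
})

test_that("score-bin fractions partition peaks and order bins by score", {
  # 20 peaks, top 10 scores motif-positive, 2 bins -> (1.0, 0.0)
  pk <- random_peaks(20, seed = 3)
  pk$score <- 1:20
  presence <- pk$score > 10
  bf <- motif_fraction_by_score_bin(pk, presence, n_bins = 2)
  expect_equal(bf$fraction, c(1, 0))
  expect_equal(sum(bf$n), 20L)
  # saturation
  bf2 <- motif_fraction_by_score_bin(pk, rep(TRUE, 20), n_bins = 10)
  expect_true(all(bf2$fraction == 1))
  # remainder spread over the top bins; sizes always sum to |peaks|
  pk23 <- random_peaks(23, seed = 4)
  bf3 <- motif_fraction_by_score_bin(pk23, rep(FALSE, 23), n_bins = 10)
  expect_equal(bf3$n, c(3L, 3L, 3L, rep(2L, 7)))
  expect_equal(sum(bf3$n), 23L)
  expect_error(motif_fraction_by_score_bin(pk, presence, n_bins = 0), "n_bins")
  expect_error(motif_fraction_by_score_bin(pk[1:5, ], presence[1:5], 10), "at least")
})

test_that("positive score-motif coupling gives a rising bin trend; zero coupling is flat", {
  cfg <- sim_config(n_chromosomes = 8, chrom_length = 500000L, n_transcripts = 0,
                    n_insulated_pairs = 0, motif_score_coupling = 2, seed = 41)
  b <- simulate_peak_sets(simulate_genome(cfg), cfg, design = list(
    n_extra_sites = 2000, frac_promoter_sites = 0))
  truth <- b$truth$peaks
  pk <- b$peak_sets$elba3$wt
  presence <- truth$motif[match(sub("^elba3_", "", pk$name), truth$site_id)]
  bf <- motif_fraction_by_score_bin(pk, presence, n_bins = 10)
  # bin 1 holds the top scores: fraction should fall along bins
  ct <- cor.test(bf$bin, bf$fraction, method = "spearman")
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)

  cfg0 <- sim_config(n_chromosomes = 8, chrom_length = 500000L, n_transcripts = 0,
                     n_insulated_pairs = 0, motif_score_coupling = 0, seed = 43)
  b0 <- simulate_peak_sets(simulate_genome(cfg0), cfg0, design = list(
    n_extra_sites = 2000, frac_promoter_sites = 0))
  truth0 <- b0$truth$peaks
  pk0 <- b0$peak_sets$elba3$wt
  presence0 <- truth0$motif[match(sub("^elba3_", "", pk0$name), truth0$site_id)]
  bf0 <- motif_fraction_by_score_bin(pk0, presence0, n_bins = 10)
  # flat at 0.5 within binomial error per bin (~200 peaks/bin, 4-sigma)
  expect_true(all(abs(bf0$fraction - 0.5) < 4 * sqrt(0.25 / min(bf0$n))))
})

test_that("motif-per-base profile localizes, vanishes, and conserves coverage", {
  pk <- peak_table(c("c1", "c1"), c(80, 280), c(120, 320), summit = c(100, 300))
  # an 8-bp motif exactly centered on each summit
  matches <- data.frame(chrom = "c1", start = c(96L, 296L), end = c(104L, 304L),
                        strand = "+", motif = "m")
  prof <- motif_per_base_profile(pk, matches, window = 10)
  expect_equal(prof$coverage[prof$offset %in% -4:3], rep(1, 8))
  expect_equal(prof$coverage[prof$offset == 5], 0)
  # conservation: sum(profile) * n_peaks equals in-window motif base count
  expect_equal(sum(prof$coverage) * nrow(pk), 16)
  none <- motif_per_base_profile(pk, matches[0, ], window = 10)
  expect_true(all(none$coverage == 0))
})
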
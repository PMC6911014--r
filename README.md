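# benstone

Analysis toolkit for chromatin insulator proteins of the BEN-solo family
(Insv, Elba1, Elba2, and the adaptor Elba3 of the ELBA heterotrimer) in the
early *Drosophila* embryo. The package re-implements, as tested R code, the
computational procedures used to characterize where these factors bind and
whether they insulate neighbouring transcription units:

* **ChIP-nexus orientation-index analysis.** ChIP-nexus gives strand-resolved,
  near base-pair binding footprints. For each binding site the orientation
  index is

  `OI = max(forward, reverse) / (forward + reverse)`

  over strand-wise read 5'-end counts in a summit-centered window. OI ranges
  from 0.5 (strand-symmetric footprint: a homodimer centered on a palindrome)
  to 1 (fully one-sided: the signature of asymmetric, directional binding by
  a heterotrimer). The analysis runs on the top 500 motif-containing peaks
  per factor.
* **ChIP-nexus read preprocessing.** Molecular-barcode (UMI) deduplication on
  the key (chromosome, 5' position, strand, random 4-nt barcode), barcode
  stripping, and a >= 22 nt read-length filter.
* **Summit-distance peak overlap.** Greedy one-to-one matching of peak
  summits within a maximum distance (default 50 nt); overlap fraction
  defined as matched pairs divided by the smaller set size; four-factor
  co-occupancy partitioning (all-four, ELBA-without-Insv, Elba3+Insv-only,
  factor-unique) and genotype-dependency classification (Elba1/2-dependent
  vs -independent Elba3 sites).
* **Consensus motif scanning.** IUPAC consensus matching for the palindromic
  symmetric site (core `CCAATTGG`, degenerate `TCYAATHRGAA`) and the
  asymmetric ELBA site `CCAATAAG`; motif-fraction-by-score-bin enrichment
  and summit-centered motif-per-base profiles.
* **Adjacent-promoter insulation analysis.** From nascent-transcription
  (PRO-seq-style) data: promoter windows TSS..+200, gene-body +400..end,
  TPM > 1 retention; for each high-confidence binding site the flanking
  promoter pair and its configuration (convergent / divergent / tandem);
  the insulation statistic `|log2(left/right)|` per genotype; Welch
  two-tailed wild-type vs mutant contrasts stratified at fourfold with
  Bonferroni correction; and an empirical null that places length-matched
  random regions on the same chromosomes 2000 times.
* **De-repression contrast.** Mutant-vs-wt log2 fold changes of the top-200
  bound motif-carrying genes vs all bound motif-carrying genes vs bound
  genes without motif, with pairwise Bonferroni-adjusted t-tests.

A synthetic-data generator (`sim_config()`, `simulate_bundle()`, and
friends) emulates every input — genome, transcripts, four-factor peak sets
across genotypes, barcoded ChIP-nexus reads, and per-genotype expression
counts — with known truth labels, so the full pipeline is testable without
any external download. `run_pipeline()` chains all stages from a single
declarative config and writes a manifest with checksums.

## Worked example

```r
library(benstone)

cfg <- sim_config(n_chromosomes = 2, chrom_length = 400000, n_transcripts = 20,
                  n_insulated_pairs = 8, strand_bias = 0.95, seed = 42)
bundle <- simulate_bundle(cfg)

## ChIP-nexus preprocessing and orientation index (asymmetric factor)
nx <- simulate_nexus_reads(bundle, cfg, "elba1", "asymmetric_plus")
pp <- preprocess_reads(nx$reads)
pp$stats
#>              input duplicates_removed      short_removed           retained
#>              34000               3001                  0              30999

cov <- coverage_from_reads(pp$reads, bundle$seqlengths)
peaks <- bundle$peak_sets$elba1$wt
oi <- oi_for_top_peaks(peaks, cov, rep(TRUE, nrow(peaks)), n = 500, window = 100)
summary(oi$oi)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.9224  0.9440  0.9490  0.9491  0.9556  0.9756
```

With a generator strand bias of 0.95, the median OI is ~0.95: the
footprints are read as asymmetric, as expected for a heterotrimer subunit.
A `mode = "symmetric"` factor yields medians near 0.5 instead.

```r
## adjacent-promoter insulation contrast
quants <- promoter_quants_from_counts(bundle)
sites <- bundle$peak_sets$elba3$wt[
  bundle$peak_sets$elba3$wt$name %in% paste0("elba3_", bundle$sites$site_id), ]
fc <- pair_fc_table(find_flanked_pairs(quants, sites), quants)
ct <- insulation_contrast(fc)
subset(ct, stratum == ">fourfold" & mutant == "elba1")[,
  c("configuration", "n", "mean_wt", "mean_mutant", "p_adj")]
#>   configuration n mean_wt mean_mutant    p_adj
#> 1    convergent 8    3.93        2.19 0.000739
#> 3     divergent 7    3.29        1.68 0.005950
#> 5        tandem 8    3.45        1.35 0.000350
```

In every configuration the highly differential (>fourfold) pairs lose about
half of their expression difference in the mutant — the planted insulation
effect — with Bonferroni-adjusted significance even at 8 pairs per class.

```r
mc <- montecarlo_null(fc, sites, quants, bundle$seqlengths,
                      genotypes = c("wt", "elba1"), iterations = 2000, seed = 1)
mc
#>   genotype observed      p iterations
#> 1       wt     3.48 0.0205       2000
#> 2    elba1     1.68 0.4720       2000
```

Random length-matched placements rarely flank pairs as differential as the
real wild-type sites (p ~ 0.02), while in the mutant the signal collapses to
background (p ~ 0.47).

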
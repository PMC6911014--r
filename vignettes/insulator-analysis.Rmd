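---
title: "Methods: binding symmetry and insulation analysis of BEN-solo factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding symmetry and insulation analysis of BEN-solo factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benstone)
```

# Scope and model

`benstone` analyses the genomic behaviour of BEN-solo chromatin proteins —
Insv, which binds a palindromic site as a homodimer, and the ELBA
heterotrimer (Elba1 + Elba2 bridged by Elba3), which binds the asymmetric
`CCAATAAG` site — and tests whether their binding sites insulate adjacent
transcription units. The package starts from already-mapped data: peak
calls with summits, strand-resolved per-base read 5'-end coverage,
transcript annotations, and count tables. Read mapping, peak calling and
de novo transcript/motif discovery are upstream tools' jobs and are not
re-implemented.

## Orientation index

For a binding site with `f` forward-strand and `r` reverse-strand read
5'-ends in a summit-centered window, the orientation index is
`OI = max(f, r) / (f + r)`, bounded in [0.5, 1]. A homodimer centered on a
palindrome produces exonuclease stop sites on both flanks, hence `OI`
near 0.5; a complex whose subunit crosslinks on one side of a directional
motif yields one-sided stops and `OI` near 1. `OI` is undefined at
`f = r = 0`; such sites are excluded with a logged count rather than
imputed.

The counting window is summit ± 100 bp by default (`window` argument).
The window size is not pinned by the underlying assay — stop sites
cluster within tens of bases of the motif — so it is an explicit
parameter; 100 bp comfortably covers the footprint flanks while staying
below typical inter-site spacing. Whether to count over a fixed window or
the whole called peak was an open choice; the window mode is the default
because it makes sites with different peak widths comparable, and the
whole-peak behaviour can be recovered by passing a large window.

The analysis runs on the top 500 motif-containing peaks per factor
(`oi_for_top_peaks()`, `n = 500`): high-scoring, motif-anchored sites are
the ones where strand structure is interpretable. Fewer available peaks
are used in full with a warning.

## Read preprocessing

ChIP-nexus reads carry a fixed 5-nt barcode and a random 4-nt molecular
barcode. `preprocess_reads()` collapses exact duplicates on the key
(chromosome, 5' position, strand, random barcode), strips barcodes, and
drops reads shorter than 22 nt (`min_len = 22`), the minimum length at
which a read maps reliably. Input without a random-barcode column is
treated as already collapsed, which makes the operation idempotent.

## Summit-distance overlap

Peak sets are compared by summit distance, not interval intersection:
summit positions are the reproducible coordinate of a binding event,
whereas interval widths are caller artefacts. `match_by_summit()` matches
greedily by ascending distance with a one-to-one constraint, ties broken
by leftmost summit in either set — deterministic, order-independent, and
checkable against an exhaustive all-pairs oracle (the test suite does
exactly that). The default `max_dist` is 50 nt; 10 and 25 nt are the
conventional stricter settings. The overlap fraction divides matched
pairs by the *smaller* set size, so containment of a small set in a large
one scores 1 and the measure is symmetric. Broad tiling-array
(ChIP-chip) peak sets are first reduced to summit ± 100 nt windows
(`extend_summits(flank = 100)`) before matching.

Whether retention of a wild-type peak in a mutant genotype (the
dependency classification) should use summit distance or region
intersection is not externally fixed; the package uses the same
summit-distance criterion as factor-factor overlap, with the same
configurable `max_dist`, for internal consistency.

## Motif scanning

Only fixed IUPAC consensus semantics are implemented — no PWM scores, no
background model — because every downstream statistic needs only a
present/absent call. Scanning uses a regular-expression translation of
the consensus with lookahead so overlapping matches are all reported;
reverse-strand matches scan the forward sequence with the
reverse-complemented consensus. An `N` in the genome matches only the
pattern code `N`: an undetermined base is never evidence for a motif.
Built-ins: symmetric core `CCAATTGG` (scanned on the forward strand only,
being its own reverse complement), degenerate symmetric `TCYAATHRGAA`
(both strands), and asymmetric `CCAATAAG` (both strands).

Motif *presence* for a peak means a match starting within summit ±
`flank`. The flank for enrichment summaries defaults to 250 bp: wide
enough to tolerate summit jitter, narrow enough that presence still
reflects the peak rather than its neighbourhood. It is a free parameter
because no single value is canonical; results should be read as
flank-parameterized.

`motif_fraction_by_score_bin()` ranks peaks by score and reports the
motif-positive fraction in ten near-equal bins (remainder to the top
bins), bin 1 holding the highest scores.

## Promoter quantification and insulation contrast

From nascent-transcription coverage, the promoter (pausing) window of a
transcript runs from its TSS to 200 nt downstream and the gene body from
+400 to the transcript end, both strand-aware. Transcripts with promoter
expression above 1 TPM in the reference genotype are retained
(`tpm_min = 1`); TPM here is the promoter read count normalized by the
fixed 200-bp window length and scaled so retained-set totals are per
million.

For each high-confidence binding site — a ChIP-nexus peak summit-matched
to a ChIP-seq peak (`require_dual_support()`) — the nearest retained
promoter on each side forms an adjacent pair, classified by strand
arrangement as convergent (+/−), divergent (−/+), or tandem (equal
strands). The insulation statistic is the absolute promoter log2 ratio
`|log2((L + c)/(R + c))|` with pseudocount `c = 0.1` RPM, which bounds
the statistic when one promoter is near-silent while barely perturbing
expressed pairs. Several peaks between the same two promoters give one
pair (leftmost peak kept, count logged).

`insulation_contrast()` stratifies pairs at a wild-type difference of 2
in log2 (fourfold): insulation demand should scale with how different the
neighbours are, so the effect of losing the insulator is expected in the
high stratum and absent in the low one. Within each (mutant,
configuration, stratum) cell a two-tailed t-test compares wild-type and
mutant values; the Welch unpaired form is the default because the
per-genotype measurements are separately noisy, but a paired mode exists
(`paired = TRUE`) since the same pairs are measured in both genotypes —
the external description of the test does not settle this, so both are
provided. P-values are Bonferroni-multiplied by the family size, by
default the number of mutants times the number of configurations within
the run (the family definition is otherwise unreported; the default makes
the family exactly the set of cells the run reports per stratum).

## Monte-Carlo placement null

To ask whether binding-site-flanked pairs are more differential than
arbitrary adjacent pairs, `montecarlo_null()` places the same number of
regions with the same lengths as the observed peaks uniformly at random
on the same chromosomes (`start ~ U[0, chrom_len − width]`), recomputes
flanked pairs, and summarizes their statistic; `p` is the fraction of
iterations whose summary exceeds the observed one, over 2000 iterations
by default. The per-iteration summary is the mean (a `median` mode is
provided; the choice is not externally fixed and the mean is the default
because it is the quantity the contrast also tests). Random regions may
overlap each other or real peaks — the simplest null consistent with
"random placement", and deliberately unconditioned on anything but
chromosome and length. An iteration with no pairs is redrawn once, then
counted as non-exceeding with a warning, keeping `p` conservative.
P-values are bit-reproducible given the seed.

## De-repression contrast

Genes are annotated with their best peak (highest score with a summit
within `max_tss_dist` of the TSS, default 1 kb — the assignment rule is
package-defined, as no canonical rule exists). Counts are CPM-normalized;
the contrast compares mutant-vs-wt log2 fold changes of (i) the top 200
bound motif-carrying genes by peak score, (ii) all bound motif-carrying
genes — a superset of (i), which the output notes — and (iii) bound genes
without the motif, with pairwise Welch tests Bonferroni-adjusted over the
three comparisons. The contrast is invariant to any global per-genotype
scale factor, so plain CPM suffices where a between-sample normalization
(e.g. TMM) would matter only for absolute fold changes.

# The synthetic-data generator

The generator (`sim_config()` + `simulate_*()`) produces every input with
known truth labels. What it emulates, and what it deliberately does not:

* **Genome and transcripts.** Random uniform sequence; transcripts
  1-3 kb, placed non-overlapping with a minimum 2-kb intergenic gap so
  promoter windows never collide and pair detection is unambiguous. Each
  requested pair (per configuration class) gets a separating site with an
  embedded symmetric or asymmetric consensus strictly between the two
  promoters. No repeat structure, GC bias, or mappability model.
* **Peak sets.** A co-occupancy design assigns sites to the five
  categories (all-four, ELBA-only, Elba3+Insv, Elba3-unique,
  Insv-unique); extra sites are kept >= 500 bp apart so summit matching is
  unambiguous. Scores are exponential (many weak, few strong); motif
  presence is Bernoulli with probability `plogis(coupling * z)` of the
  standardized score, so `motif_score_coupling = 0` gives a flat 50%.
  Mutant sets realize heterotrimer logic: Elba1/Elba2 require the whole
  complex; Elba3 retains a designed Elba1/2-independent fraction; Insv is
  autonomous.
* **ChIP-nexus reads.** Per site, `nexus_depth` reads whose 5' ends sit
  3-20 bp outside the motif flanks (forward reads upstream, reverse reads
  downstream), on the preferred strand with probability `strand_bias`
  (0.5 = symmetric). A `duplicate_rate` fraction are exact copies of
  other reads; per-site molecules are made key-unique by construction, so
  the generator's unique-read count is an exact oracle for UMI
  collapsing. Background reads are strand-balanced and uniform, isolating
  strand bias as the signal under test. No sequencing-error or
  fragment-length model.
* **Expression.** Latent log2 expression is Gaussian per transcript
  (log-normal counts); pair members are offset symmetrically so the
  wild-type pair difference equals a draw from `|N(wt_logfc_mean,
  wt_logfc_sd)|` (defaults 3.2 and 0.8, a strongly differential cohort).
  In a loss-of-insulation genotype the pair difference is multiplied by
  `mutant_shrink` (default 0.5) plus `N(0, noise_sd)` noise (default
  0.3), truncated at zero. The `shrink_min_wt_lfc` parameter restricts
  the effect to pairs above a wild-type threshold (default 0 = all
  insulated pairs; the stratified study design sets it to 2 so the
  low-differential stratum is a true negative control). Counts are
  Poisson draws from the latent mean; overdispersion beyond Poisson is
  deliberately not modelled, and no replicate structure exists — the
  contrasts therefore see somewhat cleaner data than a real experiment,
  which is what passing tests do and do not show about real data.

Identical configurations (same seed) give bit-identical bundles; each
generator stage derives its own sub-seed so stages can be rerun
independently.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; summits are stored in BED
  column 7 as offsets from the interval start (the MACS2 convention) and
  converted to absolute coordinates on read.
* The log2 ratio track uses a 1-RPM pseudocount, bounding ratios on empty
  bases; anchored matrices mark out-of-bounds cells `NA` and exclude them
  from column means.
* `rpm_normalize()` refuses to run twice; scaling silently stacked is a
  classic track bug.
* Zero-width extension (`extend_summits(flank = 0)`) is an error — an
  empty interval is not a peak. Depth-0 nexus simulation returns an empty
  read list. A transcript shorter than 400 nt has no body window and
  reports a missing body value with a warning rather than failing.
* Ranking ties (equal scores) are broken by name for reproducible group
  membership.

# Cohort sizes used by the test suite

The shipped tests exercise the analyses at sizes chosen to make their
statistical claims decisive while keeping the suite quick to run:
orientation-index separation at 200 sites with 500 reads each (binomial
sampling error on the median well below the 0.5 vs 0.9 separation);
the insulation contrast at 200 pairs per configuration (power far above
0.9 for a 50% shrink at noise 0.3); Monte-Carlo calibration over 50
independent runs of 200 iterations plus one full 2000-iteration run;
overlap matching against the exhaustive oracle on 100 random instances of
up to 200 peaks; motif-score coupling at ~2000 peaks.

# Known limitations

* Consensus-only motif semantics: degenerate binding below consensus
  identity is invisible.
* The Monte-Carlo null conditions only on chromosome and region length,
  not on chromatin context or gene density.
* Poisson-only count noise and absence of replicates mean real-data
  p-values will be larger than synthetic ones at equal effect size.
* The greedy one-to-one summit matching is a deterministic stand-in for
  merge-based peak overlap tools whose tie handling is unspecified;
  results can differ for pathological, densely stacked peak sets.
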
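#' Default pipeline configuration
#'
#' Returns the declarative configuration driving [run_pipeline()], with
#' the analysis defaults used throughout: summit max distance 50 nt,
#' promoter window +200 / body +400, promoter TPM > 1, top 500 peaks for
#' the orientation-index analysis, top 200 genes for the de-repression
#' contrast, fourfold stratification split, and 2000 Monte-Carlo
#' iterations (reduced in the demo config for speed).
#'
#' @param outdir Output directory.
#' @param seed Integer master seed for the generator.
#' @return Nested list understood by [run_pipeline()].
#' @export
default_run_config <- function(outdir = tempfile("benstone_run_"), seed = 1L) {
  list(
    outdir = outdir,
    seeds = list(simulate = as.integer(seed),
                 montecarlo = as.integer(seed) + 1L),
    simulate = list(n_chromosomes = 2L, chrom_length = 400000L,
                    n_transcripts = 20L, n_insulated_pairs = 8L),
    overlap = list(max_dist = 50L, anchor = "elba3"),
    motif = list(flank = 250L, n_bins = 10L),
    nexus = list(oi_window = 100L, top_n = 500L, min_len = 22L,
                 modes = list(elba1 = "asymmetric_plus",
                              elba2 = "asymmetric_minus",
                              elba3 = "symmetric", insv = "symmetric")),
    insulate = list(tpm_min = 1, pseudocount = 0.1, fourfold_split = 2,
                    iterations = 200L, genotypes = SIM_GENOTYPES),
    derepress = list(top_n = 200L, max_tss_dist = 1000L, effect = 1.5)
  )
}

validate_run_config <- function(config) {
  need <- function(path) {
    node <- config
    for (k in path) {
      if (is.null(node[[k]]))
        stopf("run config is missing required field '%s'", paste(path, collapse = "."))
      node <- node[[k]]
    }
    node
  }
  need("outdir")
  need(c("seeds", "simulate"))
  need(c("seeds", "montecarlo"))
  for (s in c("simulate", "overlap", "motif", "nexus", "insulate", "derepress"))
    need(s)
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> nexus preprocessing -> co-occupancy overlap ->
#' motif enrichment -> orientation index -> insulation contrast with
#' Monte-Carlo null -> de-repression contrast, writing every stage output
#' under `config$outdir` and a JSON manifest echoing all parameters with
#' per-file MD5 checksums. Reruns with an identical configuration are
#' byte-identical.
#'
#' @param config Nested list (see [default_run_config()]) or path to a
#'   YAML file holding one.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  validate_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(...) file.path(config$outdir, paste0(...))
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  # --- simulate -------------------------------------------------------
  sim_args <- config$simulate
  sim_args$seed <- config$seeds$simulate
  cfg <- do.call(sim_config, sim_args)
  bundle <- simulate_bundle(cfg, genotypes = config$insulate$genotypes)
  note("simulated %d transcripts, %d insulated pairs, %d binding sites",
       nrow(bundle$transcripts), nrow(bundle$truth$pairs),
       nrow(bundle$truth$peaks))
  write_fasta(bundle$genome, outfile("genome.fa"))
  write_transcripts(bundle$transcripts, outfile("transcripts.bed"))
  for (f in names(bundle$peak_sets))
    for (g in names(bundle$peak_sets[[f]]))
      write_peaks(bundle$peak_sets[[f]][[g]], outfile("peaks_", f, "_", g, ".bed"))
  utils::write.table(bundle$expression, outfile("expression_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bundle$truth$pairs, outfile("truth_pairs.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  # --- ChIP-nexus preprocessing and OI --------------------------------
  oi_medians <- list()
  for (f in names(config$nexus$modes)) {
    sim <- simulate_nexus_reads(bundle, cfg, f, config$nexus$modes[[f]])
    write_nexus_tsv(sim$reads, outfile("nexus_reads_", f, ".tsv"))
    pp <- preprocess_reads(sim$reads, min_len = config$nexus$min_len)
    note("nexus %s: %d reads in, %d duplicates removed, %d short removed, %d retained",
         f, pp$stats[["input"]], pp$stats[["duplicates_removed"]],
         pp$stats[["short_removed"]], pp$stats[["retained"]])
    cov <- coverage_from_reads(pp$reads, bundle$seqlengths)
    peaks <- bundle$peak_sets[[f]]$wt
    if (!nrow(peaks)) next
    presence <- bundle$truth$peaks$motif[match(sub(paste0(f, "_"), "", peaks$name),
                                               bundle$truth$peaks$site_id)]
    oi <- withCallingHandlers(
      oi_for_top_peaks(peaks, cov, presence, n = config$nexus$top_n,
                       window = config$nexus$oi_window),
      warning = function(w) invokeRestart("muffleWarning"))
    utils::write.table(oi, outfile("oi_", f, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    oi_medians[[f]] <- stats::median(oi$oi)
  }

  # --- co-occupancy ---------------------------------------------------
  wt_sets <- lapply(bundle$peak_sets, `[[`, "wt")
  venn <- venn_partition(wt_sets, anchor = config$overlap$anchor,
                         max_dist = config$overlap$max_dist)
  utils::write.table(venn, outfile("venn_partition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dep <- classify_dependency(wt_sets$elba3,
                             list(elba1 = bundle$peak_sets$elba3$elba1,
                                  elba2 = bundle$peak_sets$elba3$elba2),
                             max_dist = config$overlap$max_dist)
  utils::write.table(dep, outfile("elba3_dependency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- motif enrichment ----------------------------------------------
  spec <- builtin_motifs()$asymmetric
  anchor_peaks <- wt_sets[[config$overlap$anchor]]
  presence <- peak_motif_presence(anchor_peaks, bundle$genome,
                                  builtin_motifs()$symmetric_core,
                                  flank = config$motif$flank) |
    peak_motif_presence(anchor_peaks, bundle$genome, spec,
                        flank = config$motif$flank)
  binfrac <- motif_fraction_by_score_bin(anchor_peaks, presence,
                                         n_bins = config$motif$n_bins)
  utils::write.table(binfrac, outfile("motif_bin_fractions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- insulation -----------------------------------------------------
  quants <- promoter_quants_from_counts(bundle, tpm_min = config$insulate$tpm_min)
  site_peaks <- wt_sets$elba3[wt_sets$elba3$name %in%
                                paste0("elba3_", bundle$sites$site_id), ]
  pairs <- find_flanked_pairs(quants, site_peaks)
  fc <- pair_fc_table(pairs, quants, pseudocount = config$insulate$pseudocount)
  utils::write.table(fc, outfile("insulation_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  contrast <- insulation_contrast(fc, fourfold_split = config$insulate$fourfold_split)
  utils::write.table(contrast, outfile("insulation_contrast.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mc <- montecarlo_null(fc, site_peaks, quants, bundle$seqlengths,
                        iterations = config$insulate$iterations,
                        seed = config$seeds$montecarlo)
  utils::write.table(mc, outfile("montecarlo_null.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- de-repression --------------------------------------------------
  ann <- annotate_targets(bundle$transcripts, anchor_peaks, presence,
                          max_tss_dist = config$derepress$max_tss_dist)
  rna <- simulate_rnaseq_counts(bundle, ann, effect = config$derepress$effect)
  counts <- data.frame(gene = rna$gene, wt = rna$wt_count, mut = rna$mut_count)
  tab <- expression_table(counts, "wt", "mut", ann)
  tgc <- withCallingHandlers(
    three_group_contrast(tab, top_n = config$derepress$top_n),
    warning = function(w) invokeRestart("muffleWarning"))
  utils::write.table(tgc$groups, outfile("derepression_groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tgc$tests, outfile("derepression_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- manifest -------------------------------------------------------
  files <- sort(setdiff(list.files(config$outdir), "manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(config$outdir, files)))
  names(checksums) <- files
  manifest <- list(parameters = config, oi_median = oi_medians,
                   outputs = checksums, log = log_lines)
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, outfile("run.log"))
  invisible(manifest)
}
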
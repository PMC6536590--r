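# Orchestration: a single declarative configuration drives the synthetic
# dataset, peak calling, promoter annotation, motif discovery and the
# expression overlay, end to end. The numbered scripts under analysis/
# are thin drivers over these functions.

#' Default pipeline configuration
#'
#' Returns the full nested parameter list for every stage, optionally
#' updated with `overrides` (recursively merged). The defaults are the
#' study conditions of the synthetic benchmark: a 500-kb genome with 400
#' genes, 30 planted operator sites at tenfold enrichment over a
#' Poisson(20) background, rolling-mean smoothing with window 50 bp and
#' step 10 bp, a threefold-mean peak threshold, 100-bp summit windows,
#' an 18-bp symmetric motif model, and a fivefold / p < 0.05
#' differential-expression filter.
#'
#' @param overrides Named list of stage sublists to override.
#' @param seed Master seed; stage seeds are derived from it
#'   deterministically.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(overrides = list(), seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    genome = list(length_bp = 500000L, gc_fraction = 0.54,
                  n_genes = 400L, mean_gene_bp = 1000L,
                  intergenic_bp = 200L, circular = FALSE),
    sites = list(n_sites = 30L, promoter_fraction = 0.8,
                 mutation_rate = 0.1, consensus = default_palindrome(),
                 promoter_offset_range = c(-300L, -50L),
                 min_separation_bp = 2000L),
    coverage = list(background_lambda = 20, enrichment_fold = 10,
                    site_sd_bp = 60),
    smoothing = list(window_bp = 50L, step_bp = 10L),
    peaks = list(fold_threshold = 3, merge_gap_bp = 50L,
                 min_windows = 2L),
    window_flank_bp = 50L,
    promoter = list(upstream_bp = 500L, downstream_bp = 100L),
    motif = list(width = 18L, symmetric = TRUE, max_iter = 200L,
                 tol = 1e-6, n_seeds = 10L),
    expression = list(n_replicates = 4L, noise_sd = 0.3,
                      effect_log2 = -2.8, offtarget_fraction = 0.02,
                      offtarget_effect_log2 = 3),
    de = list(fold_cutoff = 5, p_cutoff = 0.05, p_adjust = "none"),
    flow = list(n_events = 100000L, induced_fraction = 0.2,
                off_meanlog = log(50), on_meanlog = log(2000),
                sd_log = 0.4, gate_quantile = 0.995)
  )
  utils::modifyList(cfg, overrides)
}

#' Read a pipeline configuration from a YAML file
#'
#' Values in the file override the defaults of [pipeline_config()];
#' anything not mentioned keeps its default.
#'
#' @param path YAML file path.
#' @param seed Master seed (overridden by a `seed` key in the file).
#' @export
read_pipeline_config <- function(path, seed = 1L) {
  pipeline_config(yaml::read_yaml(path), seed = seed)
}

# derived stage seeds, kept well below 2^31
stage_seed <- function(cfg, k) (cfg$seed %% 1000000L) * 1000L + k

#' Generate the full synthetic dataset
#'
#' Simulates the genome, plants operator sites, simulates the enriched
#' coverage track, the two-condition expression table and the reporter
#' flow-cytometry populations. With `out_dir` set, writes genome.fasta,
#' genes.gff3, coverage.bedgraph, truth_sites.bed / truth_sites.tsv,
#' expression.tsv and flow_events.tsv; re-running with the same
#' configuration and seed reproduces the files byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return Dataset list with `annotation`, `truth`, `coverage`,
#'   `expression` and `flow`.
#' @export
pipeline_simulate <- function(config = pipeline_config(),
                              out_dir = NULL) {
  g <- config$genome
  ann0 <- simulate_genome(length_bp = g$length_bp,
                          gc_fraction = g$gc_fraction,
                          n_genes = g$n_genes,
                          mean_gene_bp = g$mean_gene_bp,
                          intergenic_bp = g$intergenic_bp,
                          seed = stage_seed(config, 1L),
                          circular = g$circular)
  s <- config$sites
  planted <- plant_sites(ann0, consensus = s$consensus,
                         n_sites = s$n_sites,
                         promoter_fraction = s$promoter_fraction,
                         mutation_rate = s$mutation_rate,
                         seed = stage_seed(config, 2L),
                         promoter_offset_range = s$promoter_offset_range,
                         min_separation_bp = s$min_separation_bp)
  cv <- config$coverage
  coverage <- simulate_coverage(
    planted$annotation, planted$truth,
    coverage_sim_params(cv$background_lambda, cv$enrichment_fold,
                        cv$site_sd_bp),
    seed = stage_seed(config, 3L))
  e <- config$expression
  expression <- simulate_expression(
    planted$annotation, planted$truth, n_replicates = e$n_replicates,
    noise_sd = e$noise_sd, effect_log2 = e$effect_log2,
    offtarget_fraction = e$offtarget_fraction,
    offtarget_effect_log2 = e$offtarget_effect_log2,
    seed = stage_seed(config, 4L))
  f <- config$flow
  flow <- simulate_flow(n_events = f$n_events,
                        induced_fraction = f$induced_fraction,
                        off_meanlog = f$off_meanlog,
                        on_meanlog = f$on_meanlog, sd_log = f$sd_log,
                        seed = stage_seed(config, 5L))
  dataset <- list(annotation = planted$annotation, truth = planted$truth,
                  coverage = coverage, expression = expression,
                  flow = flow)
  if (!is.null(out_dir)) write_dataset(dataset, out_dir)
  dataset
}

write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ct <- dataset$annotation$contigs[[1L]]
  seqs <- Biostrings::DNAStringSet(stats::setNames(ct$sequence, ct$id))
  Biostrings::writeXStringSet(seqs, file.path(out_dir, "genome.fasta"))
  genes <- dataset$annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  gr$locus_tag <- genes$gene_id
  gr$product <- genes$product
  rtracklayer::export(gr, file.path(out_dir, "genes.gff3"),
                      format = "gff3")
  # bedGraph: run-length encode, omit zero-coverage runs
  r <- S4Vectors::Rle(dataset$coverage$values)
  rl <- S4Vectors::runLength(r); rv <- S4Vectors::runValue(r)
  starts0 <- cumsum(c(0L, rl[-length(rl)]))
  keep <- rv != 0
  bg <- GenomicRanges::GRanges(
    seqnames = ct$id,
    ranges = IRanges::IRanges(start = starts0[keep] + 1L,
                              width = rl[keep]),
    score = rv[keep])
  rtracklayer::export(bg, file.path(out_dir, "coverage.bedgraph"),
                      format = "bedGraph")
  sites <- dataset$truth$sites
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", sites$contig_id,
                     sites$center - nchar(sites$seq) %/% 2L,
                     sites$center - nchar(sites$seq) %/% 2L +
                       nchar(sites$seq),
                     sites$site_id, sites$strand),
             file.path(out_dir, "truth_sites.bed"))
  utils::write.table(sites, file.path(out_dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$expression$table,
                     file.path(out_dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = dataset$flow$sample$events,
               control = dataset$flow$control$events),
    file.path(out_dir, "flow_events.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Smooth, threshold and extract peaks from a dataset
#'
#' @param dataset From [pipeline_simulate()] (or an equivalent list with
#'   `annotation` and `coverage`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for peaks.bed and the summit table.
#' @return List with `smoothed`, `genome_mean` and `peaks` (windows
#'   attached).
#' @export
pipeline_call_peaks <- function(dataset, config = pipeline_config(),
                                out_dir = NULL) {
  ct <- dataset$annotation$contigs[[1L]]
  sp <- smoothing_params(config$smoothing$window_bp,
                         config$smoothing$step_bp)
  smoothed <- rolling_mean(dataset$coverage, sp, circular = ct$circular)
  gmean <- genome_mean(dataset$coverage)
  pp <- peak_call_params(config$peaks$fold_threshold,
                         config$peaks$merge_gap_bp,
                         config$peaks$min_windows)
  peaks <- call_peaks(smoothed, gmean, pp, contig_length = ct$length)
  peaks <- extract_peak_windows(peaks, dataset$annotation$contigs,
                                flank_bp = config$window_flank_bp)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_peaks_bed(peaks, file.path(out_dir, "peaks.bed"))
  }
  list(smoothed = smoothed, genome_mean = gmean, peaks = peaks)
}

#' Annotate peaks, infer the motif and overlay expression
#'
#' Runs promoter assignment, region tallies, motif discovery on the
#' full-length (non-truncated) peak windows, and — when the dataset
#' carries an expression table — per-gene statistics and direct-target
#' classification.
#'
#' @param dataset From [pipeline_simulate()].
#' @param peak_result From [pipeline_call_peaks()].
#' @param config A [pipeline_config()].
#' @param regulator_gene_id Optional gene id to test for autoregulation.
#' @param out_dir Optional directory for the regulon table, motif files
#'   and target table.
#' @return List with `assignments`, `bound_genes`, `region_tallies`,
#'   `motif` (a `zoops_fit`), `records`, `calls` and `autoregulation`.
#' @export
pipeline_regulon <- function(dataset, peak_result,
                             config = pipeline_config(),
                             regulator_gene_id = NULL, out_dir = NULL) {
  peaks <- peak_result$peaks
  genes <- dataset$annotation$genes
  rule <- promoter_rule(config$promoter$upstream_bp,
                        config$promoter$downstream_bp)
  assignments <- assign_peaks_to_genes(peaks, genes, rule)
  bound_genes <- unique(stats::na.omit(assignments$gene_id))
  region_tallies <- vapply(dataset$annotation$regions,
                           function(r) tally_region(peaks, r),
                           integer(1))
  windows <- peaks$window_seq[!peaks$truncated &
                                nchar(peaks$window_seq) ==
                                2L * config$window_flank_bp]
  mt <- config$motif
  motif_fit <- if (length(windows) >= 2L) {
    zoops_em(windows, width = mt$width, symmetric = mt$symmetric,
             max_iter = mt$max_iter, tol = mt$tol,
             n_seeds = mt$n_seeds, rng_seed = stage_seed(config, 6L))
  } else NULL
  records <- NULL; calls <- NULL
  if (!is.null(dataset$expression)) {
    records <- summarize_expression(dataset$expression$table)
    calls <- classify_targets(records, bound_genes,
                              de_criteria(config$de$fold_cutoff,
                                          config$de$p_cutoff),
                              p_adjust = config$de$p_adjust)
  }
  autoreg <- if (!is.null(regulator_gene_id)) {
    autoregulation_check(peaks, genes, regulator_gene_id, rule)
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    regulon <- merge(assignments,
                     cbind(peak_id = seq_len(nrow(peaks)),
                           peaks[, c("summit", "fold_over_mean")]),
                     by = "peak_id")
    utils::write.table(regulon, file.path(out_dir, "regulon_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(motif_fit)) {
      write_meme_motif(motif_fit$pwm, file.path(out_dir, "motif.meme"),
                       nsites = length(windows))
      utils::write.table(
        data.frame(position = seq_len(motif_fit$pwm$width),
                   motif_fit$pwm$probs),
        file.path(out_dir, "motif_matrix.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(motif_fit$hits,
                         file.path(out_dir, "motif_hits.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(calls)) {
      utils::write.table(calls, file.path(out_dir, "target_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(assignments = assignments, bound_genes = bound_genes,
       region_tallies = region_tallies, motif = motif_fit,
       records = records, calls = calls, autoregulation = autoreg)
}

#' Run the whole pipeline on synthetic data and score it against truth
#'
#' simulate -> smooth/call peaks -> extract windows -> assign promoters
#' -> infer motif -> overlay expression -> classify targets, then score
#' every stage against the planted truth.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for all stage files.
#' @return List with `dataset`, `peak_result`, `regulon` and
#'   `evaluation` (peak recovery, motif comparison, target recovery,
#'   flow gating).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  dataset <- pipeline_simulate(config, out_dir = out_dir)
  peak_result <- pipeline_call_peaks(dataset, config, out_dir = out_dir)
  regulon <- pipeline_regulon(dataset, peak_result, config,
                              out_dir = out_dir)
  pr <- peak_recovery_stats(peak_result$peaks, dataset$truth)
  motif_eval <- NULL
  if (!is.null(regulon$motif)) {
    cons <- pwm_consensus(regulon$motif$pwm)
    planted <- dataset$truth$consensus
    motif_eval <- list(
      palindromicity = palindromicity(regulon$motif$pwm),
      at_content = at_content(regulon$motif$pwm),
      planted_at_content = at_content(dataset$truth$motif),
      consensus = cons,
      consensus_edit_distance = min(edit_distance(cons, planted),
                                    edit_distance(revcomp(cons), planted))
    )
  }
  target_eval <- if (!is.null(regulon$calls)) {
    target_recovery_stats(regulon$calls, dataset$expression$effects)
  } else NULL
  gate <- gate_induced_fraction(dataset$flow$sample,
                                dataset$flow$control,
                                config$flow$gate_quantile)
  list(dataset = dataset, peak_result = peak_result, regulon = regulon,
       evaluation = list(peaks = pr, motif = motif_eval,
                         targets = target_eval,
                         flow = list(
                           gated_fraction = gate,
                           true_fraction = config$flow$induced_fraction)))
}
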
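#!/usr/bin/env Rscript
# Stage 2: call binding peaks from the on-disk dataset.
#
# Deliberately reloads the genome, gene models and coverage from the
# files written by 01_simulate.R (exercising the FASTA / GFF3 /
# bedGraph readers), smooths coverage with a 50-bp rolling mean at
# 10-bp steps, calls peaks above 3x the genome-wide mean and writes
# peaks.bed (+ summit table) under results/peaks/.

suppressPackageStartupMessages(library(regulonmap))

cfg <- pipeline_config(seed = 42L)
contigs <- read_fasta("results/dataset/genome.fasta")
genes <- read_gff3("results/dataset/genes.gff3")
coverage <- read_bedgraph("results/dataset/coverage.bedgraph",
                          contigs)[[1]]
ann <- genome_annotation(contigs, genes)
dataset <- list(annotation = ann, coverage = coverage)

pk <- pipeline_call_peaks(dataset, cfg, out_dir = "results/peaks")
message("genome-wide mean coverage: ", round(pk$genome_mean, 3))
message("peaks called: ", nrow(pk$peaks))
message(sprintf("fold enrichment range: %.1f - %.1f",
                min(pk$peaks$fold_over_mean),
                max(pk$peaks$fold_over_mean)))

# score against planted truth when available
truth_path <- "results/dataset/truth_sites.tsv"
if (file.exists(truth_path)) {
  sites <- utils::read.delim(truth_path)
  stats <- peak_recovery_stats(pk$peaks,
                               list(sites = sites))
  message(sprintf("recall %.3f, precision %.3f, summits within 15 bp %.3f",
                  stats$recall, stats$precision,
                  stats$summit_within_tol_fraction))
}
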
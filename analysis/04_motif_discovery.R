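#!/usr/bin/env Rscript
# Stage 4: infer the binding motif from 100-bp summit windows.
#
# Runs the symmetric ZOOPS-EM mixture finder (width 18, ten random
# restarts) on the full-length peak windows and writes the motif as a
# MEME-format file plus a plain probability matrix and the per-window
# placements under results/regulon/.

suppressPackageStartupMessages(library(regulonmap))

cfg <- pipeline_config(seed = 42L)
contigs <- read_fasta("results/dataset/genome.fasta")
genes <- read_gff3("results/dataset/genes.gff3")
coverage <- read_bedgraph("results/dataset/coverage.bedgraph",
                          contigs)[[1]]
dataset <- list(annotation = genome_annotation(contigs, genes),
                coverage = coverage)
pk <- pipeline_call_peaks(dataset, cfg)

windows <- pk$peaks$window_seq[!pk$peaks$truncated]
fit <- zoops_em(windows, width = cfg$motif$width,
                symmetric = cfg$motif$symmetric,
                n_seeds = cfg$motif$n_seeds,
                rng_seed = 42L * 1000L + 6L)

dir.create("results/regulon", recursive = TRUE, showWarnings = FALSE)
write_meme_motif(fit$pwm, "results/regulon/motif.meme",
                 nsites = length(windows))
utils::write.table(
  data.frame(position = seq_len(fit$pwm$width), fit$pwm$probs),
  "results/regulon/motif_matrix.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(fit$hits, "results/regulon/motif_hits.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

message("windows used: ", length(windows))
message("consensus: ", pwm_consensus(fit$pwm))
message(sprintf("information content: %.2f bits",
                information_content(fit$pwm)$total))
message(sprintf("AT content: %.3f, palindromicity: %.3f",
                at_content(fit$pwm), palindromicity(fit$pwm)))
message("windows with a motif placement: ", nrow(fit$hits), "/",
        length(windows))
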
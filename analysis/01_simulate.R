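#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Writes a 500-kb genome with 400 genes, 30 planted palindromic operator
# sites (24 in promoters, 6 intergenic), a ChAP-Seq-style enriched
# coverage track, a two-condition expression table and reporter
# flow-cytometry events, all with ground truth, under results/dataset/.

suppressPackageStartupMessages(library(regulonmap))

seed <- 42L
cfg <- pipeline_config(seed = seed)
dataset <- pipeline_simulate(cfg, out_dir = "results/dataset")

message("genome: ", dataset$annotation$contigs[[1]]$length, " bp, ",
        nrow(dataset$annotation$genes), " genes")
message("planted sites: ", nrow(dataset$truth$sites),
        " (", sum(dataset$truth$sites$in_promoter), " in promoters)")
message("mean coverage: ", round(mean(dataset$coverage$values), 2))
message("files written to results/dataset/")
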
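#!/usr/bin/env Rscript
# Stage 5: overlay expression and classify direct targets.
#
# Reads the two-condition expression table, computes per-gene M / A
# statistics and replicate t-tests, intersects differential expression
# (|M| >= log2 5, p < 0.05) with the bound-gene list from stage 3, and
# writes target_calls.tsv plus a simple MA plot under results/regulon/.

suppressPackageStartupMessages(library(regulonmap))

cfg <- pipeline_config(seed = 42L)
tab <- utils::read.delim("results/dataset/expression.tsv")
bound <- readLines("results/regulon/bound_genes.txt")

records <- summarize_expression(tab)
calls <- classify_targets(records, bound,
                          de_criteria(cfg$de$fold_cutoff,
                                      cfg$de$p_cutoff),
                          p_adjust = cfg$de$p_adjust)

dir.create("results/regulon", recursive = TRUE, showWarnings = FALSE)
utils::write.table(calls, "results/regulon/target_calls.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

grDevices::pdf("results/regulon/ma_plot.pdf", width = 6, height = 5)
direct <- calls$class %in% c("direct_repressed", "direct_activated")
plot(records$A, records$M, pch = 20,
     col = ifelse(direct[match(records$gene_id, calls$gene_id)],
                  "firebrick", "grey50"),
     xlab = "A (mean log2 intensity)",
     ylab = "M (log2 perturbed/control)",
     main = "Expression overlay; direct targets in red")
abline(h = c(-1, 1) * log2(cfg$de$fold_cutoff), lty = 2)
invisible(grDevices::dev.off())

message("genes: ", nrow(calls))
for (cl in c("direct_repressed", "direct_activated",
             "bound_unchanged", "unbound_DE")) {
  message(cl, ": ", sum(calls$class == cl))
}
message("wrote results/regulon/target_calls.tsv and ma_plot.pdf")
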
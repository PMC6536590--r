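# regulonmap

Reconstruct the regulon of a bacterial transcription factor from
ChAP-Seq coverage and a two-condition expression experiment.

Chromatin affinity purification sequencing (ChAP-Seq) pulls down a
tagged DNA-binding protein together with its crosslinked genomic DNA;
sequencing the bound fragments yields a per-base coverage track whose
enrichment peaks mark binding sites. `regulonmap` turns such a track,
a genome annotation and replicated expression ratios into a regulon
map:

1. **Peak calling** — coverage is smoothed with a 50 bp rolling mean
   at 10 bp steps; windows whose smoothed value exceeds 3× the
   genome-wide mean are merged into peaks (runs of ≥ 2 windows, gaps
   ≤ 50 bp bridged) and each peak is summarized by a 100 bp window
   centered on its summit.
2. **Promoter assignment** — a summit is assigned to a gene when it
   lies in the orientation-aware window \[−500, +100) bp around the
   annotated start; divergent promoters shared by two genes are
   flagged, and operon maps re-point targets to the leader gene.
3. **Motif discovery** — a zero-or-one-occurrence-per-sequence
   (ZOOPS) expectation–maximization mixture model infers the binding
   motif from the summit windows, with a symmetric mode for the
   palindromic operators typical of MarR-family regulators, multiple
   random restarts, and a provably non-decreasing MAP objective.
4. **Expression integration** — per-gene M (mean log2 ratio) and A
   statistics with replicate *t*-tests; genes are classified as
   `direct_repressed` / `direct_activated` (bound and |M| ≥ log2 5,
   p < 0.05), `bound_unchanged`, `unbound_DE` or `none`.
5. **Follow-up assays** — qRT-PCR relative quantification
   (2^−ΔCt) and flow-cytometry reporter gating against an uninduced
   negative control.

A synthetic-data module plants palindromic operator sites with known
ground truth (Poisson background, Gaussian-shaped 10-fold enrichment,
repression effects with replicate noise), so the entire pipeline is
testable end to end and every headline number below is scored against
truth.

## Worked example

```r
library(regulonmap)

run <- run_pipeline(pipeline_config(seed = 1))
run$evaluation$peaks[c("recall", "precision",
                       "summit_within_tol_fraction", "n_peaks")]
#> $recall
#> [1] 1
#> $precision
#> [1] 1
#> $summit_within_tol_fraction
#> [1] 1
#> $n_peaks
#> [1] 30

run$evaluation$motif[c("consensus", "palindromicity", "at_content")]
#> $consensus
#> [1] "TTGTAATTATAATTACAA"
#> $palindromicity
#> [1] 1
#> $at_content
#> [1] 0.8420111

run$evaluation$targets[c("sensitivity", "specificity",
                         "n_called_direct")]
#> $sensitivity
#> [1] 1
#> $specificity
#> [1] 1
#> $n_called_direct
#> [1] 24

run$evaluation$flow
#> $gated_fraction
#> [1] 0.20184
#> $true_fraction
#> [1] 0.2
```

The same analysis can be run stage by stage through the numbered
scripts in `analysis/`, which communicate through files in the
standard formats (FASTA, GFF3, bedGraph, BED, MEME) under `results/`:

```sh
Rscript analysis/01_simulate.R             # genome + truth + coverage
Rscript analysis/02_call_peaks.R           # 30 peaks, recall 1.000
Rscript analysis/03_annotate_peaks.R       # 38 promoter assignments
Rscript analysis/04_motif_discovery.R      # consensus TTGTAATTATAATTACAA
Rscript analysis/05_integrate_expression.R # 24 direct_repressed + MA plot
```

Stage 2, for example, prints:

```
genome-wide mean coverage: 21.629
peaks called: 30
fold enrichment range: 8.8 - 9.2
recall 1.000, precision 1.000, summits within 15 bp 1.000
```

## Documentation

The methods vignette
(`vignettes/regulon-mapping-methods.Rmd`) documents the statistical
model, the ZOOPS-EM derivation, the synthetic-data generator and the
numerical conventions. Every exported function carries roxygen
documentation in `R/`.

## License

MIT (see `LICENSE`).
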
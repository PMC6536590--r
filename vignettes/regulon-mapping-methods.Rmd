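---
title: "Methods: regulon mapping from ChAP-Seq coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulon mapping from ChAP-Seq coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model, the algorithmic choices
and the numerical conventions behind `regulonmap`. It is written for a
reader who wants to audit the methods, not just run them.

## Problem

A DNA-binding transcription factor is pulled down together with its
crosslinked genomic DNA (chromatin affinity purification, ChAP-Seq),
and the sequenced fragments yield a per-base coverage track. The task
is to turn that track, a genome annotation and a two-condition
expression experiment into a regulon: the set of genes the factor
directly controls, the binding motif, and per-gene regulatory calls.

## Peak calling

Coverage $c_1, \dots, c_L$ is smoothed with a rolling mean of window
$w = 50$ bp evaluated every $s = 10$ bp; window $k$ covers bases
$[ks, ks + w)$ (0-based, half-open — the convention for *all*
coordinates in this package) and is reported at its center
$ks + \lfloor w/2 \rfloor$. A window is *marked* when its smoothed
value strictly exceeds $\tau \cdot \bar{c}$, where $\bar{c}$ is the
genome-wide (length-weighted) mean coverage and $\tau = 3$ by default.
Runs of marked windows are merged when the unmarked gap between
consecutive window centers is at most `merge_gap_bp` (50 bp) beyond
the step, and runs shorter than `min_windows = 2` are discarded: a
single marked window is indistinguishable from a sampling fluctuation
at Poisson-like noise levels. The summit is the center of the window
with the maximal smoothed value (ties resolve to the leftmost), and
each peak is summarized by a 100 bp window centered on the summit
(summit at offset 50). On a linear contig, windows that would run off
an end are clipped and flagged `truncated`; on a circular contig they
wrap.

The smoothing uses a cumulative-sum formulation, which is exact (not
merely close) for integer-valued coverage because sums of integers are
representable exactly in double precision; the test suite exploits
this with `expect_identical` against a loop-based oracle.

## Promoter assignment

A gene's transcription start is approximated by its annotated start
(`+` strand) or `end − 1` (`−` strand). A summit at signed offset
$r$ relative to the start (negative = upstream in the gene's reading
direction) is assigned when $r \in [-500, 100)$. A summit falling in
the shared window of two divergently transcribed genes is assigned to
both and flagged `divergent_shared`; peaks matching no window are kept
with `NA` gene assignment so the intergenic peak count is not silently
lost. An optional operon map re-points assignments to the operon
leader. The asymmetric window reflects bacterial promoter anatomy:
operators act from the core promoter and a few hundred bases upstream,
rarely from inside the coding sequence.

## Motif discovery: symmetric ZOOPS-EM

Each 100 bp peak window contains zero or one motif occurrence
(ZOOPS). With motif width $m$, window length $\ell$, position weight
matrix $\theta$ and 0-order background $q$ estimated from the windows
themselves, the likelihood of window $x$ is

$$P(x) = (1-\gamma)\,P_{bg}(x) + \frac{\gamma}{2(\ell-m+1)}
  \sum_{o=0}^{\ell-m} \sum_{\sigma \in \{+,-\}} P(x \mid o, \sigma),$$

with occurrences equally likely at every offset and on either strand.
EM alternates posterior computation over $(o, \sigma, \text{absent})$
with a weighted-count M-step using pseudocount 0.5. Because the
planted operators of MarR-family regulators are palindromic, the
default *symmetric* mode averages the expected counts with their
reverse-complement mirror before normalizing; this is the exact
maximizer of the expected complete-data log-posterior under the
palindromic constraint (the two orientations contribute equal total
counts), so monotonicity of the objective is preserved. The objective
is the *penalized* log-likelihood
$\log P(\text{data}) + 0.5 \sum \log \theta$, i.e. MAP-EM under a
Dirichlet(1.5) prior — this is what the pseudocount M-step actually
maximizes, and it is asserted non-decreasing (tolerance $10^{-9}$)
every iteration in the tests. Ten random restarts seeded from random
window $k$-mers guard against local optima; the best final objective
wins. A window is called a hit when its posterior probability of
containing an occurrence exceeds 0.5; the reported placement is the
maximum-posterior offset/strand, scored in bits against the
background.

Motif quality is summarized by information content
$\sum_i \sum_b \theta_{ib} \log_2(\theta_{ib}/q_b)$, AT content
(mean $\theta_{iA} + \theta_{iT}$), and palindromicity
$1 - \sum |\theta - \theta^{rc}| / (2m)$, which is 1 exactly when the
PWM equals its reverse complement.

## Expression integration

For $n$ paired measurements, $M$ is the mean per-replicate
$\log_2(\text{perturbed}/\text{control})$ and $A$ the mean $\log_2$
intensity over both channels. Significance is a one-sample two-sided
$t$-test of the replicate $\log_2$ ratios against zero. Conventions
for degenerate inputs are explicit: identical nonzero ratios give
$p = 0$ with flag `zero_variance` (the test statistic diverges), and a
single replicate gives `NA` with flag `undefined`. A gene is
differentially expressed when $|M| \ge \log_2 5$ and $p < 0.05$
(unadjusted by default; Benjamini–Hochberg available via
`p_adjust = "BH"`). Crossing with the bound-gene list yields five
classes: `direct_repressed`, `direct_activated`, `bound_unchanged`,
`unbound_DE`, `none`. The deliberately stringent fivefold cutoff
trades sensitivity to weak regulation for a near-zero false direct
call rate, matching how regulons are typically curated.

Follow-up assays get small exact helpers: qRT-PCR relative abundance
$2^{-\Delta C_t}$, and flow-cytometry reporter gating where the gate
is the 0.995 quantile (type 7) of an uninduced negative control and
the readout is the fraction of sample events strictly above it — so a
sample distributed like the control reads ~0.005 by construction.

## Synthetic data generator

The generator exists to make the whole pipeline testable against
ground truth; its defaults define the study conditions and are *not*
tuned to the analysis:

* **Genome** — 500 kb i.i.d. sequence at GC 0.54 (typical for
  *Corynebacterium*-like actinobacteria), 400 genes of 1000 bp on a
  regular grid with 200 bp gaps, strands in `+ + − −` blocks so that
  divergent, convergent and tandem intergenic layouts all occur. The
  middle fifth is labeled as a prophage-like region for tally
  reporting. A regular grid sacrifices realism in gene length
  variation for exactness of the geometric test oracles.
* **Sites** — the planted operator is the 18 bp perfect palindrome
  `TTGTAATTATAATTACAA` (16/18 AT). 30 sites are planted: 24 at a
  uniform offset in $(-300, -50)$ upstream of a gene start and 6 in
  convergent (3′–3′) intergenic gaps, which genuinely belong to no
  promoter window. Sites are mutated per base with probability 0.1,
  placed on a random strand, and kept $\ge 2$ kb apart so peaks never
  merge ambiguously.
* **Coverage** — Poisson with rate
  $\lambda_b = 20\,(1 + 9 e^{-d^2 / (2 \cdot 60^2)})$, $d$ the
  distance to the nearest site center: background 20×, 10-fold
  enrichment at the summit, Gaussian spread 60 bp mimicking the
  fragment-size footprint.
* **Expression** — direct targets get a true effect of $-2.8$ log2
  (repression); 2% of other genes get off-target effects of $\pm 3$;
  replicate noise is $N(0, 0.3)$; intensities are
  $2^{A \pm m/2}$ with $A \sim U(6, 12)$.
* **Flow** — a two-component lognormal mixture with a 20% induced
  fraction.

Limits worth knowing: the background sequence is i.i.d. (no
codon/operon structure, no GC skew), coverage noise is Poisson with no
mappability or PCR-duplicate artifacts, and expression effects are
homoscedastic. These idealizations are what make exact recovery
statements testable; they also mean measured recall/precision here are
upper bounds on real-data performance.

## Determinism and numerics

Every stochastic stage takes an explicit seed; the pipeline derives
per-stage seeds as $(\text{seed} \bmod 10^6) \cdot 1000 + k$ so stages
are independently reproducible and all derived seeds stay below
$2^{31}$. `with_seed()` restores the caller's RNG state, so seeded
helpers compose. Identical configuration and seed reproduce every
output file byte for byte — this is asserted with MD5 comparisons in
the test suite. Likelihood computations in the EM are done in log
space with a `log_sum_exp` guard; probabilities never reach exact zero
because of the pseudocount, keeping the objective finite.

## Design decisions that could have gone another way

* **Motif input: all peak windows, not a curated subset.** Using
  every non-truncated window avoids an arbitrary curation step and is
  honest about what an automated pipeline can do; with a strong
  palindromic signal ZOOPS handles occurrence-free windows natively.
* **Threshold on smoothed, mean-relative coverage** rather than a
  per-position Poisson $p$-value: the mean-relative rule is what the
  simple ChAP-Seq protocol supports without an input-control track,
  and it makes the threshold interpretable as a fold enrichment.
* **Unadjusted $p$-values by default** with a BH switch: at a
  fivefold effect cutoff the $p$ filter is secondary, and the default
  mirrors the common practice the classification rule comes from;
  methodologically inclined users should flip `p_adjust = "BH"`.

## Reproducing the full analysis

```r
# end-to-end, scored against planted truth
run <- run_pipeline(pipeline_config(seed = 1))
str(run$evaluation, max.level = 2)
```

or stage by stage via the numbered scripts in `analysis/`, which
communicate through files under `results/` using the standard formats
(FASTA, GFF3, bedGraph, BED, MEME).
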
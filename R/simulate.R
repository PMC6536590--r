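# Synthetic-data generators with planted ground truth. They stand in for
# the study system — a high-GC actinobacterial chromosome, a regulator
# binding AT-rich palindromic operators preferentially in promoters, a
# coverage track enriched at bound sites, a two-condition expression
# matrix in which bound genes respond to regulator overexpression, and a
# fluorescent prophage-reporter population — so every pipeline stage is
# testable against known truth. Every generator is a pure function of its
# parameters and seed.

#' Default planted operator consensus
#'
#' An 18-bp AT-rich palindrome (its own reverse complement; 16/18 A or
#' T), the operator shape typical of homodimeric MarR-family regulators.
#' @export
default_palindrome <- function() {
  half <- "TTGTAATTA"
  paste0(half, revcomp(half))
}

#' Simulate a bacterial chromosome with annotated genes
#'
#' Sequence is i.i.d. with the given GC content (default 0.54, a high-GC
#' actinobacterial chromosome). Genes are laid on a regular grid in
#' alternating strand blocks of two (`+ + - -`), so divergent, convergent
#' and tandem intergenic regions all occur. A named `prophage` region
#' spanning the middle fifth of the contig stands in for a resident
#' prophage element.
#'
#' @param length_bp Contig length (default 500 kb).
#' @param gc_fraction GC content (default 0.54).
#' @param n_genes Number of genes (default 400); 0 gives a gene-free
#'   contig.
#' @param mean_gene_bp Gene length (default 1000).
#' @param intergenic_bp Gap between genes (default 200).
#' @param seed RNG seed.
#' @param circular Circular contig (default FALSE).
#' @param contig_id Contig name.
#' @return A [genome_annotation()].
#' @export
simulate_genome <- function(length_bp = 500000L, gc_fraction = 0.54,
                            n_genes = 400L, mean_gene_bp = 1000L,
                            intergenic_bp = 200L, seed = 1L,
                            circular = FALSE, contig_id = "chrS") {
  length_bp <- as.integer(length_bp)
  if (n_genes * (mean_gene_bp + intergenic_bp) > length_bp) {
    stop("infeasible layout: n_genes * (mean_gene_bp + intergenic_bp) ",
         "exceeds length_bp")
  }
  seq_chr <- with_seed(seed, {
    paste(sample(DNA_BASES, length_bp, replace = TRUE,
                 prob = c((1 - gc_fraction) / 2, gc_fraction / 2,
                          gc_fraction / 2, (1 - gc_fraction) / 2)),
          collapse = "")
  })
  ct <- contig(contig_id, seq_chr, circular = circular)
  if (n_genes > 0L) {
    i <- seq_len(n_genes)
    starts <- intergenic_bp + (i - 1L) * (mean_gene_bp + intergenic_bp)
    genes <- data.frame(
      gene_id = sprintf("sg%04d", i),
      contig_id = contig_id,
      start = as.integer(starts),
      end = as.integer(starts + mean_gene_bp),
      strand = c("+", "+", "-", "-")[((i - 1L) %% 4L) + 1L],
      product = "hypothetical protein",
      stringsAsFactors = FALSE
    )
  } else {
    genes <- data.frame(gene_id = character(0), contig_id = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), product = character(0))
  }
  prophage <- region_interval(contig_id,
                              as.integer(floor(length_bp * 2 / 5)),
                              as.integer(floor(length_bp * 3 / 5)),
                              "prophage")
  genome_annotation(list(ct), genes, regions = list(prophage = prophage))
}

mutate_site <- function(site, rate) {
  b <- strsplit(site, "")[[1L]]
  hit <- stats::runif(length(b)) < rate
  if (any(hit)) {
    b[hit] <- vapply(b[hit], function(x) {
      sample(setdiff(DNA_BASES, x), 1L)
    }, character(1))
  }
  paste(b, collapse = "")
}

#' Plant operator sites into a simulated genome
#'
#' A fraction of sites is centered within a promoter offset range
#' upstream of a gene start (the intended target gene is recorded); the
#' remainder goes to convergent intergenic gaps, away from any promoter.
#' Each planted instance mutates each base independently with
#' `mutation_rate`; site centers keep a minimum pairwise separation so
#' every planted site yields its own distinct peak.
#'
#' @param annotation A [genome_annotation()] from [simulate_genome()].
#' @param consensus Operator consensus (default [default_palindrome()]);
#'   must have even length.
#' @param n_sites Number of sites (default 30).
#' @param promoter_fraction Fraction placed in promoters (default 0.8).
#' @param mutation_rate Per-base mutation probability (default 0.1).
#' @param seed RNG seed.
#' @param promoter_offset_range Offset of the site center from the gene
#'   start, in reading orientation (default -300 to -50).
#' @param min_separation_bp Minimum distance between site centers
#'   (default 2000).
#' @return List with the modified `annotation` and `truth`, a
#'   `synthetic_truth` object: `sites` data.frame (site_id, contig_id,
#'   center, strand, seq, target_gene, in_promoter), the planting `motif`
#'   PWM (consensus base probability `1 - mutation_rate`, others
#'   `mutation_rate / 3`), `consensus`, `mutation_rate`, `seed`.
#' @export
plant_sites <- function(annotation, consensus = default_palindrome(),
                        n_sites = 30L, promoter_fraction = 0.8,
                        mutation_rate = 0.1, seed = 1L,
                        promoter_offset_range = c(-300L, -50L),
                        min_separation_bp = 2000L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  w <- nchar(consensus)
  half <- w %/% 2L
  genes <- annotation$genes
  ct <- annotation$contigs[[1L]]
  n_prom <- round(n_sites * promoter_fraction)
  n_other <- n_sites - n_prom

  placed <- with_seed(seed, {
    accepted <- list()
    centers <- integer(0)
    ok_sep <- function(center) {
      length(centers) == 0L || all(abs(centers - center) >= min_separation_bp)
    }
    # promoter sites: upstream of a randomly chosen gene start
    cand_genes <- sample(nrow(genes))
    for (gi in cand_genes) {
      if (length(accepted) >= n_prom) break
      off <- sample(seq(promoter_offset_range[1L],
                        promoter_offset_range[2L]), 1L)
      tss <- if (genes$strand[gi] == "+") genes$start[gi] else
        genes$end[gi] - 1L
      center <- if (genes$strand[gi] == "+") tss + off else tss - off
      if (center - half < 0L || center + half > ct$length) next
      if (!ok_sep(center)) next
      centers <- c(centers, center)
      accepted[[length(accepted) + 1L]] <- list(
        center = center, target = genes$gene_id[gi], in_promoter = TRUE)
    }
    if (length(accepted) < n_prom) {
      stop("not enough eligible promoters for ", n_prom, " sites")
    }
    # intergenic sites: centers of convergent (3'-3') gaps
    conv <- which(genes$strand[-nrow(genes)] == "+" &
                    genes$strand[-1L] == "-" &
                    genes$contig_id[-nrow(genes)] == genes$contig_id[-1L])
    conv_centers <- (genes$end[conv] + genes$start[conv + 1L]) %/% 2L
    n_acc <- 0L
    for (center in conv_centers[sample.int(length(conv_centers))]) {
      if (n_acc >= n_other) break
      if (center - half < 0L || center + half > ct$length) next
      if (!ok_sep(center)) next
      centers <- c(centers, center)
      accepted[[length(accepted) + 1L]] <- list(
        center = center, target = NA_character_, in_promoter = FALSE)
      n_acc <- n_acc + 1L
    }
    if (n_acc < n_other) {
      stop("not enough convergent intergenic gaps for ", n_other, " sites")
    }
    # planted instance: mutated consensus on a random strand
    lapply(accepted, function(a) {
      a$strand <- sample(c("+", "-"), 1L)
      a$seq <- mutate_site(consensus, mutation_rate)
      a
    })
  })

  seq_chr <- ct$sequence
  for (a in placed) {
    ins <- if (a$strand == "+") a$seq else revcomp(a$seq)
    substr(seq_chr, a$center - half + 1L, a$center - half + w) <- ins
  }
  new_ct <- contig(ct$id, seq_chr, circular = ct$circular)
  new_ann <- genome_annotation(stats::setNames(list(new_ct), ct$id),
                               genes, annotation$regions)

  sites <- data.frame(
    site_id = sprintf("site_%d", seq_along(placed)),
    contig_id = ct$id,
    center = vapply(placed, function(a) a$center, integer(1)),
    strand = vapply(placed, function(a) a$strand, character(1)),
    seq = vapply(placed, function(a) a$seq, character(1)),
    target_gene = vapply(placed, function(a) a$target, character(1)),
    in_promoter = vapply(placed, function(a) a$in_promoter, logical(1)),
    stringsAsFactors = FALSE
  )
  cons_idx <- encode_dna(consensus)
  motif_probs <- matrix(mutation_rate / 3, nrow = w, ncol = 4L)
  motif_probs[cbind(seq_len(w), cons_idx)] <- 1 - mutation_rate
  truth <- structure(
    list(sites = sites, motif = pwm(motif_probs), consensus = consensus,
         mutation_rate = mutation_rate, seed = seed),
    class = "synthetic_truth"
  )
  list(annotation = new_ann, truth = truth)
}

#' Coverage-simulation parameters
#'
#' @param background_lambda Poisson background coverage (default 20).
#' @param enrichment_fold Coverage fold at a site center over background
#'   (default 10).
#' @param site_sd_bp Gaussian spread of the enrichment around the site
#'   center, approximating the fragment pileup (default 60).
#' @export
coverage_sim_params <- function(background_lambda = 20,
                                enrichment_fold = 10, site_sd_bp = 60) {
  stopifnot(background_lambda > 0, enrichment_fold > 0, site_sd_bp > 0)
  list(background_lambda = background_lambda,
       enrichment_fold = enrichment_fold, site_sd_bp = site_sd_bp)
}

#' Simulate a coverage track with enrichment at planted sites
#'
#' Per-base counts are Poisson with rate
#' `lambda_b = background * (1 + sum_sites (fold - 1) *
#' exp(-(b - center)^2 / (2 sd^2)))` — a Gaussian fragment-pileup
#' approximation rather than read-level simulation, since the pipeline
#' consumes coverage, not reads.
#'
#' @param annotation A [genome_annotation()].
#' @param truth A `synthetic_truth` from [plant_sites()] (or NULL for
#'   site-free background).
#' @param params [coverage_sim_params()].
#' @param seed RNG seed.
#' @return A [coverage_track()].
#' @export
simulate_coverage <- function(annotation, truth = NULL,
                              params = coverage_sim_params(), seed = 1L) {
  ct <- annotation$contigs[[1L]]
  L <- ct$length
  lambda <- rep(params$background_lambda, L)
  if (!is.null(truth)) {
    reach <- ceiling(6 * params$site_sd_bp)
    for (center in truth$sites$center) {
      lo <- max(1L, center - reach)
      hi <- min(L, center + reach)
      b <- lo:hi
      lambda[b] <- lambda[b] + params$background_lambda *
        (params$enrichment_fold - 1) *
        exp(-(b - center)^2 / (2 * params$site_sd_bp^2))
    }
  }
  values <- with_seed(seed, stats::rpois(L, lambda))
  coverage_track(ct$id, values)
}

#' Simulate a two-condition expression table
#'
#' Per gene and replicate, `m ~ N(true effect, noise_sd^2)`. Genes that
#' are intended targets of a planted promoter site get `effect_log2`
#' (default -2.8, about sevenfold down, clearing the fivefold cutoff with
#' margin at the default noise); a configurable fraction of the remaining
#' genes gets an off-target effect of random sign. Intensities are
#' reconstructed so that [compute_ma()] recovers `m` exactly.
#'
#' @param annotation A [genome_annotation()].
#' @param truth A `synthetic_truth` from [plant_sites()].
#' @param n_replicates Paired replicates (default 4).
#' @param noise_sd Replicate noise on the log2 scale (default 0.3).
#' @param effect_log2 True log2 effect of regulator overexpression on
#'   bound targets (default -2.8; repression-dominant).
#' @param offtarget_fraction Fraction of non-target genes with secondary
#'   effects (default 0.02).
#' @param offtarget_effect_log2 Magnitude of off-target effects
#'   (default 3; sign random).
#' @param seed RNG seed.
#' @return List with `table` (gene_id, pert_1..n, ctrl_1..n) and
#'   `effects` (gene_id, true_effect, is_direct_target, is_offtarget).
#' @export
simulate_expression <- function(annotation, truth, n_replicates = 4L,
                                noise_sd = 0.3, effect_log2 = -2.8,
                                offtarget_fraction = 0.02,
                                offtarget_effect_log2 = 3, seed = 1L) {
  genes <- annotation$genes
  n <- nrow(genes)
  targets <- unique(stats::na.omit(truth$sites$target_gene))
  is_target <- genes$gene_id %in% targets
  out <- with_seed(seed, {
    effect <- ifelse(is_target, effect_log2, 0)
    nontarget <- which(!is_target)
    n_off <- floor(length(nontarget) * offtarget_fraction)
    off_idx <- if (n_off > 0L) sample(nontarget, n_off) else integer(0)
    effect[off_idx] <- sample(c(-1, 1), n_off, replace = TRUE) *
      offtarget_effect_log2
    m <- matrix(stats::rnorm(n * n_replicates, mean = effect,
                             sd = noise_sd),
                nrow = n, ncol = n_replicates)
    A <- stats::runif(n, 6, 12)
    list(effect = effect, m = m, A = A, off_idx = off_idx)
  })
  pert <- 2^(out$A + out$m / 2)
  ctrl <- 2^(out$A - out$m / 2)
  colnames(pert) <- sprintf("pert_%d", seq_len(n_replicates))
  colnames(ctrl) <- sprintf("ctrl_%d", seq_len(n_replicates))
  tab <- cbind(data.frame(gene_id = genes$gene_id,
                          stringsAsFactors = FALSE),
               as.data.frame(pert), as.data.frame(ctrl))
  effects <- data.frame(
    gene_id = genes$gene_id,
    true_effect = out$effect,
    is_direct_target = is_target,
    is_offtarget = seq_len(n) %in% out$off_idx,
    stringsAsFactors = FALSE
  )
  list(table = tab, effects = effects)
}

#' Simulate reporter flow-cytometry events
#'
#' The negative control is lognormal around the "off" fluorescence; the
#' sample is a mixture with `induced_fraction` of events drawn from the
#' "on" mode.
#'
#' @param n_events Events per sample (default 100000).
#' @param induced_fraction True induced fraction in `[0, 1]`.
#' @param off_meanlog,on_meanlog Lognormal meanlog of the off and on
#'   modes (defaults `log(50)` and `log(2000)`, well separated).
#' @param sd_log Lognormal sdlog of both modes (default 0.4).
#' @param seed RNG seed.
#' @return List with `sample` and `control` ([flow_sample()] objects)
#'   and `truth` (`induced_fraction`, realized `n_on`).
#' @export
simulate_flow <- function(n_events = 100000L, induced_fraction = 0.2,
                          off_meanlog = log(50), on_meanlog = log(2000),
                          sd_log = 0.4, seed = 1L) {
  if (n_events <= 0L) stop("n_events must be positive")
  if (induced_fraction < 0 || induced_fraction > 1) {
    stop("induced_fraction must be in [0, 1]")
  }
  with_seed(seed, {
    control <- stats::rlnorm(n_events, off_meanlog, sd_log)
    n_on <- stats::rbinom(1L, n_events, induced_fraction)
    smp <- c(stats::rlnorm(n_events - n_on, off_meanlog, sd_log),
             stats::rlnorm(n_on, on_meanlog, sd_log))
    list(sample = flow_sample(smp), control = flow_sample(control),
         truth = list(induced_fraction = induced_fraction, n_on = n_on))
  })
}
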
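# Differential-expression statistics and the binding x expression
# overlay that classifies direct regulator targets, plus the qRT-PCR
# relative-quantification and flow-cytometry gating calculations used to
# validate the expression data.

#' Per-gene M and A statistics from paired intensities
#'
#' For paired replicates, `m_r = log2(I_pert,r / I_ctrl,r)`; `M` is their
#' mean and `A` the mean log2 intensity over both channels and all
#' replicates, the axes of an MA plot.
#'
#' @param intensities_perturbed,intensities_control Positive per-replicate
#'   intensities, paired and of equal length.
#' @return List with `M`, `A` and the per-replicate `m_values`.
#' @export
compute_ma <- function(intensities_perturbed, intensities_control) {
  stopifnot(length(intensities_perturbed) == length(intensities_control),
            length(intensities_perturbed) >= 1L)
  if (any(intensities_perturbed <= 0) || any(intensities_control <= 0)) {
    stop("intensities must be positive")
  }
  m <- log2(intensities_perturbed / intensities_control)
  list(M = mean(m),
       A = mean(c(log2(intensities_perturbed), log2(intensities_control))),
       m_values = m)
}

#' Per-gene significance of a nonzero mean log2 ratio
#'
#' Two-sided one-sample t test of `mean(m) = 0` over replicates. With a
#' single replicate the p value is undefined; with zero variance and a
#' nonzero mean the p value is 0 by convention. Both cases are flagged.
#'
#' @param m_values Per-replicate log2 ratios.
#' @return List with `p_value` and `flag` (`"ok"`, `"undefined"` or
#'   `"zero_variance"`).
#' @export
replicate_pvalue <- function(m_values) {
  m_values <- m_values[is.finite(m_values)]
  if (length(m_values) < 2L) {
    return(list(p_value = NA_real_, flag = "undefined"))
  }
  if (stats::sd(m_values) == 0) {
    p <- if (mean(m_values) == 0) 1 else 0
    return(list(p_value = p, flag = "zero_variance"))
  }
  list(p_value = stats::t.test(m_values)$p.value, flag = "ok")
}

#' Differential-expression criteria
#'
#' Defaults mirror the published filter: more than fivefold altered mRNA
#' level with p below 0.05, applied to raw (uncorrected) p values.
#'
#' @param fold_cutoff Linear fold-change cutoff (default 5).
#' @param p_cutoff P-value cutoff (default 0.05).
#' @export
de_criteria <- function(fold_cutoff = 5, p_cutoff = 0.05) {
  stopifnot(fold_cutoff > 1, p_cutoff > 0, p_cutoff < 1)
  list(fold_cutoff = fold_cutoff, p_cutoff = p_cutoff)
}

#' Summarize an intensity table into per-gene expression records
#'
#' @param intensities data.frame with a `gene_id` column plus paired
#'   numeric columns `pert_1..n` and `ctrl_1..n`.
#' @return data.frame with `gene_id`, `M`, `A`, `p_value`,
#'   `n_replicates` and `flag`.
#' @export
summarize_expression <- function(intensities) {
  stopifnot("gene_id" %in% names(intensities))
  pert_cols <- grep("^pert_", names(intensities), value = TRUE)
  ctrl_cols <- grep("^ctrl_", names(intensities), value = TRUE)
  stopifnot(length(pert_cols) >= 1L,
            length(pert_cols) == length(ctrl_cols))
  pert <- as.matrix(intensities[, pert_cols, drop = FALSE])
  ctrl <- as.matrix(intensities[, ctrl_cols, drop = FALSE])
  if (any(pert <= 0) || any(ctrl <= 0)) stop("intensities must be positive")
  nrep <- ncol(pert)
  m <- log2(pert / ctrl)
  M <- rowMeans(m)
  A <- rowMeans(cbind(log2(pert), log2(ctrl)))
  # vectorized one-sample t test, equivalent to replicate_pvalue() per row
  if (nrep >= 2L) {
    s <- sqrt(rowSums((m - M)^2) / (nrep - 1L))
    p <- 2 * stats::pt(-abs(M / (s / sqrt(nrep))), df = nrep - 1L)
    flag <- rep("ok", nrow(m))
    zv <- s == 0
    p[zv] <- ifelse(M[zv] == 0, 1, 0)
    flag[zv] <- "zero_variance"
  } else {
    p <- rep(NA_real_, nrow(m))
    flag <- rep("undefined", nrow(m))
  }
  data.frame(gene_id = intensities$gene_id, M = M, A = A, p_value = p,
             n_replicates = nrep, flag = flag,
             stringsAsFactors = FALSE)
}

#' Classify genes as direct regulator targets
#'
#' A gene is differentially expressed (DE) when `|M| >= log2(fold_cutoff)`
#' and `p < p_cutoff`. Classes: `direct_repressed` (bound, DE, M < 0 —
#' regulator overexpression lowers the target), `direct_activated`
#' (bound, DE, M > 0), `bound_unchanged`, `unbound_DE`, else `none`.
#' M > 0 means higher expression in the regulator-overexpression
#' condition throughout.
#'
#' @param records data.frame with `gene_id`, `M`, `p_value` (one row per
#'   gene; duplicates are an error).
#' @param bound_genes Character vector of genes with an assigned binding
#'   peak.
#' @param criteria [de_criteria()].
#' @param p_adjust Multiple-testing correction applied before
#'   thresholding (a [stats::p.adjust()] method); the default `"none"`
#'   matches the published raw-p filter, `"BH"` is the conservative
#'   alternative.
#' @return data.frame with `gene_id`, `bound`, `M`, `p_value`, `de` and
#'   `class`.
#' @export
classify_targets <- function(records, bound_genes,
                             criteria = de_criteria(),
                             p_adjust = "none") {
  if (anyDuplicated(records$gene_id)) {
    stop("duplicate gene_id in expression records")
  }
  p_use <- stats::p.adjust(records$p_value, method = p_adjust)
  de <- !is.na(records$M) & !is.na(p_use) &
    abs(records$M) >= log2(criteria$fold_cutoff) &
    p_use < criteria$p_cutoff
  bound <- records$gene_id %in% bound_genes
  class <- rep("none", nrow(records))
  class[bound & de & records$M < 0] <- "direct_repressed"
  class[bound & de & records$M > 0] <- "direct_activated"
  class[bound & !de] <- "bound_unchanged"
  class[!bound & de] <- "unbound_DE"
  data.frame(gene_id = records$gene_id, bound = bound, M = records$M,
             p_value = records$p_value, de = de, class = class,
             stringsAsFactors = FALSE)
}

#' qRT-PCR relative quantification
#'
#' `delta_ct = Ct(sample) - Ct(control)`; relative transcriptional change
#' `= 2^-delta_ct`.
#'
#' @param ct_sample,ct_control Finite threshold-cycle values (vectorized).
#' @param gene_id Optional gene labels.
#' @return data.frame with `gene_id`, `ct_sample`, `ct_control`,
#'   `delta_ct` and `relative_change`.
#' @export
qpcr_relative_change <- function(ct_sample, ct_control, gene_id = NULL) {
  stopifnot(all(is.finite(ct_sample)), all(is.finite(ct_control)),
            length(ct_sample) == length(ct_control))
  if (is.null(gene_id)) gene_id <- rep(NA_character_, length(ct_sample))
  delta <- ct_sample - ct_control
  data.frame(gene_id = gene_id, ct_sample = ct_sample,
             ct_control = ct_control, delta_ct = delta,
             relative_change = 2^(-delta), stringsAsFactors = FALSE)
}

#' Create a flow-cytometry sample
#'
#' @param events Numeric vector of per-event fluorescence values
#'   (arbitrary units); must be non-empty.
#' @export
flow_sample <- function(events) {
  stopifnot(is.numeric(events), length(events) > 0L)
  structure(list(events = as.numeric(events), n_events = length(events)),
            class = "flow_sample")
}

#' Fraction of induced cells, gated against a negative control
#'
#' The gate is placed at a high quantile of the uninduced negative
#' control's fluorescence (linear interpolation between order
#' statistics); the induced fraction is the share of sample events
#' strictly above it.
#'
#' @param sample,negative_control [flow_sample()] objects.
#' @param quantile Control quantile defining the gate (default 0.995);
#'   must lie strictly in (0, 1).
#' @return Fraction in `[0, 1]`.
#' @export
gate_induced_fraction <- function(sample, negative_control,
                                  quantile = 0.995) {
  stopifnot(inherits(sample, "flow_sample"),
            inherits(negative_control, "flow_sample"))
  if (quantile <= 0 || quantile >= 1) {
    stop("gating quantile must be in (0, 1)")
  }
  gate <- stats::quantile(negative_control$events, probs = quantile,
                          names = FALSE, type = 7)
  mean(sample$events > gate)
}
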
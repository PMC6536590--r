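# Peak-to-promoter assignment and regional tallies: turning a peak set
# into the candidate-target table of a regulon.

#' Promoter window rule
#'
#' A peak is assigned to a gene when its summit falls within
#' `[-upstream_bp, +downstream_bp)` of the gene's transcriptional start,
#' measured in the gene's reading orientation. The window spans typical
#' bacterial operator placement and is deliberately generous upstream.
#'
#' @param upstream_bp Bases upstream of the gene start (default 500).
#' @param downstream_bp Bases downstream of the gene start (default 100).
#' @export
promoter_rule <- function(upstream_bp = 500L, downstream_bp = 100L) {
  upstream_bp <- as.integer(upstream_bp)
  downstream_bp <- as.integer(downstream_bp)
  stopifnot(upstream_bp >= 0L, downstream_bp >= 0L,
            upstream_bp + downstream_bp > 0L)
  list(upstream_bp = upstream_bp, downstream_bp = downstream_bp)
}

# 0-based coordinate of the first transcribed base: leftmost for "+",
# rightmost for "-".
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' Assign peaks to candidate target genes by summit position
#'
#' Assignment is by summit, not span overlap, mirroring the
#' summit-centered fragment logic of the peak windows. A summit lying
#' upstream of two divergently oriented gene starts, within both windows,
#' yields two assignments flagged `divergent_shared`. Peaks matching no
#' window are retained with `gene_id = NA`.
#'
#' When an operon map is supplied, assignments to non-leader operon
#' members are re-pointed to the operon leader, so operons are reported
#' as regulatory units.
#'
#' @param peaks A `peak_set` (needs `summit` and `contig_id`).
#' @param genes Gene table (see [read_gff3()]).
#' @param rule A [promoter_rule()].
#' @param operon_map Optional data.frame with columns `gene_id` and
#'   `leader_id`.
#' @return data.frame with columns `peak_id`, `gene_id`, `offset_bp`
#'   (signed summit-to-start distance in reading orientation; negative =
#'   upstream) and `relation` (`upstream`, `overlapping_start`,
#'   `divergent_shared`, or NA for unassigned peaks).
#' @export
assign_peaks_to_genes <- function(peaks, genes, rule = promoter_rule(),
                                  operon_map = NULL) {
  tss <- gene_tss(genes)
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    summit <- peaks$summit[i]
    on_contig <- genes$contig_id == peaks$contig_id[i]
    rel <- ifelse(genes$strand == "+", summit - tss, tss - summit)
    hit <- on_contig & rel >= -rule$upstream_bp & rel < rule$downstream_bp
    if (!any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        peak_id = i, gene_id = NA_character_, offset_bp = NA_integer_,
        relation = NA_character_, stringsAsFactors = FALSE)
      next
    }
    idx <- which(hit)
    relation <- ifelse(rel[idx] < 0L, "upstream", "overlapping_start")
    upstream_hits <- idx[rel[idx] < 0L]
    if (length(upstream_hits) >= 2L &&
        length(unique(genes$strand[upstream_hits])) == 2L) {
      relation[rel[idx] < 0L] <- "divergent_shared"
    }
    out[[length(out) + 1L]] <- data.frame(
      peak_id = i, gene_id = genes$gene_id[idx],
      offset_bp = as.integer(rel[idx]), relation = relation,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) {
    res <- data.frame(peak_id = integer(0), gene_id = character(0),
                      offset_bp = integer(0), relation = character(0))
  }
  if (!is.null(operon_map)) {
    stopifnot(all(c("gene_id", "leader_id") %in% names(operon_map)))
    m <- match(res$gene_id, operon_map$gene_id)
    repoint <- !is.na(m)
    res$operon_repointed <- repoint
    res$gene_id[repoint] <- operon_map$leader_id[m[repoint]]
  }
  res
}

#' Count peaks with summit inside a named region
#'
#' @param peaks A `peak_set`.
#' @param region A [region_interval()] (0-based half-open; a summit
#'   exactly at `end` is outside).
#' @return Integer count.
#' @export
tally_region <- function(peaks, region) {
  stopifnot(inherits(region, "region_interval"))
  sum(peaks$contig_id == region$contig_id &
        peaks$summit >= region$start & peaks$summit < region$end)
}

#' Check for binding in the regulator's own promoter
#'
#' Many MarR-family regulators repress their own operon; a peak assigned
#' to the regulator gene (or its operon leader) indicates autoregulation.
#'
#' @param peaks A `peak_set`.
#' @param genes Gene table.
#' @param regulator_gene_id Gene id of the regulator; must exist in
#'   `genes`.
#' @param rule A [promoter_rule()].
#' @param operon_map Optional operon map (see
#'   [assign_peaks_to_genes()]).
#' @return List with `autoregulated` (logical) and `assignments` (the
#'   matching assignment rows).
#' @export
autoregulation_check <- function(peaks, genes, regulator_gene_id,
                                 rule = promoter_rule(),
                                 operon_map = NULL) {
  if (!regulator_gene_id %in% genes$gene_id) {
    stop("unknown regulator gene id: ", regulator_gene_id)
  }
  target_id <- regulator_gene_id
  if (!is.null(operon_map)) {
    m <- match(regulator_gene_id, operon_map$gene_id)
    if (!is.na(m)) target_id <- operon_map$leader_id[m]
  }
  asg <- assign_peaks_to_genes(peaks, genes, rule, operon_map)
  hits <- asg[!is.na(asg$gene_id) & asg$gene_id == target_id, , drop = FALSE]
  list(autoregulated = nrow(hits) > 0L, assignments = hits)
}
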
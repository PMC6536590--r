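# Scoring pipeline output against planted ground truth.

#' Match called peaks to planted sites one-to-one
#'
#' Greedy nearest-neighbour matching on |summit - planted center|, up to
#' `max_dist`; each peak and each site is used at most once.
#'
#' @param peaks A `peak_set` with summits.
#' @param truth A `synthetic_truth` from [plant_sites()].
#' @param max_dist Maximum summit-to-center distance for a match
#'   (default 250 bp, about four times the enrichment spread).
#' @return data.frame with `site_id`, `peak_id`, `center`, `summit` and
#'   `dist`.
#' @export
match_peaks_to_sites <- function(peaks, truth, max_dist = 250L) {
  sites <- truth$sites
  if (nrow(peaks) == 0L || nrow(sites) == 0L) {
    return(data.frame(site_id = character(0), peak_id = integer(0),
                      center = integer(0), summit = integer(0),
                      dist = integer(0)))
  }
  d <- abs(outer(sites$center, peaks$summit, "-"))
  same_contig <- outer(sites$contig_id, peaks$contig_id, "==")
  d[!same_contig | d > max_dist] <- NA
  pairs <- which(!is.na(d), arr.ind = TRUE)
  if (nrow(pairs) == 0L) {
    return(data.frame(site_id = character(0), peak_id = integer(0),
                      center = integer(0), summit = integer(0),
                      dist = integer(0)))
  }
  ord <- order(d[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_site <- logical(nrow(sites)); used_peak <- logical(nrow(peaks))
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    si <- pairs[k, 1L]; pi <- pairs[k, 2L]
    if (used_site[si] || used_peak[pi]) next
    used_site[si] <- TRUE; used_peak[pi] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      site_id = sites$site_id[si], peak_id = pi,
      center = sites$center[si], summit = peaks$summit[pi],
      dist = abs(sites$center[si] - peaks$summit[pi]))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Recall, precision and summit accuracy of peak calling
#'
#' @inheritParams match_peaks_to_sites
#' @param summit_tol Summit-error tolerance in bp (default 15).
#' @return List with `recall`, `precision`,
#'   `summit_within_tol_fraction` (over recovered sites), `n_peaks`,
#'   `n_sites` and the `matches` table.
#' @export
peak_recovery_stats <- function(peaks, truth, max_dist = 250L,
                                summit_tol = 15L) {
  m <- match_peaks_to_sites(peaks, truth, max_dist)
  n_sites <- nrow(truth$sites)
  n_peaks <- nrow(peaks)
  list(
    recall = if (n_sites) nrow(m) / n_sites else NA_real_,
    precision = if (n_peaks) nrow(m) / n_peaks else NA_real_,
    summit_within_tol_fraction =
      if (nrow(m)) mean(m$dist <= summit_tol) else NA_real_,
    n_peaks = n_peaks, n_sites = n_sites, matches = m
  )
}

#' Sensitivity and specificity of direct-target classification
#'
#' A gene counts as a called direct target when its class is
#' `direct_repressed` or `direct_activated`; truth is the
#' `is_direct_target` flag of the expression simulation.
#'
#' @param calls Output of [classify_targets()].
#' @param effects `effects` table from [simulate_expression()].
#' @return List with `sensitivity`, `specificity`, `n_true_targets`,
#'   `n_called_direct`.
#' @export
target_recovery_stats <- function(calls, effects) {
  stopifnot(all(calls$gene_id %in% effects$gene_id))
  truth_direct <- effects$is_direct_target[
    match(calls$gene_id, effects$gene_id)]
  called_direct <- calls$class %in% c("direct_repressed",
                                      "direct_activated")
  list(
    sensitivity = if (any(truth_direct))
      mean(called_direct[truth_direct]) else NA_real_,
    specificity = if (any(!truth_direct))
      mean(!called_direct[!truth_direct]) else NA_real_,
    n_true_targets = sum(truth_direct),
    n_called_direct = sum(called_direct)
  )
}

#' Levenshtein distance between two sequences
#'
#' Thin wrapper over [utils::adist()], used to compare a recovered motif
#' consensus with the planted one.
#' @param a,b Character scalars.
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}
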
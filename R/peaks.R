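# Binding-region detection: rolling-mean smoothing of the coverage track,
# thresholding at a fold of the genome-wide mean coverage, segmentation of
# supra-threshold windows into peaks, summit localization, and extraction
# of 100-bp summit-centered sequence windows.

#' Smoothing parameters for the rolling mean
#'
#' @param window_bp Window size in bp (default 50).
#' @param step_bp Step between window starts in bp (default 10).
#' @export
smoothing_params <- function(window_bp = 50L, step_bp = 10L) {
  window_bp <- as.integer(window_bp); step_bp <- as.integer(step_bp)
  stopifnot(step_bp >= 1L, window_bp >= step_bp)
  list(window_bp = window_bp, step_bp = step_bp)
}

#' Rolling-mean smoothing of a coverage track
#'
#' Windows are anchored on a fixed step grid: window k covers raw bases
#' `[k*step, k*step + window)` and is reported at its center coordinate
#' `k*step + floor(window/2)`. The final partial windows are truncated at
#' the contig end (their mean is over the remaining bases), or wrap through
#' the origin when `circular = TRUE`.
#'
#' @param track A [coverage_track()].
#' @param params [smoothing_params()].
#' @param circular Wrap the trailing windows through the origin.
#' @return A `smoothed_track`: list with `contig_id`, `positions` (window
#'   centers, 0-based), `values` (window means) and `params`.
#' @export
rolling_mean <- function(track, params = smoothing_params(),
                         circular = FALSE) {
  stopifnot(inherits(track, "coverage_track"))
  v <- track$values
  L <- length(v)
  w <- params$window_bp
  step <- params$step_bp
  if (L < w) stop("contig shorter than smoothing window (", L, " < ", w, ")")
  starts <- seq.int(0L, L - 1L, by = step)
  cs <- c(0, cumsum(v))
  ends <- starts + w
  if (circular) {
    wrap <- ends > L
    sums <- numeric(length(starts))
    sums[!wrap] <- cs[ends[!wrap] + 1L] - cs[starts[!wrap] + 1L]
    if (any(wrap)) {
      sums[wrap] <- (cs[L + 1L] - cs[starts[wrap] + 1L]) +
        cs[ends[wrap] - L + 1L]
    }
    vals <- sums / w
  } else {
    ends <- pmin(ends, L)
    vals <- (cs[ends + 1L] - cs[starts + 1L]) / (ends - starts)
  }
  structure(
    list(contig_id = track$contig_id,
         positions = starts + w %/% 2L,
         values = vals,
         params = params),
    class = "smoothed_track"
  )
}

#' Genome-wide mean raw coverage
#'
#' Length-weighted mean over all contigs' raw per-base coverage; this is
#' the reference against which the fold threshold is applied.
#'
#' @param tracks A single [coverage_track()] or a list of them.
#' @export
genome_mean <- function(tracks) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1L)
  total <- sum(vapply(tracks, function(t) sum(t$values), numeric(1)))
  bases <- sum(vapply(tracks, function(t) length(t$values), numeric(1)))
  total / bases
}

#' Peak-calling parameters
#'
#' @param fold_threshold Smoothed coverage must exceed this fold of the
#'   genome-wide mean (default 3).
#' @param merge_gap_bp Supra-threshold window groups separated by at most
#'   this many bp of sub-threshold grid are merged (default 50).
#' @param min_windows Minimum number of supra-threshold windows per peak
#'   (default 2); suppresses single-window noise.
#' @export
peak_call_params <- function(fold_threshold = 3, merge_gap_bp = 50L,
                             min_windows = 2L) {
  stopifnot(fold_threshold > 1, merge_gap_bp >= 0L, min_windows >= 1L)
  list(fold_threshold = fold_threshold,
       merge_gap_bp = as.integer(merge_gap_bp),
       min_windows = as.integer(min_windows))
}

#' Call peaks from a smoothed track
#'
#' Window positions with smoothed value strictly greater than
#' `fold_threshold` times the genome-wide mean are marked; consecutive
#' marked positions are grouped, groups whose marked windows are separated
#' by at most `merge_gap_bp` of unmarked grid are merged, and groups with
#' fewer than `min_windows` marked windows are discarded. The peak span
#' runs from the first marked window's start to the last marked window's
#' end; the summit is the marked window center with maximal smoothed
#' value (ties to the smallest coordinate).
#'
#' @param smoothed A `smoothed_track` from [rolling_mean()].
#' @param gmean Genome-wide mean raw coverage ([genome_mean()]); must be
#'   positive.
#' @param params [peak_call_params()].
#' @param contig_length Optional contig length used to clip the final
#'   window's end; defaults to just past the last window.
#' @return A `peak_set` data.frame sorted by start, with columns
#'   `contig_id`, `start`, `end`, `summit`, `max_smoothed`,
#'   `fold_over_mean`, `n_windows`, and attribute `genome_mean`.
#' @export
call_peaks <- function(smoothed, gmean, params = peak_call_params(),
                       contig_length = NULL) {
  stopifnot(inherits(smoothed, "smoothed_track"))
  if (!is.finite(gmean) || gmean <= 0) {
    stop("genome mean coverage must be positive; threshold undefined")
  }
  w <- smoothed$params$window_bp
  step <- smoothed$params$step_bp
  half <- w %/% 2L
  pos <- smoothed$positions
  val <- smoothed$values
  if (is.null(contig_length)) contig_length <- max(pos) - half + w
  thr <- params$fold_threshold * gmean
  marked <- which(val > thr)
  empty <- data.frame(
    contig_id = character(0), start = integer(0), end = integer(0),
    summit = integer(0), max_smoothed = numeric(0),
    fold_over_mean = numeric(0), n_windows = integer(0)
  )
  if (length(marked) == 0L) {
    return(structure(empty, genome_mean = gmean,
                     class = c("peak_set", "data.frame")))
  }
  # group marked windows; bridge unmarked grid spans of <= merge_gap_bp
  gaps <- diff(pos[marked]) - step
  grp <- cumsum(c(0L, as.integer(gaps > params$merge_gap_bp)))
  groups <- split(marked, grp)
  rows <- lapply(groups, function(ix) {
    if (length(ix) < params$min_windows) return(NULL)
    imax <- ix[which.max(val[ix])]
    data.frame(
      contig_id = smoothed$contig_id,
      start = pos[ix[1L]] - half,
      end = min(pos[ix[length(ix)]] - half + w, contig_length),
      summit = pos[imax],
      max_smoothed = val[imax],
      fold_over_mean = val[imax] / gmean,
      n_windows = length(ix)
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  peaks <- if (length(rows) == 0L) empty else do.call(rbind, rows)
  rownames(peaks) <- NULL
  peaks <- peaks[order(peaks$start), , drop = FALSE]
  structure(peaks, genome_mean = gmean,
            class = c("peak_set", "data.frame"))
}

#' Extract summit-centered sequence windows for a peak set
#'
#' Each window covers `[summit - flank_bp, summit + flank_bp)` — with the
#' default flank of 50 bp, a 100-bp fragment centered on the peak maximum.
#' On linear contigs windows are clipped at the contig bounds and the peak
#' flagged `truncated`; on circular contigs they wrap through the origin.
#'
#' @param peaks A `peak_set` from [call_peaks()].
#' @param contigs Named list of [contig()] objects.
#' @param flank_bp Flank on each side of the summit (default 50).
#' @return The peak set with added columns `window_start`, `window_end`,
#'   `window_seq` and `truncated`.
#' @export
extract_peak_windows <- function(peaks, contigs, flank_bp = 50L) {
  flank_bp <- as.integer(flank_bp)
  n <- nrow(peaks)
  ws <- integer(n); we <- integer(n)
  seqs <- character(n); trunc <- logical(n)
  for (i in seq_len(n)) {
    ct <- contigs[[peaks$contig_id[i]]]
    if (is.null(ct)) stop("peak on unknown contig: ", peaks$contig_id[i])
    s <- peaks$summit[i] - flank_bp
    e <- peaks$summit[i] + flank_bp
    if (ct$circular) {
      seqs[i] <- extract_sequence(ct, s, e, circular_wrap = TRUE)
      ws[i] <- s; we[i] <- e
    } else {
      cs <- max(0L, s); ce <- min(ct$length, e)
      trunc[i] <- (cs != s) || (ce != e)
      seqs[i] <- extract_sequence(ct, cs, ce, circular_wrap = FALSE)
      ws[i] <- cs; we[i] <- ce
    }
  }
  peaks$window_start <- ws
  peaks$window_end <- we
  peaks$window_seq <- seqs
  peaks$truncated <- trunc
  peaks
}
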
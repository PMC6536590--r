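# Independent loop-based oracles and small fixture builders shared by
# the tests. The oracles deliberately avoid the package's cumsum /
# vectorized code paths.

# per-window mean by explicit subsetting
oracle_rolling_mean <- function(values, window_bp, step_bp) {
  L <- length(values)
  starts <- seq.int(0L, L - 1L, by = step_bp)
  vals <- vapply(starts, function(s) {
    e <- min(s + window_bp, L)
    mean(values[(s + 1L):e])
  }, numeric(1))
  list(positions = starts + window_bp %/% 2L, values = vals)
}

# threshold-scan segmentation by an explicit left-to-right walk
oracle_call_peaks <- function(positions, values, gmean, window_bp,
                              step_bp, fold_threshold = 3,
                              merge_gap_bp = 50L, min_windows = 2L,
                              contig_length) {
  half <- window_bp %/% 2L
  marked <- which(values > fold_threshold * gmean)
  groups <- list()
  cur <- integer(0)
  for (i in marked) {
    if (length(cur) == 0L) {
      cur <- i
    } else if (positions[i] - positions[cur[length(cur)]] - step_bp <=
               merge_gap_bp) {
      cur <- c(cur, i)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- i
    }
  }
  if (length(cur)) groups[[length(groups) + 1L]] <- cur
  empty <- data.frame(start = integer(0), end = integer(0),
                      summit = integer(0), max_smoothed = numeric(0),
                      n_windows = integer(0))
  rows <- list()
  for (g in groups) {
    if (length(g) < min_windows) next
    best <- g[1L]
    for (i in g) if (values[i] > values[best]) best <- i
    rows[[length(rows) + 1L]] <- data.frame(
      start = positions[g[1L]] - half,
      end = min(positions[g[length(g)]] - half + window_bp,
                contig_length),
      summit = positions[best],
      max_smoothed = values[best],
      n_windows = length(g))
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# small annotated test genome: three genes covering divergent,
# convergent and tandem layouts on a 6-kb contig
tiny_annotation <- function() {
  ct <- contig("chr", paste(rep("ACGT", 1500), collapse = ""))
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    contig_id = "chr",
    start = c(1000L, 2500L, 4500L),
    end = c(2000L, 3500L, 5500L),
    strand = c("-", "+", "+"),
    product = NA_character_,
    stringsAsFactors = FALSE
  )
  genome_annotation(list(ct), genes)
}

# minimal peak_set with given summits
peaks_at <- function(summits, contig_id = "chr") {
  structure(
    data.frame(contig_id = contig_id,
               start = summits - 100L, end = summits + 100L,
               summit = summits, max_smoothed = 100,
               fold_over_mean = 5, n_windows = 10L),
    genome_mean = 20, class = c("peak_set", "data.frame"))
}

# one full default-condition pipeline run, cached across test files
default_run_cache <- new.env(parent = emptyenv())
default_run <- function(seed = 1L) {
  key <- as.character(seed)
  if (is.null(default_run_cache[[key]])) {
    default_run_cache[[key]] <- run_pipeline(pipeline_config(seed = seed))
  }
  default_run_cache[[key]]
}
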
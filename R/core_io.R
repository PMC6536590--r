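# Domain containers and readers/writers for the standard genomics formats.
#
# All internal coordinates are 0-based half-open. GFF3 (1-based inclusive)
# and BED/bedGraph (0-based half-open) are converted at the boundary, once.

#' Create a contig
#'
#' A contig is a single chromosome or plasmid sequence. Bacterial
#' chromosomes are typically circular; circularity controls whether
#' sequence extraction and smoothing windows wrap through the origin.
#'
#' @param id Non-empty contig identifier.
#' @param sequence Character scalar over `A,C,G,T,N` (lowercase accepted,
#'   stored uppercase).
#' @param circular Logical; treat the contig as circular (default linear).
#' @return An object of class `contig`: a list with `id`, `sequence`,
#'   `length` and `circular`.
#' @export
contig <- function(id, sequence, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    stop("contig '", id, "': sequence contains non-ACGTN characters: ",
         substr(bad, 1L, 10L))
  }
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         circular = isTRUE(circular)),
    class = "contig"
  )
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("<contig> %s: %d bp (%s)\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read contigs from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param circular Logical scalar or named logical vector (by contig id)
#'   declaring circularity; defaults to linear.
#' @return Named list of [contig()] objects, in file order.
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  contigs <- lapply(seq_along(seqs), function(i) {
    circ <- if (length(circular) == 1L && is.null(names(circular))) {
      circular
    } else {
      isTRUE(circular[[ids[i]]])
    }
    contig(ids[i], as.character(seqs[[i]]), circular = circ)
  })
  names(contigs) <- ids
  contigs
}

#' Read gene features from a GFF3 file
#'
#' Reads `gene` (or, lacking genes, `CDS`) features and converts their
#' 1-based inclusive coordinates to the internal 0-based half-open
#' convention. The gene key is the `locus_tag` attribute when present,
#' else `ID`.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand` and `product`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  types <- as.character(gr$type)
  keep <- types == "gene"
  if (!any(keep)) keep <- types == "CDS"
  gr <- gr[keep]
  if (length(gr) == 0L) stop("no gene or CDS features in ", path)
  mc <- S4Vectors::mcols(gr)
  ids <- if ("locus_tag" %in% names(mc)) as.character(mc$locus_tag) else
    rep(NA_character_, length(gr))
  fallback <- if ("ID" %in% names(mc)) as.character(mc$ID) else
    rep(NA_character_, length(gr))
  ids[is.na(ids)] <- fallback[is.na(ids)]
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1L]
    stop("feature without locus_tag or ID at ",
         as.character(GenomicRanges::seqnames(gr))[bad], ":",
         GenomicRanges::start(gr)[bad], "-", GenomicRanges::end(gr)[bad])
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  prod <- if ("product" %in% names(mc)) as.character(mc$product) else
    rep(NA_character_, length(gr))
  genes <- data.frame(
    gene_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = prod,
    stringsAsFactors = FALSE
  )
  if (any(genes$start >= genes$end)) {
    stop("feature with end < start in ", path)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene features must have strand '+' or '-'")
  }
  genes
}

#' Bundle contigs, genes and named regions into a genome annotation
#'
#' @param contigs Named list of [contig()] objects.
#' @param genes Gene table as returned by [read_gff3()] (may have 0 rows).
#' @param regions Named list of [region_interval()] objects (e.g. a
#'   prophage span).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(contigs, genes, regions = list()) {
  stopifnot(is.list(contigs), length(contigs) >= 1L)
  lens <- vapply(contigs, function(ct) ct$length, integer(1))
  names(lens) <- vapply(contigs, function(ct) ct$id, character(1))
  names(contigs) <- names(lens)
  if (nrow(genes) > 0L) {
    if (!all(genes$contig_id %in% names(lens))) {
      stop("gene references unknown contig")
    }
    if (any(genes$start < 0L) || any(genes$end > lens[genes$contig_id])) {
      stop("gene interval outside contig bounds")
    }
    if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  }
  for (r in regions) {
    if (!r$contig_id %in% names(lens) || r$start < 0L ||
        r$end > lens[[r$contig_id]]) {
      stop("region '", r$name, "' outside contig bounds")
    }
  }
  structure(list(contigs = contigs, genes = genes, regions = regions),
            class = "genome_annotation")
}

#' Create a named region interval (0-based half-open)
#'
#' @param contig_id Contig identifier.
#' @param start,end 0-based half-open interval with `start < end`.
#' @param name Region name (e.g. `"prophage"`).
#' @export
region_interval <- function(contig_id, start, end, name) {
  stopifnot(start < end)
  structure(list(contig_id = contig_id, start = as.integer(start),
                 end = as.integer(end), name = name),
            class = "region_interval")
}

#' Create a per-base coverage track
#'
#' @param contig_id Contig the track belongs to.
#' @param values Non-negative numeric vector, one value per base.
#' @export
coverage_track <- function(contig_id, values) {
  stopifnot(is.numeric(values))
  if (any(values < 0)) stop("coverage values must be non-negative")
  structure(list(contig_id = contig_id, values = as.numeric(values)),
            class = "coverage_track")
}

#' Read a bedGraph file into dense per-base coverage tracks
#'
#' Intervals are 0-based half-open; bases not covered by any interval get
#' coverage 0. Overlapping intervals, intervals beyond the contig end and
#' negative values are errors.
#'
#' @param path Path to a bedGraph file.
#' @param contigs Named list of [contig()] objects defining contig lengths.
#' @return Named list of [coverage_track()] objects, one per contig.
#' @export
read_bedgraph <- function(path, contigs) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lens <- vapply(contigs, function(ct) ct$length, integer(1))
  names(lens) <- vapply(contigs, function(ct) ct$id, character(1))
  tracks <- lapply(names(lens), function(id) {
    coverage_track(id, numeric(lens[[id]]))
  })
  names(tracks) <- names(lens)
  if (file.size(path) == 0L) return(tracks)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) return(tracks)
  if (any(gr$score < 0)) stop("negative coverage value in ", path)
  seqs <- as.character(GenomicRanges::seqnames(gr))
  if (!all(seqs %in% names(lens))) {
    stop("bedGraph interval on unknown contig: ",
         paste(setdiff(unique(seqs), names(lens)), collapse = ", "))
  }
  starts <- GenomicRanges::start(gr) - 1L  # back to 0-based half-open
  ends <- GenomicRanges::end(gr)
  if (any(ends > lens[seqs])) stop("bedGraph interval beyond contig length")
  if (!GenomicRanges::isDisjoint(gr)) {
    stop("overlapping bedGraph intervals in ", path)
  }
  widths <- ends - starts
  for (id in unique(seqs)) {
    sel <- seqs == id
    idx <- sequence(widths[sel], from = starts[sel] + 1L)
    tracks[[id]]$values[idx] <- rep(gr$score[sel], widths[sel])
  }
  tracks
}

#' Write a peak set as BED6 plus a summit table
#'
#' The BED score column is the fold-over-mean rounded to two decimals.
#' A companion tab-separated file records, per peak, the summit coordinate
#' and maximal smoothed coverage.
#'
#' @param peaks A peak set data.frame from [call_peaks()].
#' @param path Output BED path.
#' @param summit_path Output path for the summit table; defaults to the
#'   BED path with a `_summits.tsv` suffix.
#' @return Invisibly, the BED path.
#' @export
write_peaks_bed <- function(peaks, path,
                            summit_path = sub("\\.bed$", "", path)) {
  if (identical(summit_path, sub("\\.bed$", "", path))) {
    summit_path <- paste0(summit_path, "_summits.tsv")
  }
  n <- nrow(peaks)
  bed <- if (n == 0L) character(0) else sprintf(
    "%s\t%d\t%d\tpeak_%d\t%.2f\t.",
    peaks$contig_id, peaks$start, peaks$end, seq_len(n),
    peaks$fold_over_mean
  )
  writeLines(bed, path)
  summits <- data.frame(
    peak_id = if (n == 0L) character(0) else sprintf("peak_%d", seq_len(n)),
    contig_id = peaks$contig_id,
    summit = peaks$summit,
    max_smoothed = peaks$max_smoothed,
    fold_over_mean = peaks$fold_over_mean
  )
  utils::write.table(summits, summit_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Extract a subsequence from a contig
#'
#' @param ct A [contig()].
#' @param start,end 0-based half-open coordinates; `start < end`.
#' @param circular_wrap If `TRUE`, coordinates outside `[0, length)` wrap
#'   modulo the contig length; otherwise they are an error.
#' @return Character scalar of length `end - start`.
#' @export
extract_sequence <- function(ct, start, end,
                             circular_wrap = ct$circular) {
  stopifnot(inherits(ct, "contig"), start < end)
  L <- ct$length
  len <- end - start
  if (!circular_wrap) {
    if (start < 0 || end > L) {
      stop("coordinates [", start, ",", end, ") outside linear contig '",
           ct$id, "' of length ", L)
    }
    return(substr(ct$sequence, start + 1L, end))
  }
  if (len > L) stop("requested length exceeds contig length")
  s0 <- ((start %% L) + L) %% L
  if (s0 + len <= L) {
    return(substr(ct$sequence, s0 + 1L, s0 + len))
  }
  paste0(substr(ct$sequence, s0 + 1L, L),
         substr(ct$sequence, 1L, len - (L - s0)))
}

#' Reverse complement of a DNA string
#'
#' @param x Character scalar over `A,C,G,T,N`.
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
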
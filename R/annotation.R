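#' Construct a genome annotation object
#'
#' A `genome_annotation` bundles reference sequences with strand-annotated
#' genes decomposed into UTR/exon intervals. All internal coordinates are
#' 1-based closed (the GRanges convention); conversions to the 0-based
#' half-open BED/bedGraph conventions happen only at file boundaries.
#'
#' @param sequences named character vector, chromosome name -> A/C/G/T string.
#' @param intervals data.frame with columns `gene_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `start`, `end` (1-based closed), `type`
#'   (`"UTR"` or `"exon"`). One row per interval.
#' @param polyruns optional data.frame of planted homopolymer runs
#'   (`chrom`, `start`, `end`, `base`); recorded for simulation truth.
#' @return An object of class `genome_annotation` whose `genes` table carries
#'   an `unambiguous` flag per interval: intervals are split at overlaps with
#'   other genes so that every interval either overlaps no other gene
#'   (unambiguous) or lies entirely within an overlap (ambiguous).
#' @export
genome_annotation <- function(sequences, intervals, polyruns = NULL) {
  stopifnot(is.character(sequences), length(names(sequences)) == length(sequences))
  intervals <- as.data.frame(intervals)
  required <- c("gene_id", "chrom", "strand", "start", "end", "type")
  if (!all(required %in% names(intervals))) {
    stop("intervals must have columns: ", paste(required, collapse = ", "))
  }
  if (!all(intervals$chrom %in% names(sequences))) {
    stop("interval chromosome not present in sequences")
  }
  if (any(intervals$start < 1) ||
      any(intervals$end > nchar(sequences)[match(intervals$chrom, names(sequences))])) {
    stop("interval outside chromosome bounds")
  }
  if (any(intervals$end < intervals$start)) stop("interval end < start")
  if (!all(intervals$type %in% c("UTR", "exon"))) stop("interval type must be UTR or exon")
  if (!all(intervals$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")

  # per-gene non-overlap and sortedness
  by_gene <- split(intervals, intervals$gene_id)
  for (g in by_gene) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)])) {
      stop("overlapping intervals within gene ", g$gene_id[1])
    }
  }

  obj <- structure(
    list(sequences = sequences,
         genes = annotate_ambiguity(intervals),
         polyruns = polyruns),
    class = "genome_annotation"
  )
  obj
}

#' Split gene intervals at cross-gene overlaps and label ambiguity
#'
#' An interval is unambiguous when it overlaps no UTR/exonic interval of any
#' other gene. Intervals partially overlapping another gene are split at the
#' overlap boundaries so the label is exact per position.
#'
#' @param intervals interval data.frame (see [genome_annotation()]).
#' @return The interval table, possibly with intervals split, sorted by gene
#'   then start, with a logical `unambiguous` column.
#' @keywords internal
annotate_ambiguity <- function(intervals) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(intervals$start, intervals$end)
  )
  dj <- GenomicRanges::disjoin(gr)
  hits <- GenomicRanges::findOverlaps(dj, gr)
  genes_per_piece <- tapply(
    intervals$gene_id[S4Vectors::subjectHits(hits)],
    S4Vectors::queryHits(hits),
    function(x) length(unique(x))
  )
  piece_unamb <- genes_per_piece <= 1L

  # map each original interval to its disjoint pieces
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    idx <- S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]
    data.frame(
      gene_id = intervals$gene_id[i],
      chrom = intervals$chrom[i],
      strand = intervals$strand[i],
      start = GenomicRanges::start(dj)[idx],
      end = GenomicRanges::end(dj)[idx],
      type = intervals$type[i],
      unambiguous = unname(piece_unamb[as.character(idx)]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$gene_id, out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$sequences), "chromosome(s),",
      length(unique(x$genes$gene_id)), "gene(s),",
      nrow(x$genes), "UTR/exon interval(s)\n")
  cat("  chromosome lengths:",
      paste(names(x$sequences), nchar(x$sequences), sep = "=", collapse = ", "),
      "\n")
  cat("  ambiguous intervals:", sum(!x$genes$unambiguous), "\n")
  invisible(x)
}

#' Gene intervals as a GRanges
#'
#' @param annotation a `genome_annotation`.
#' @param unambiguous_only keep only intervals labeled unambiguous.
#' @return GRanges with `gene_id`, `type`, `unambiguous` metadata and the gene
#'   strand.
#' @export
annotation_granges <- function(annotation, unambiguous_only = FALSE) {
  g <- annotation$genes
  if (unambiguous_only) g <- g[g$unambiguous, ]
  GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(g$start, g$end),
    strand = g$strand,
    gene_id = g$gene_id, type = g$type, unambiguous = g$unambiguous
  )
}

#' Reference base(s) at given positions
#'
#' @param annotation a `genome_annotation`.
#' @param chrom chromosome names (recycled against `pos`).
#' @param pos 1-based positions.
#' @return Character vector of bases.
#' @export
reference_base <- function(annotation, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  lens <- nchar(annotation$sequences)[match(chrom, names(annotation$sequences))]
  if (anyNA(lens) || any(pos < 1 | pos > lens)) {
    stop("position outside reference bounds")
  }
  substring(annotation$sequences[chrom], pos, pos)
}

#' Find maximal homopolymer runs in a sequence
#'
#' @param seq A/C/G/T string.
#' @param min_length minimal run length (default 7).
#' @return data.frame with `start`, `end` (1-based closed) and `base`.
#' @export
find_homopolymer_runs <- function(seq, min_length = 7L) {
  r <- rle(strsplit(seq, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_length
  data.frame(start = starts[keep], end = ends[keep], base = r$values[keep],
             stringsAsFactors = FALSE)
}

#' Boundary bases of annotated exon/UTR intervals
#'
#' Splice-junction-adjacent artifact filtering measures distance to the
#' terminal exonic base on each side of every annotated interval.
#'
#' @param annotation a `genome_annotation`.
#' @param extra optional data.frame of additional junction boundaries
#'   (`chrom`, `pos`), e.g. per-accession junction calls, merged in.
#' @return data.frame with `chrom`, `pos` (one row per boundary base).
#' @export
exon_boundaries <- function(annotation, extra = NULL) {
  g <- annotation$genes
  out <- data.frame(
    chrom = rep(g$chrom, 2L),
    pos = c(g$start, g$end),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) out <- rbind(out, extra[, c("chrom", "pos")])
  unique(out)
}

#' Enumerate annotated gene positions
#'
#' @param annotation a `genome_annotation`.
#' @param unambiguous_only restrict to unambiguous intervals.
#' @return data.table with `chrom`, `pos`, `gene_id`, `type`, `unambiguous`,
#'   `strand` and the forward-strand reference base `ref`. Positions inside
#'   overlapping genes appear once per gene.
#' @export
annotation_positions <- function(annotation, unambiguous_only = FALSE) {
  g <- annotation$genes
  if (unambiguous_only) g <- g[g$unambiguous, ]
  n <- g$end - g$start + 1L
  dt <- data.table::data.table(
    chrom = rep(g$chrom, n),
    pos = unlist(lapply(seq_len(nrow(g)), function(i) g$start[i]:g$end[i])),
    gene_id = rep(g$gene_id, n),
    type = rep(g$type, n),
    unambiguous = rep(g$unambiguous, n),
    strand = rep(g$strand, n)
  )
  dt[, ref := reference_base(annotation, chrom, pos)]
  dt[]
}
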
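#' Site-level pass table
#'
#' Per accession x position: raw depth and whether the site passes the
#' site-level quality filters (coverage at or above the cutoff) used for
#' effective-gene-length and depth normalization.
#'
#' @param pileup site-observation table.
#' @param min_coverage coverage cutoff (default 40).
#' @return data.table with `accession`, `chrom`, `pos`, `depth`, `passes`.
#' @export
site_pass_table <- function(pileup, min_coverage = 40L) {
  pu <- data.table::as.data.table(pileup)
  pu[, .(accession, chrom, pos, depth = cov, passes = cov >= min_coverage)]
}

required_forward_base <- function(base, gene_strand, strand_class) {
  stopifnot(all(base %in% PYRIMIDINES))
  on_gene_strand <- strand_class == "coding"
  pyr_on_plus <- ifelse(on_gene_strand, gene_strand == "+", gene_strand == "-")
  ifelse(pyr_on_plus, base, comp_base(base))
}

gene_position_table <- function(annotation) {
  pos <- annotation_positions(annotation, unambiguous_only = TRUE)
  unique(pos, by = c("gene_id", "chrom", "pos"))
}

#' Base-aware effective gene length
#'
#' The number of unambiguous UTR/exonic positions of a gene that pass all
#' site-level quality filters in at least one accession and whose reference
#' base, read on the strand implied by the gene strand and strand class,
#' equals the required pyrimidine.
#'
#' @param annotation a [genome_annotation()].
#' @param gene_id gene identifier.
#' @param base `"C"` or `"T"` (the pyrimidine of the mutation type).
#' @param strand_class `"coding"` or `"template"`.
#' @param site_pass table from [site_pass_table()].
#' @return Integer count (0 when no accession covers the gene).
#' @export
effective_gene_length <- function(annotation, gene_id, base, strand_class,
                                  site_pass) {
  if (!base %in% PYRIMIDINES) stop("base must be C or T")
  tab <- as.data.frame(gene_base_table(annotation, site_pass))
  row <- tab[tab$gene_id == gene_id & tab$base == base &
               tab$strand_class == strand_class, ]
  if (nrow(row) == 0L) return(0L)
  as.integer(row$b)
}

#' Base-aware normalized transcriptional depth
#'
#' Sum of per-accession, per-position depths over the passing positions that
#' enter the effective gene length, divided by the effective gene length
#' (reads per site, summed across accessions).
#'
#' @inheritParams effective_gene_length
#' @return Numeric; `NA` when the effective length is zero (row excluded
#'   from modeling).
#' @export
normalized_depth <- function(annotation, gene_id, base, strand_class,
                             site_pass) {
  tab <- as.data.frame(gene_base_table(annotation, site_pass))
  row <- tab[tab$gene_id == gene_id & tab$base == base &
               tab$strand_class == strand_class, ]
  if (nrow(row) == 0L || row$b == 0L) return(NA_real_)
  row$d / row$b
}

# per gene x pyrimidine x strand_class: b (union length) and d (summed depth)
gene_base_table <- function(annotation, site_pass) {
  pos <- gene_position_table(annotation)
  sp <- data.table::as.data.table(site_pass)[passes == TRUE]
  agg <- sp[, .(depth_sum = sum(as.numeric(depth)), n_pass = .N),
            by = .(chrom, pos)]
  merged <- merge(pos, agg, by = c("chrom", "pos"), all.x = TRUE)
  merged[is.na(depth_sum), `:=`(depth_sum = 0, n_pass = 0L)]
  combos <- data.table::CJ(base = PYRIMIDINES,
                           strand_class = c("coding", "template"))
  out <- list()
  for (i in seq_len(nrow(combos))) {
    base_i <- combos$base[i]; class_i <- combos$strand_class[i]
    fb <- required_forward_base(rep(base_i, nrow(merged)), merged$strand,
                                rep(class_i, nrow(merged)))
    sel <- merged$ref == fb & merged$n_pass >= 1L
    g <- merged[sel, .(b = .N, d = sum(depth_sum)), by = gene_id]
    if (nrow(g)) {
      g[, `:=`(base = ..base_i, strand_class = ..class_i)]
      out[[length(out) + 1L]] <- g
    }
  }
  data.table::rbindlist(out)
}

#' Collapse a mutation to its pyrimidine type and transcriptional strand
#'
#' Mutations are expressed in the six pyrimidine types (C>A, C>G, C>T, T>A,
#' T>C, T>G); purine-reference mutations are complemented. The strand class
#' is `template` when the reference pyrimidine resides on the strand
#' opposite the annotated gene strand, `coding` when on the same strand.
#'
#' @param ref,alt reference / alternate bases on the forward strand.
#' @param gene_strand `"+"` or `"-"` per mutation.
#' @return data.frame with `mutation_type` and `strand_class`.
#' @export
assign_strand <- function(ref, alt, gene_strand) {
  if (!all(ref %in% BASES) || !all(alt %in% BASES)) {
    stop("ref and alt must be A, C, G or T")
  }
  stopifnot(all(gene_strand %in% c("+", "-")))
  is_pyr <- ref %in% PYRIMIDINES
  p_ref <- ifelse(is_pyr, ref, comp_base(ref))
  p_alt <- ifelse(is_pyr, alt, comp_base(alt))
  pyr_strand <- ifelse(is_pyr, "+", "-")
  data.frame(
    mutation_type = paste0(p_ref, ">", p_alt),
    strand_class = ifelse(pyr_strand == gene_strand, "coding", "template"),
    stringsAsFactors = FALSE
  )
}

#' GC content of a gene's unambiguous UTR/exonic sequence
#'
#' @param annotation a [genome_annotation()].
#' @param gene_id gene identifier.
#' @return Fraction of G/C bases; `NA` for zero-length support.
#' @export
gc_content <- function(annotation, gene_id) {
  pos <- gene_position_table(annotation)
  b <- pos$ref[pos$gene_id == gene_id]
  if (!length(b)) return(NA_real_)
  mean(b %in% c("G", "C"))
}

gene_intervals_granges <- function(annotation, gene_id) {
  g <- annotation$genes
  g <- g[g$gene_id == gene_id & g$unambiguous, ]
  GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
}

overlap_weighted_sum <- function(gene_gr, track, values) {
  hits <- GenomicRanges::findOverlaps(track, gene_gr)
  if (length(hits) == 0L) return(NA_real_)
  ov <- GenomicRanges::pintersect(track[S4Vectors::queryHits(hits)],
                                  gene_gr[S4Vectors::subjectHits(hits)])
  sum(values[S4Vectors::queryHits(hits)] * GenomicRanges::width(ov))
}

#' Genewise replication-timing signal
#'
#' log2 of the overlap-weighted mean of late/early replication signal
#' ratios over the gene's UTR/exonic intervals:
#' `log2( sum_r (L_r / E_r) o_{r,g} / l_g )` with `l_g` the summed
#' UTR/exonic length.
#'
#' @param annotation a [genome_annotation()].
#' @param gene_id gene identifier.
#' @param early,late GRanges with `score` (early signal must be positive on
#'   overlapping regions). Region boundaries must match between the two.
#' @return Numeric; `NA` when no region overlaps the gene.
#' @export
replication_timing_signal <- function(annotation, gene_id, early, late) {
  stopifnot(length(early) == length(late))
  if (!all(GenomicRanges::start(early) == GenomicRanges::start(late)) ||
      !all(GenomicRanges::end(early) == GenomicRanges::end(late))) {
    stop("early and late tracks must share region boundaries")
  }
  gg <- gene_intervals_granges(annotation, gene_id)
  lg <- sum(GenomicRanges::width(gg))
  hits <- GenomicRanges::findOverlaps(early, gg)
  if (length(hits) == 0L) return(NA_real_)
  e <- early$score[S4Vectors::queryHits(hits)]
  if (any(e <= 0)) stop("early replication signal must be positive over the gene")
  ratio <- late$score / early$score
  s <- overlap_weighted_sum(gg, early, ratio)
  log2(s / lg)
}

#' Genewise chromatin signal
#'
#' Sum over replicate files and regions of signal times overlap with the
#' gene's UTR/exonic intervals, divided by the summed UTR/exonic length.
#' Signals are expected pre-normalized to `[0, 1]`.
#'
#' @param annotation a [genome_annotation()].
#' @param gene_id gene identifier.
#' @param replicates a GRanges with `score`, or a list of such (one per
#'   replicate file; values are summed across replicates).
#' @return Numeric; `NA` when no region of any replicate overlaps the gene.
#' @export
chromatin_signal <- function(annotation, gene_id, replicates) {
  if (methods::is(replicates, "GRanges")) replicates <- list(replicates)
  if (length(replicates) == 0L) stop("no replicate track supplied for mark")
  gg <- gene_intervals_granges(annotation, gene_id)
  lg <- sum(GenomicRanges::width(gg))
  vals <- vapply(replicates, function(tr) {
    overlap_weighted_sum(gg, tr, tr$score)
  }, numeric(1))
  if (all(is.na(vals))) return(NA_real_)
  sum(vals, na.rm = TRUE) / lg
}

#' Build the genewise modeling table
#'
#' One row per gene x strand class per mutation type: mutation count `m`,
#' effective gene length `b`, normalized depth `d_star`, strand class, and
#' the covariate vector (GC content, replication timing, accessibility,
#' methylation, histone marks). Rows with `b = 0` are excluded; covariates
#' are standardized to zero mean / unit variance within each mutation-type
#' table after exclusions (`m`, `b`, `d_star` are left on their natural
#' scales). Genes without track coverage are excluded from that model.
#'
#' @param mutations data.frame of PASS mutations (`chrom`, `pos`, `ref`,
#'   `alt`), e.g. the `pass` element of [call_somatic_mutations()].
#' @param annotation a [genome_annotation()].
#' @param tracks track list as produced by [simulate_tracks()] (element
#'   `tracks`): `replication_timing` with `early`/`late`, plus one GRanges
#'   (or replicate list) per chromatin track.
#' @param site_pass table from [site_pass_table()].
#' @return data.table with columns `mutation_type`, `gene_id`,
#'   `strand_class`, `m`, `b`, `d_star` and the standardized covariates; the
#'   unstandardized covariates are kept in attribute `"unscaled"`.
#' @export
build_feature_table <- function(mutations, annotation, tracks, site_pass) {
  gene_ids <- unique(annotation$genes$gene_id)
  gstrand <- vapply(gene_ids, function(id) {
    annotation$genes$strand[annotation$genes$gene_id == id][1]
  }, character(1))

  # per-gene covariates
  cov_df <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  cov_df$gc_content <- vapply(gene_ids, function(id) gc_content(annotation, id),
                              numeric(1))
  rt <- tracks$replication_timing
  cov_df$replication_timing <- vapply(gene_ids, function(id) {
    replication_timing_signal(annotation, id, rt$early, rt$late)
  }, numeric(1))
  for (tr in CHROMATIN_TRACKS) {
    if (is.null(tracks[[tr]])) stop("no track supplied for ", tr)
    cov_df[[tr]] <- vapply(gene_ids, function(id) {
      chromatin_signal(annotation, id, tracks[[tr]])
    }, numeric(1))
  }

  base_tab <- gene_base_table(annotation, site_pass)

  # assign PASS mutations to genes and strand classes
  mut <- as.data.frame(mutations)
  mcount <- NULL
  if (nrow(mut)) {
    gr <- GenomicRanges::GRanges(mut$chrom, IRanges::IRanges(mut$pos, mut$pos))
    ua <- annotation_granges(annotation, unambiguous_only = TRUE)
    hits <- GenomicRanges::findOverlaps(gr, ua)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    keep <- !duplicated(qh)  # unambiguous => at most one gene
    qh <- qh[keep]; sh <- sh[keep]
    gid <- ua$gene_id[sh]
    asg <- assign_strand(mut$ref[qh], mut$alt[qh], gstrand[gid])
    mcount <- data.table::as.data.table(
      data.frame(gene_id = gid, mutation_type = asg$mutation_type,
                 strand_class = asg$strand_class)
    )[, .(m = .N), by = .(gene_id, mutation_type, strand_class)]
  }

  rows <- list()
  for (mt in MUTATION_TYPES) {
    pyr <- substr(mt, 1L, 1L)
    grid <- data.table::CJ(gene_id = gene_ids,
                           strand_class = c("coding", "template"))
    grid <- merge(grid,
                  base_tab[base == pyr, .(gene_id, strand_class, b, d)],
                  by = c("gene_id", "strand_class"), all.x = TRUE)
    grid[is.na(b), `:=`(b = 0L, d = 0)]
    grid[, d_star := ifelse(b > 0L, d / b, NA_real_)]
    grid[, mutation_type := mt]
    if (!is.null(mcount)) {
      grid <- merge(grid, mcount[mutation_type == mt,
                                 .(gene_id, strand_class, m)],
                    by = c("gene_id", "strand_class"), all.x = TRUE)
    } else {
      grid[, m := NA_integer_]
    }
    grid[is.na(m), m := 0L]
    rows[[mt]] <- grid
  }
  tab <- data.table::rbindlist(rows, use.names = TRUE)
  tab <- merge(tab, cov_df, by = "gene_id")
  tab <- tab[b > 0L]
  tab <- tab[stats::complete.cases(tab[, COVARIATE_NAMES, with = FALSE])]
  data.table::setcolorder(tab, c("mutation_type", "gene_id", "strand_class",
                                 "m", "b", "d_star"))
  tab[, d := NULL]

  unscaled <- data.table::copy(tab)
  for (mt in MUTATION_TYPES) {
    idx <- which(tab$mutation_type == mt)
    for (cc in COVARIATE_NAMES) {
      v <- tab[[cc]][idx]
      mu <- mean(v); s <- stats::sd(v)
      tab[idx, (cc) := if (is.na(s) || s == 0) v - mu else (v - mu) / s]
    }
  }
  data.table::setattr(tab, "unscaled", unscaled)
  tab[]
}
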
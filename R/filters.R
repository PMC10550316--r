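#' Mann-Whitney U test (two-sided) with tie handling
#'
#' Exact enumeration (via the null U distribution) when both groups have at
#' most `exact_max` observations and no ties are present; otherwise the
#' normal approximation with tie correction and continuity correction.
#' A fully tied comparison has zero-variance rank sums and returns p = 1.
#'
#' @param x,y numeric vectors (alt-supporting and ref-supporting read values).
#' @param exact_max group-size limit for the exact branch.
#' @return two-sided p-value, or `NA` if either group is empty.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) return(NA_real_)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (!has_ties && n1 <= exact_max && n2 <= exact_max) {
    p_lo <- stats::pwilcox(u1, n1, n2)
    p_hi <- stats::pwilcox(u1 - 1, n1, n2, lower.tail = FALSE)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  n <- n1 + n2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (abs(u1 - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  min(1, 2 * stats::pnorm(-z))
}

parse_vec <- function(s) {
  lapply(strsplit(s, ",", fixed = TRUE), function(v) as.numeric(v[nzchar(v)]))
}

empty_candidates <- function() {
  dt <- data.table::data.table(
    accession = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0),
    ref_count = integer(0), alt_count = integer(0), coverage = integer(0),
    ref_read_pos = list(), ref_mapq = list(), ref_baseq = list(),
    ref_strand = list(), alt_read_pos = list(), alt_mapq = list(),
    alt_baseq = list(), alt_strand = list()
  )
  for (f in FLAG_NAMES) dt[, (f) := logical(0)]
  dt
}

#' Select candidate variant sites from pileup observations
#'
#' Emits one candidate per accession x site with exactly two observed base
#' calls, coverage at or above the cutoff, and a minor-allele count (over
#' bases at or above the Phred threshold) of at least `min_minor_count`.
#' Sites with three or more observed alleles are dropped (not errors).
#'
#' @param pileup data.table of site observations (see [simulate_pileup()]).
#' @param min_coverage minimum read coverage (default 40).
#' @param min_base_phred Phred threshold for counting allele support
#'   (default 30).
#' @param min_minor_count minimum minor-allele read count (default 6).
#' @return data.table of candidates with high-quality `ref_count` and
#'   `alt_count`, raw `coverage`, per-read attribute list-columns and one
#'   (all-`FALSE`) logical column per filter flag. A candidate passes the
#'   pipeline when no flag is set.
#' @export
select_candidate_sites <- function(pileup, min_coverage = 40L,
                                   min_base_phred = 30L, min_minor_count = 6L) {
  pu <- data.table::as.data.table(pileup)
  counts <- as.matrix(pu[, .(n_A, n_C, n_G, n_T)])
  colnames(counts) <- BASES
  n_calls <- rowSums(counts >= 1L)
  keep <- pu$cov >= min_coverage & n_calls == 2L & pu$alt != "" & pu$alt != pu$ref
  pu <- pu[keep]
  if (nrow(pu) == 0L) return(empty_candidates())
  counts <- counts[keep, , drop = FALSE]

  ref_raw <- counts[cbind(seq_len(nrow(pu)), match(pu$ref, BASES))]
  alt_raw <- counts[cbind(seq_len(nrow(pu)), match(pu$alt, BASES))]
  # the two calls must be ref + alt
  keep2 <- (ref_raw + alt_raw) == pu$cov & ref_raw >= 1L
  pu <- pu[keep2]
  if (nrow(pu) == 0L) return(empty_candidates())

  rq <- parse_vec(pu$ref_baseq)
  aq <- parse_vec(pu$alt_baseq)
  ref_hq <- vapply(rq, function(v) sum(v >= min_base_phred), numeric(1))
  alt_hq <- vapply(aq, function(v) sum(v >= min_base_phred), numeric(1))
  no_vec <- lengths(rq) == 0L & lengths(aq) == 0L
  # sites emitted without attribute vectors carry counts only
  ref_hq[no_vec] <- counts[cbind(seq_len(nrow(pu)), match(pu$ref, BASES))][no_vec]
  alt_hq[no_vec] <- counts[cbind(seq_len(nrow(pu)), match(pu$alt, BASES))][no_vec]

  keep3 <- pmin(ref_hq, alt_hq) >= min_minor_count & alt_hq >= 1L
  pu <- pu[keep3]
  if (nrow(pu) == 0L) return(empty_candidates())

  out <- data.table::data.table(
    accession = pu$accession, chrom = pu$chrom, pos = pu$pos,
    ref = pu$ref, alt = pu$alt,
    ref_count = as.integer(ref_hq[keep3]),
    alt_count = as.integer(alt_hq[keep3]),
    coverage = pu$cov,
    ref_read_pos = parse_vec(pu$ref_read_pos),
    ref_mapq = parse_vec(pu$ref_mapq),
    ref_baseq = parse_vec(pu$ref_baseq),
    ref_strand = parse_vec(pu$ref_strand),
    alt_read_pos = parse_vec(pu$alt_read_pos),
    alt_mapq = parse_vec(pu$alt_mapq),
    alt_baseq = parse_vec(pu$alt_baseq),
    alt_strand = parse_vec(pu$alt_strand)
  )
  for (f in FLAG_NAMES) out[, (f) := FALSE]
  out[]
}

candidate_passes <- function(candidates, upto = FLAG_NAMES) {
  flags <- as.matrix(candidates[, intersect(upto, names(candidates)), with = FALSE])
  rowSums(flags) == 0L
}

#' Flag candidates at annotated germline variant positions
#'
#' Matching is by position only (any alternate allele).
#'
#' @param candidates candidate table from [select_candidate_sites()].
#' @param germline data.frame with `chrom` and 1-based `pos` (e.g. from
#'   [read_vcf()]).
#' @return The candidate table with the `germline` flag set.
#' @export
remove_germline <- function(candidates, germline) {
  if (is.null(germline) || nrow(germline) == 0L) return(candidates)
  key <- paste(germline$chrom, germline$pos)
  candidates[, germline := germline | (paste(chrom, pos) %in% key)]
  candidates[]
}

#' Flag candidates inside masked regions
#'
#' @param candidates candidate table.
#' @param regions GRanges of masked regions (1-based closed, as returned by
#'   [read_bed()]); unsorted input is handled.
#' @param flag_name which flag to set (`"blacklist"` or `"rna_edit"`).
#' @return The candidate table with the flag set for candidates whose
#'   position falls inside any region.
#' @export
region_mask_filter <- function(candidates, regions, flag_name) {
  stopifnot(flag_name %in% FLAG_NAMES)
  if (is.null(regions) || length(regions) == 0L || nrow(candidates) == 0L) {
    return(candidates)
  }
  gr <- GenomicRanges::GRanges(candidates$chrom,
                               IRanges::IRanges(candidates$pos, candidates$pos))
  hit <- GenomicRanges::countOverlaps(gr, regions) > 0L
  candidates[, (flag_name) := candidates[[flag_name]] | hit]
  candidates[]
}

nearest_boundary_distance <- function(chrom, pos, bchrom, bpos) {
  out <- rep(Inf, length(pos))
  for (cn in unique(chrom)) {
    b <- sort(bpos[bchrom == cn])
    if (!length(b)) next
    i <- chrom == cn
    idx <- findInterval(pos[i], b)
    lo <- ifelse(idx >= 1L, abs(pos[i] - b[pmax(idx, 1L)]), Inf)
    hi <- ifelse(idx < length(b), abs(b[pmin(idx + 1L, length(b))] - pos[i]), Inf)
    out[i] <- pmin(lo, hi)
  }
  out
}

#' Flag candidates close to annotated exon ends
#'
#' Distance is measured in whole bases between the candidate position and the
#' terminal exonic base of each annotated interval; candidates strictly
#' closer than `min_distance` are flagged.
#'
#' @param candidates candidate table.
#' @param boundaries data.frame with `chrom`, `pos` of exon-end bases (see
#'   [exon_boundaries()]); annotation-derived and per-accession junction
#'   boundaries can be merged upstream.
#' @param min_distance minimal tolerated distance in bp (default 7).
#' @return The candidate table with the `splice_junction` flag set.
#' @export
splice_junction_filter <- function(candidates, boundaries, min_distance = 7L) {
  if (nrow(candidates) == 0L || is.null(boundaries) || nrow(boundaries) == 0L) {
    return(candidates)
  }
  d <- nearest_boundary_distance(candidates$chrom, candidates$pos,
                                 boundaries$chrom, boundaries$pos)
  candidates[, splice_junction := splice_junction | (d < min_distance)]
  candidates[]
}

#' Binomial sequencing-error test
#'
#' Flags candidates whose alternate-allele count is compatible with
#' sequencing error: the upper-tail probability
#' P(X >= alt_count | n = coverage, p = p_err) at or above `alpha`.
#'
#' @param coverage read coverage (> 0).
#' @param alt_count alternate-supporting reads.
#' @param p_err per-read error probability (default 0.001, i.e. Phred 30).
#' @param alpha tail-probability cutoff (default 1e-4).
#' @return Logical vector: `TRUE` = flagged as possible sequencing error.
#' @export
sequencing_error_test <- function(coverage, alt_count, p_err = 0.001,
                                  alpha = 1e-4) {
  if (any(coverage <= 0L)) stop("coverage must be positive")
  stopifnot(all(alt_count >= 0L), all(alt_count <= coverage))
  p_upper <- stats::pbinom(alt_count - 1, coverage, p_err, lower.tail = FALSE)
  p_upper >= alpha
}

#' Binomial variant-allele-frequency test
#'
#' Flags candidates whose allele counts are consistent with a true VAF of 0.5
#' or higher (candidate missed germline variants): lower-tail probability
#' P(K <= alt_count | n = ref_count + alt_count, 0.5) above `alpha`.
#'
#' @param ref_count,alt_count reference / alternate supporting reads.
#' @param alpha lower-tail cutoff (default 0.05).
#' @return Logical vector: `TRUE` = flagged.
#' @export
vaf_test <- function(ref_count, alt_count, alpha = 0.05) {
  n <- ref_count + alt_count
  stopifnot(all(n >= 1L))
  stats::pbinom(alt_count, n, 0.5) > alpha
}

#' Per-read attribute bias tests for one candidate
#'
#' Five two-sided Mann-Whitney comparisons of alternate- versus
#' reference-supporting reads: position in read, mapping quality, base
#' quality, strand (encoded 0/1) and variant distance. The variant-distance
#' value of a read is the mean absolute distance between its position in
#' read and the positions of the reference-supporting reads (self excluded
#' for reference reads), so both groups' values are the same transform of
#' the underlying read positions and the test stays calibrated.
#' A test with an empty group is skipped (`NA`, not flagged).
#'
#' @param alt_read_pos,alt_mapq,alt_baseq,alt_strand alt-read attributes.
#' @param ref_read_pos,ref_mapq,ref_baseq,ref_strand ref-read attributes.
#' @param alpha significance cutoff (default 0.05).
#' @return Named logical vector over
#'   `c("read_pos_bias","map_qual_bias","base_qual_bias","strand_bias","var_dist_bias")`.
#' @export
bias_tests <- function(alt_read_pos, alt_mapq, alt_baseq, alt_strand,
                       ref_read_pos, ref_mapq, ref_baseq, ref_strand,
                       alpha = 0.05) {
  flag <- function(p) !is.na(p) && p < alpha
  res <- c(
    read_pos_bias = flag(mann_whitney_u(alt_read_pos, ref_read_pos)),
    map_qual_bias = flag(mann_whitney_u(alt_mapq, ref_mapq)),
    base_qual_bias = flag(mann_whitney_u(alt_baseq, ref_baseq)),
    strand_bias = flag(mann_whitney_u(alt_strand, ref_strand)),
    var_dist_bias = FALSE
  )
  nr <- length(ref_read_pos)
  if (nr >= 2L && length(alt_read_pos) >= 1L) {
    alt_d <- vapply(alt_read_pos, function(p) mean(abs(p - ref_read_pos)), numeric(1))
    ref_d <- vapply(seq_len(nr), function(i) {
      mean(abs(ref_read_pos[i] - ref_read_pos[-i]))
    }, numeric(1))
    res["var_dist_bias"] <- flag(mann_whitney_u(alt_d, ref_d))
  }
  res
}

apply_bias_tests <- function(candidates, alpha = 0.05) {
  if (nrow(candidates) == 0L) return(candidates)
  tests <- c("read_pos_bias", "map_qual_bias", "base_qual_bias",
             "strand_bias", "var_dist_bias")
  res <- t(vapply(seq_len(nrow(candidates)), function(i) {
    bias_tests(candidates$alt_read_pos[[i]], candidates$alt_mapq[[i]],
               candidates$alt_baseq[[i]], candidates$alt_strand[[i]],
               candidates$ref_read_pos[[i]], candidates$ref_mapq[[i]],
               candidates$ref_baseq[[i]], candidates$ref_strand[[i]],
               alpha = alpha)
  }, logical(5L)))
  for (j in seq_along(tests)) {
    candidates[, (tests[j]) := candidates[[tests[j]]] | res[, j]]
  }
  candidates[]
}

#' Flag candidates near homopolymer runs
#'
#' A candidate is flagged when any maximal run of at least `run_length`
#' identical bases lies within `window` bases (distance 0 when the candidate
#' sits inside the run).
#'
#' @param candidates candidate table.
#' @param annotation a [genome_annotation()] providing reference sequences.
#' @param run_length minimal run length (default 7).
#' @param window proximity window in bp (default 20; distance <= window
#'   flags).
#' @return The candidate table with the `polynucleotide` flag set.
#' @export
polynucleotide_filter <- function(candidates, annotation, run_length = 7L,
                                  window = 20L) {
  if (nrow(candidates) == 0L) return(candidates)
  lens <- nchar(annotation$sequences)[match(candidates$chrom,
                                            names(annotation$sequences))]
  if (anyNA(lens) || any(candidates$pos < 1L | candidates$pos > lens)) {
    stop("candidate position outside reference bounds")
  }
  hit <- rep(FALSE, nrow(candidates))
  for (cn in unique(candidates$chrom)) {
    runs <- find_homopolymer_runs(annotation$sequences[[cn]], run_length)
    i <- which(candidates$chrom == cn)
    if (!nrow(runs) || !length(i)) next
    gr_pos <- IRanges::IRanges(candidates$pos[i], candidates$pos[i])
    gr_run <- IRanges::IRanges(pmax(1L, runs$start - window), runs$end + window)
    hit[i] <- IRanges::countOverlaps(gr_pos, gr_run) > 0L
  }
  candidates[, polynucleotide := polynucleotide | hit]
  candidates[]
}

#' Flag cross-accession recurrent candidates
#'
#' Applied to candidates that pass all previous filters. Two stages: loci
#' mutated in at least `ceiling(max_fraction * n_accessions)` accessions are
#' flagged `recurrence_fraction`; among the remaining survivors, loci mutated
#' in two or more accessions are flagged `recurrent`.
#'
#' @param candidates candidate table (prior flags already recorded).
#' @param n_accessions total number of accessions in the study.
#' @param max_fraction sample-fraction cutoff (default 0.04).
#' @return The candidate table with recurrence flags set.
#' @export
recurrence_filter <- function(candidates, n_accessions, max_fraction = 0.04) {
  if (nrow(candidates) == 0L) return(candidates)
  prior <- setdiff(FLAG_NAMES, c("recurrence_fraction", "recurrent",
                                 "outlier_accession", "ambiguous_region"))
  surv <- candidate_passes(candidates, prior)
  # a locus must be repeated to be removable: the fraction threshold never
  # drops below two accessions in small cohorts
  thresh <- max(2L, ceiling(max_fraction * n_accessions))
  loc <- paste(candidates$chrom, candidates$pos)
  n_acc_locus <- function(sel) {
    tab <- tapply(candidates$accession[sel], loc[sel],
                  function(a) length(unique(a)))
    out <- rep(0L, nrow(candidates))
    m <- match(loc, names(tab))
    out[!is.na(m)] <- as.integer(tab[m[!is.na(m)]])
    out
  }
  n1 <- n_acc_locus(surv)
  candidates[, recurrence_fraction := recurrence_fraction | (surv & n1 >= thresh)]
  surv2 <- surv & !candidates$recurrence_fraction
  n2 <- n_acc_locus(surv2)
  candidates[, recurrent := recurrent | (surv2 & n2 >= 2L)]
  candidates[]
}

#' Detect outlier accessions by a groupwise interquartile-range rule
#'
#' Accessions are partitioned into `n_groups` equal-width bins over their
#' total depth of coverage; within each bin an accession is an outlier when
#' its mutation count lies outside `[Q25 - k IQR, Q75 + k IQR]` (type-7
#' quantiles). An accession alone in its bin is flagged.
#'
#' @param summaries data.frame with `accession`, `total_depth`, `m`
#'   (mutation count).
#' @param k IQR multiplier (default 1.5).
#' @param n_groups number of depth bins (default 4).
#' @return The summary table with `depth_group` and logical `outlier` columns.
#' @export
outlier_accession_filter <- function(summaries, k = 1.5, n_groups = 4L) {
  s <- as.data.frame(summaries)
  if (nrow(s) < n_groups) stop("need at least ", n_groups, " accessions")
  rng <- range(s$total_depth)
  if (rng[1] == rng[2]) {
    s$depth_group <- 1L
  } else {
    brk <- seq(rng[1], rng[2], length.out = n_groups + 1L)
    s$depth_group <- as.integer(cut(s$total_depth, brk, include.lowest = TRUE))
  }
  s$outlier <- FALSE
  for (g in unique(s$depth_group)) {
    i <- which(s$depth_group == g)
    if (length(i) == 1L) { s$outlier[i] <- TRUE; next }
    q <- stats::quantile(s$m[i], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    s$outlier[i] <- s$m[i] < q[1] - k * iqr | s$m[i] > q[2] + k * iqr
  }
  s
}

#' Flag candidates outside unambiguous UTR/exonic regions
#'
#' Only candidates inside intervals that do not overlap UTR/exonic intervals
#' of a different gene are retained; everything else (ambiguous overlap,
#' intronic, intergenic) is flagged.
#'
#' @param candidates candidate table.
#' @param annotation a [genome_annotation()].
#' @return The candidate table with the `ambiguous_region` flag set.
#' @export
unambiguous_region_filter <- function(candidates, annotation) {
  if (nrow(candidates) == 0L) return(candidates)
  gr <- GenomicRanges::GRanges(candidates$chrom,
                               IRanges::IRanges(candidates$pos, candidates$pos))
  ok <- GenomicRanges::countOverlaps(
    gr, annotation_granges(annotation, unambiguous_only = TRUE)) > 0L
  candidates[, ambiguous_region := ambiguous_region | !ok]
  candidates[]
}

#' Run the full somatic-mutation calling cascade
#'
#' Candidate selection followed by germline removal and the artifact filters
#' in their fixed order: masks, splice-junction proximity, binomial
#' sequencing-error and VAF tests, the five read-attribute bias tests,
#' polynucleotide proximity, cross-accession recurrence, outlier-accession
#' exclusion and restriction to unambiguous UTR/exonic regions. Only the
#' last three consume prior survivors; every other filter records its flag
#' independently.
#'
#' @param pileup site-observation table (see [simulate_pileup()]).
#' @param annotation a [genome_annotation()].
#' @param germline data.frame of germline variant positions, or `NULL`.
#' @param blacklist,rna_edit mask GRanges, or `NULL`.
#' @param junctions optional extra junction boundaries (`chrom`, `pos`).
#' @param config threshold configuration, see [default_config()].
#' @return list with `candidates` (flag-annotated table), `pass` (subset with
#'   no flags), `accession_summary` (depths, mutation counts, depth group and
#'   outlier status) and `filter_counts` (records flagged per filter).
#' @export
call_somatic_mutations <- function(pileup, annotation, germline = NULL,
                                   blacklist = NULL, rna_edit = NULL,
                                   junctions = NULL,
                                   config = default_config()) {
  cfg <- utils::modifyList(default_config(), config)
  cand <- select_candidate_sites(pileup,
                                 min_coverage = cfg$min_coverage,
                                 min_base_phred = cfg$min_base_phred,
                                 min_minor_count = cfg$min_minor_count)
  cand <- remove_germline(cand, germline)
  cand <- region_mask_filter(cand, blacklist, "blacklist")
  cand <- region_mask_filter(cand, rna_edit, "rna_edit")
  cand <- splice_junction_filter(cand, exon_boundaries(annotation, junctions),
                                 min_distance = cfg$splice_min_distance)
  if (nrow(cand)) {
    cand[, seq_error := seq_error | sequencing_error_test(
      coverage, alt_count, p_err = cfg$seq_error_p, alpha = cfg$seq_error_alpha)]
    cand[, vaf := vaf | vaf_test(ref_count, alt_count, alpha = cfg$vaf_alpha)]
  }
  cand <- apply_bias_tests(cand, alpha = cfg$bias_alpha)
  cand <- polynucleotide_filter(cand, annotation,
                                run_length = cfg$polyrun_length,
                                window = cfg$polyrun_window)
  pu <- data.table::as.data.table(pileup)
  n_accessions <- length(unique(pu$accession))
  cand <- recurrence_filter(cand, n_accessions,
                            max_fraction = cfg$recurrence_fraction)

  # accession summaries from recurrence-stage survivors
  pre_outlier <- setdiff(FLAG_NAMES, c("outlier_accession", "ambiguous_region"))
  surv <- candidate_passes(cand, pre_outlier)
  depth <- pu[, .(total_depth = sum(as.numeric(cov))), by = accession]
  m_tab <- if (nrow(cand)) {
    stats::setNames(as.integer(table(cand$accession[surv])),
                    names(table(cand$accession[surv])))
  } else integer(0)
  summaries <- data.frame(
    accession = depth$accession,
    total_depth = depth$total_depth,
    m = ifelse(is.na(m_tab[depth$accession]), 0L,
               as.integer(m_tab[depth$accession]))
  )
  summaries <- outlier_accession_filter(summaries, k = cfg$iqr_k,
                                        n_groups = cfg$n_depth_groups)
  out_acc <- summaries$accession[summaries$outlier]
  if (nrow(cand)) {
    cand[, outlier_accession := outlier_accession | (accession %in% out_acc)]
  }
  cand <- unambiguous_region_filter(cand, annotation)

  pass <- cand[candidate_passes(cand)]
  counts <- vapply(FLAG_NAMES, function(f) sum(cand[[f]]), integer(1))
  list(candidates = cand, pass = pass, accession_summary = summaries,
       filter_counts = counts)
}
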
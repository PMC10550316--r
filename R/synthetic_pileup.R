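#' Default planted-truth specification for pileup simulation
#'
#' Counts and rates of planted true somatic mutations and artifact classes.
#' True somatic mutations are private to one accession with a sub-0.5 variant
#' allele fraction; germline leaks recur across accessions at VAF 0.5;
#' read-bias records draw their alt-read attributes from shifted
#' distributions; outlier accessions receive an inflated private mutation
#' rate.
#'
#' @param n_true number of true somatic mutations.
#' @param true_vaf variant allele fraction of true somatic mutations.
#' @param n_germline_leak number of unannotated germline loci leaking through.
#' @param leak_carrier_prob per-accession carrier probability for a leak locus.
#' @param n_polyA planted polynucleotide-adjacent error records.
#' @param n_splice planted splice-edge error records.
#' @param n_high_vaf planted high-VAF records.
#' @param high_vaf allele fraction of high-VAF records.
#' @param n_read_bias planted biased-read records.
#' @param artifact_vaf allele fraction of polyA/splice/read-bias records.
#' @param n_outlier_accessions accessions given an inflated mutation rate.
#' @param outlier_multiplier rate multiplier for outlier accessions.
#' @param n_germline_annotated records planted at annotated germline positions.
#' @param mapq_shift downward mapping-quality shift for biased alt reads.
#' @return list of the above.
#' @export
default_truth_spec <- function(n_true = 100L, true_vaf = 0.25,
                               n_germline_leak = 30L, leak_carrier_prob = 0.3,
                               n_polyA = 20L, n_splice = 20L,
                               n_high_vaf = 20L, high_vaf = 0.9,
                               n_read_bias = 20L, artifact_vaf = 0.25,
                               n_outlier_accessions = 1L,
                               outlier_multiplier = 10,
                               n_germline_annotated = 20L,
                               mapq_shift = 20L) {
  as.list(environment())
}

draw_baseq <- function(n, mean = 36, sd = 2) {
  pmin(41L, pmax(2L, as.integer(round(stats::rnorm(n, mean, sd)))))
}

join_num <- function(x) paste(x, collapse = ",")

#' Simulate per-accession pileup observations with planted truths
#'
#' Emits one site observation per accession x annotated gene position with
#' nonzero coverage: per-base allele counts, a high-quality (Phred >= 30)
#' base count, and per-read attribute vectors (position in read, mapping
#' quality, base quality, strand) for reference- and alternate-supporting
#' reads at sites whose alternate count is at least 2 (sites below that can
#' never reach the minor-allele selection rule and carry empty vectors).
#'
#' Planted records are placed at "detectable" sites: coverage >= 60 in the
#' carrier accession (>= 40 for germline-class records), away from exon
#' boundaries, homopolymer runs, masks and annotated germline positions
#' (except the germline-annotated class), and inside unambiguous intervals.
#' True somatic mutations are never planted in designated outlier accessions,
#' whose inflated mutation load is its own artifact class.
#'
#' @param annotation a [genome_annotation()].
#' @param truth_spec see [default_truth_spec()].
#' @param n_accessions number of accessions (>= 2).
#' @param depth_params list: `mean_coverage` (mean reads/site),
#'   `accession_range` (multiplicative uniform range across accessions),
#'   `gene_dispersion` (log-normal sd of per-gene expression factors),
#'   `read_length` (bp, after 5' clipping).
#' @param error_params list: `miscall_rate` (per-read miscall probability,
#'   matching a mean base quality around Q35-36).
#' @param germline optional data.frame (`chrom`, `pos`, `ref`, `alt`) of
#'   annotated germline variants; used both to avoid planting somatic records
#'   at annotated positions and to plant `germline_annotated` records.
#' @param masks optional list of GRanges to avoid when planting (e.g.
#'   blacklist and RNA-edit masks).
#' @param seed integer seed.
#' @return list with `pileup` (data.table of site observations), `truth`
#'   (data.table of planted records with `class`), `outlier_accessions`,
#'   and `params` (all generator parameters, seed included).
#' @export
simulate_pileup <- function(annotation, truth_spec = default_truth_spec(),
                            n_accessions = 50L,
                            depth_params = list(), error_params = list(),
                            germline = NULL, masks = NULL, seed = 1L) {
  stopifnot(n_accessions >= 2L)
  dp <- utils::modifyList(
    list(mean_coverage = 100, accession_range = c(0.6, 1.5),
         gene_dispersion = 0.3, read_length = 94L),
    depth_params
  )
  ep <- utils::modifyList(list(miscall_rate = 3e-4), error_params)
  ts <- utils::modifyList(default_truth_spec(), truth_spec)
  set.seed(sub_seed(seed, "pileup"))

  accessions <- sprintf("acc%03d", seq_len(n_accessions))
  outlier_acc <- integer(0)
  if (ts$n_outlier_accessions > 0L) {
    outlier_acc <- sample.int(n_accessions, ts$n_outlier_accessions)
  }

  # unique annotated positions with a representative gene for expression level
  pos_all <- annotation_positions(annotation)
  pos_dt <- pos_all[, .(gene_id = gene_id[1L], unamb = all(unambiguous)),
                    by = .(chrom, pos, ref)]
  data.table::setkey(pos_dt, chrom, pos)
  n_pos <- nrow(pos_dt)

  gene_ids <- unique(pos_dt$gene_id)
  gene_factor <- stats::setNames(
    exp(stats::rnorm(length(gene_ids), 0, dp$gene_dispersion)), gene_ids)
  acc_factor <- stats::runif(n_accessions, dp$accession_range[1],
                             dp$accession_range[2])

  full <- data.table::data.table(
    acc = rep(seq_len(n_accessions), each = n_pos),
    pidx = rep(seq_len(n_pos), n_accessions)
  )
  lambda <- dp$mean_coverage * acc_factor[full$acc] *
    gene_factor[pos_dt$gene_id[full$pidx]]
  full[, cov := stats::rpois(.N, lambda)]

  # ---- choose plantable positions -------------------------------------------
  bounds <- exon_boundaries(annotation)
  runs <- annotation$polyruns
  nat <- do.call(rbind, lapply(names(annotation$sequences), function(cn) {
    r <- find_homopolymer_runs(annotation$sequences[[cn]])
    if (nrow(r)) cbind(chrom = cn, r) else NULL
  }))
  run_all <- rbind(if (!is.null(runs)) runs[, c("chrom", "start", "end")] else NULL,
                   if (!is.null(nat)) nat[, c("chrom", "start", "end")] else NULL)

  near <- function(dtab, chroms, starts, ends, margin) {
    # logical per pos_dt row: within margin of any [start, end] on same chrom
    res <- rep(FALSE, nrow(dtab))
    if (is.null(starts) || length(starts) == 0L) return(res)
    gr_pos <- GenomicRanges::GRanges(dtab$chrom, IRanges::IRanges(dtab$pos, dtab$pos))
    gr_box <- GenomicRanges::GRanges(chroms,
                                     IRanges::IRanges(pmax(1L, starts - margin), ends + margin))
    res[S4Vectors::queryHits(GenomicRanges::findOverlaps(gr_pos, gr_box))] <- TRUE
    res
  }

  near_boundary <- near(pos_dt, bounds$chrom, bounds$pos, bounds$pos, 6L)
  near_run <- if (!is.null(run_all)) {
    near(pos_dt, run_all$chrom, run_all$start, run_all$end, 20L)
  } else rep(FALSE, n_pos)
  in_mask <- rep(FALSE, n_pos)
  if (!is.null(masks)) {
    for (m in masks) {
      if (length(m)) {
        in_mask <- in_mask | near(pos_dt, as.character(GenomicRanges::seqnames(m)),
                                  GenomicRanges::start(m), GenomicRanges::end(m), 0L)
      }
    }
  }
  at_germline <- rep(FALSE, n_pos)
  if (!is.null(germline) && nrow(germline)) {
    at_germline <- near(pos_dt, germline$chrom, germline$pos, germline$pos, 0L)
  }
  clean <- pos_dt$unamb & !near_boundary & !near_run & !in_mask & !at_germline
  clean_idx <- which(clean)

  polyA_idx <- which(near_run & !near_boundary & !in_mask & !at_germline & pos_dt$unamb)
  splice_idx <- which(near_boundary & !near_run & !in_mask & !at_germline & pos_dt$unamb)

  # ---- assemble planted events ----------------------------------------------
  # events: pidx, acc, frac, alt, class, bias
  events <- list()
  cov_of <- function(pidx, acc) full$cov[(acc - 1L) * n_pos + pidx]

  pick_accession <- function(pidx, min_cov, exclude = outlier_acc, n = 1L) {
    pool <- setdiff(seq_len(n_accessions), exclude)
    covs <- cov_of(rep(pidx, length(pool)), pool)
    ok <- pool[covs >= min_cov]
    if (length(ok) < n) return(NULL)
    sample(ok, n)
  }

  take_loci <- function(pool, n, used) {
    avail <- setdiff(pool, used)
    if (length(avail) < n) {
      warning("only ", length(avail), " plantable sites for a class needing ", n)
      n <- length(avail)
    }
    if (n == 0L) return(integer(0))
    sample(avail, n)
  }

  used <- integer(0)
  add_private <- function(pool, n, frac, class, bias = FALSE, min_cov = 60L) {
    loci <- take_loci(pool, n, used)
    used <<- c(used, loci)
    for (p in loci) {
      a <- pick_accession(p, min_cov)
      if (is.null(a)) next
      alt <- sample(setdiff(BASES, pos_dt$ref[p]), 1L)
      events[[length(events) + 1L]] <<- data.frame(
        pidx = p, acc = a, frac = frac, alt = alt, class = class,
        bias = bias, stringsAsFactors = FALSE)
    }
  }

  if (ts$n_true > 0L) add_private(clean_idx, ts$n_true, ts$true_vaf, "true_somatic")
  if (ts$n_high_vaf > 0L) add_private(clean_idx, ts$n_high_vaf, ts$high_vaf, "high_vaf")
  if (ts$n_read_bias > 0L) add_private(clean_idx, ts$n_read_bias, ts$artifact_vaf,
                                       "read_bias", bias = TRUE)
  if (ts$n_polyA > 0L) add_private(polyA_idx, ts$n_polyA, ts$artifact_vaf, "polyA_error")
  if (ts$n_splice > 0L) add_private(splice_idx, ts$n_splice, ts$artifact_vaf, "splice_edge")

  # recurrent classes: one alt allele per locus, several carrier accessions
  add_recurrent <- function(loci, prob, class, min_cov = 40L) {
    for (p in loci) {
      covs <- cov_of(rep(p, n_accessions), seq_len(n_accessions))
      eligible <- which(covs >= min_cov)
      if (length(eligible) < 2L) next
      carriers <- eligible[stats::runif(length(eligible)) < prob]
      if (length(carriers) < 2L) carriers <- sample(eligible, 2L)
      alt <- sample(setdiff(BASES, pos_dt$ref[p]), 1L)
      for (a in carriers) {
        events[[length(events) + 1L]] <<- data.frame(
          pidx = p, acc = a, frac = 0.5, alt = alt, class = class,
          bias = FALSE, stringsAsFactors = FALSE)
      }
    }
  }

  if (ts$n_germline_leak > 0L) {
    loci <- take_loci(clean_idx, ts$n_germline_leak, used)
    used <- c(used, loci)
    add_recurrent(loci, ts$leak_carrier_prob, "germline_leak")
  }
  if (ts$n_germline_annotated > 0L && !is.null(germline) && nrow(germline)) {
    gpos <- which(at_germline & pos_dt$unamb & !near_boundary & !near_run & !in_mask)
    loci <- take_loci(gpos, min(ts$n_germline_annotated, length(gpos)), used)
    used <- c(used, loci)
    add_recurrent(loci, ts$leak_carrier_prob, "germline_annotated")
  }

  # outlier accessions: inflated private mutation load
  if (length(outlier_acc)) {
    per_acc <- ceiling(ts$outlier_multiplier * max(1L, ceiling(ts$n_true / n_accessions)))
    for (a in outlier_acc) {
      loci <- take_loci(clean_idx, per_acc, used)
      used <- c(used, loci)
      for (p in loci) {
        if (cov_of(p, a) < 40L) next
        alt <- sample(setdiff(BASES, pos_dt$ref[p]), 1L)
        events[[length(events) + 1L]] <- data.frame(
          pidx = p, acc = a, frac = ts$true_vaf, alt = alt,
          class = "outlier_accession", bias = FALSE, stringsAsFactors = FALSE)
      }
    }
  }

  events <- if (length(events)) data.table::rbindlist(events) else
    data.table::data.table(pidx = integer(0), acc = integer(0), frac = numeric(0),
                           alt = character(0), class = character(0), bias = logical(0))

  # ---- realize allele counts -------------------------------------------------
  full[, row_id := .I]
  full[, err_n := stats::rbinom(.N, cov, ep$miscall_rate)]
  full[, alt_n := 0L]
  full[, alt_base := ""]
  full[, bias := FALSE]
  if (nrow(events)) {
    ev_rows <- (events$acc - 1L) * n_pos + events$pidx
    full$err_n[ev_rows] <- 0L  # planted rows carry exactly the planted signal
    full$alt_n[ev_rows] <- stats::rbinom(nrow(events), full$cov[ev_rows], events$frac)
    full$alt_base[ev_rows] <- events$alt
    full$bias[ev_rows] <- events$bias
    events$alt_count <- full$alt_n[ev_rows]
    events$coverage <- full$cov[ev_rows]
  }

  # counts per base
  refs <- pos_dt$ref[full$pidx]
  counts <- matrix(0L, nrow(full), 4L, dimnames = list(NULL, BASES))
  counts[cbind(seq_len(nrow(full)), match(refs, BASES))] <-
    pmax(0L, full$cov - full$alt_n - full$err_n)
  has_alt <- full$alt_n > 0L
  counts[cbind(which(has_alt), match(full$alt_base[has_alt], BASES))] <-
    counts[cbind(which(has_alt), match(full$alt_base[has_alt], BASES))] +
    full$alt_n[has_alt]
  err_rows <- which(full$err_n > 0L)
  if (length(err_rows)) {
    err_base <- vapply(refs[err_rows],
                       function(r) sample(setdiff(BASES, r), 1L), character(1))
    counts[cbind(err_rows, match(err_base, BASES))] <-
      counts[cbind(err_rows, match(err_base, BASES))] + full$err_n[err_rows]
  }

  full[, `:=`(n_A = counts[, "A"], n_C = counts[, "C"],
              n_G = counts[, "G"], n_T = counts[, "T"])]

  # observed alt = most frequent non-reference base
  nonref <- counts
  nonref[cbind(seq_len(nrow(full)), match(refs, BASES))] <- -1L
  amax <- max.col(nonref, ties.method = "first")
  alt_obs_n <- nonref[cbind(seq_len(nrow(full)), amax)]
  full[, alt_obs := ifelse(alt_obs_n > 0L, BASES[amax], "")]
  full[, alt_obs_n := pmax(0L, alt_obs_n)]

  # ---- per-read attribute vectors -------------------------------------------
  p_hq <- 1 - stats::pnorm(29.5, 36, 2)
  emit <- which(full$alt_obs_n >= 2L)
  attr_cols <- c("ref_read_pos", "ref_mapq", "ref_baseq", "ref_strand",
                 "alt_read_pos", "alt_mapq", "alt_baseq", "alt_strand")
  for (cc in attr_cols) full[, (cc) := ""]
  full[, n_hq := stats::rbinom(.N, cov, p_hq)]

  if (length(emit)) {
    refc <- counts[cbind(emit, match(refs[emit], BASES))]
    altc <- full$alt_obs_n[emit]
    biasf <- full$bias[emit]
    rl <- dp$read_length
    mk <- function(n, biased, what) {
      switch(what,
        pos = if (biased) sample.int(10L, n, TRUE) - 1L else sample.int(rl, n, TRUE) - 1L,
        mapq = if (biased) rep(60L - ts$mapq_shift, n) else rep(60L, n),
        baseq = draw_baseq(n),
        strand = stats::rbinom(n, 1L, 0.5)
      )
    }
    strs <- matrix("", length(emit), 8L)
    nhq <- integer(length(emit))
    for (i in seq_along(emit)) {
      rq <- mk(refc[i], FALSE, "baseq"); aq <- mk(altc[i], biasf[i], "baseq")
      strs[i, ] <- c(
        join_num(mk(refc[i], FALSE, "pos")), join_num(mk(refc[i], FALSE, "mapq")),
        join_num(rq), join_num(mk(refc[i], FALSE, "strand")),
        join_num(mk(altc[i], biasf[i], "pos")), join_num(mk(altc[i], biasf[i], "mapq")),
        join_num(aq), join_num(mk(altc[i], biasf[i], "strand"))
      )
      other <- full$cov[emit[i]] - refc[i] - altc[i]
      nhq[i] <- sum(rq >= 30L) + sum(aq >= 30L) +
        if (other > 0L) stats::rbinom(1L, other, p_hq) else 0L
    }
    for (j in seq_along(attr_cols)) {
      data.table::set(full, i = emit, j = attr_cols[j], value = strs[, j])
    }
    data.table::set(full, i = emit, j = "n_hq", value = nhq)
  }

  pileup <- data.table::data.table(
    accession = accessions[full$acc],
    chrom = pos_dt$chrom[full$pidx],
    pos = pos_dt$pos[full$pidx],
    ref = refs,
    cov = full$cov,
    n_A = full$n_A, n_C = full$n_C, n_G = full$n_G, n_T = full$n_T,
    n_hq = full$n_hq,
    alt = full$alt_obs,
    full[, attr_cols, with = FALSE]
  )[cov > 0L]
  data.table::setkey(pileup, accession, chrom, pos)

  truth <- if (nrow(events)) data.table::data.table(
    accession = accessions[events$acc],
    chrom = pos_dt$chrom[events$pidx],
    pos = pos_dt$pos[events$pidx],
    ref = pos_dt$ref[events$pidx],
    alt = events$alt,
    class = events$class,
    coverage = events$coverage,
    alt_count = events$alt_count
  ) else data.table::data.table(
    accession = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), class = character(0),
    coverage = integer(0), alt_count = integer(0))

  list(
    pileup = pileup,
    truth = truth,
    outlier_accessions = accessions[outlier_acc],
    params = list(truth_spec = ts, n_accessions = n_accessions,
                  depth_params = dp, error_params = ep, seed = seed)
  )
}
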
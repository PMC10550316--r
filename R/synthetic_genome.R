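#' Simulate a small annotated genome
#'
#' Generates random reference chromosomes at a target GC content and packs
#' strand-annotated genes (5'UTR, one or more exons separated by introns,
#' 3'UTR) onto them. One deliberately overlapping gene pair is placed (when
#' `n_genes >= 2`) so that downstream ambiguity handling is always exercised,
#' and homopolymer runs of length >= 7 are planted at a configurable rate to
#' feed the polynucleotide-proximity filter.
#'
#' @param n_chrom number of chromosomes.
#' @param n_genes number of genes (>= 1).
#' @param length_params list of structural parameters: `utr_len` (UTR length,
#'   bp), `exon_len` (mean exon length, bp), `n_exons_lambda` (Poisson mean of
#'   extra exons beyond the first), `intron_len` (intron length, bp),
#'   `gap_len` (intergenic gap, bp), and optionally `chrom_len` (fixed
#'   chromosome length; an explicit error is raised if the genes do not fit).
#' @param gc_target target GC fraction in (0, 1).
#' @param polyrun_rate expected planted homopolymer runs per kilobase.
#' @param seed integer seed; identical inputs give byte-identical output.
#' @return A [genome_annotation()] whose `polyruns` component records the
#'   planted runs.
#' @export
simulate_genome <- function(n_chrom = 2L, n_genes = 20L,
                            length_params = list(), gc_target = 0.42,
                            polyrun_rate = 0.3, seed = 1L) {
  stopifnot(n_chrom >= 1, n_genes >= 1, gc_target > 0, gc_target < 1,
            polyrun_rate >= 0)
  lp <- utils::modifyList(
    list(utr_len = 60L, exon_len = 220L, n_exons_lambda = 1.5,
         intron_len = 90L, gap_len = 250L, chrom_len = NULL),
    length_params
  )
  set.seed(sub_seed(seed, "genome"))

  base_probs <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
                  G = gc_target / 2, T = (1 - gc_target) / 2)

  # gene structural plans
  plans <- lapply(seq_len(n_genes), function(i) {
    n_ex <- 1L + stats::rpois(1L, lp$n_exons_lambda)
    ex_len <- pmax(40L, stats::rpois(n_ex, lp$exon_len))
    list(n_ex = n_ex, ex_len = ex_len,
         strand = if (i %% 2L == 0L) "-" else "+")
  })

  gene_span <- vapply(plans, function(p) {
    2L * lp$utr_len + sum(p$ex_len) + (p$n_ex - 1L) * lp$intron_len
  }, integer(1))

  # round-robin chromosome assignment; the final two genes share a chromosome
  # and overlap so ambiguous intervals always exist
  chrom_of <- ((seq_len(n_genes) - 1L) %% n_chrom) + 1L
  if (n_genes >= 2L) chrom_of[n_genes] <- chrom_of[n_genes - 1L]

  intervals <- list()
  offsets <- rep(lp$gap_len, n_chrom)
  for (i in seq_len(n_genes)) {
    p <- plans[[i]]
    ch <- chrom_of[i]
    start <- offsets[ch]
    if (n_genes >= 2L && i == n_genes) {
      # overlap the tail of the previous gene by ~half a UTR
      start <- offsets[ch] - lp$gap_len - 2L * lp$utr_len
      p$strand <- if (plans[[n_genes - 1L]]$strand == "+") "-" else "+"
    }
    pieces <- c(lp$utr_len,
                as.vector(rbind(p$ex_len, c(rep(lp$intron_len, p$n_ex - 1L), NA))),
                lp$utr_len)
    pieces <- pieces[!is.na(pieces)]
    types <- c("UTR",
               as.vector(rbind(rep("exon", p$n_ex),
                               c(rep("intron", p$n_ex - 1L), NA))),
               "UTR")
    types <- types[!is.na(types)]
    pos <- start
    for (j in seq_along(pieces)) {
      if (types[j] != "intron") {
        intervals[[length(intervals) + 1L]] <- data.frame(
          gene_id = sprintf("gene%03d", i),
          chrom = sprintf("chr%d", ch), strand = p$strand,
          start = pos, end = pos + pieces[j] - 1L, type = types[j],
          stringsAsFactors = FALSE
        )
      }
      pos <- pos + pieces[j]
    }
    offsets[ch] <- max(offsets[ch], pos) + lp$gap_len
  }
  intervals <- do.call(rbind, intervals)

  chrom_needed <- vapply(seq_len(n_chrom), function(ch) {
    max(intervals$end[intervals$chrom == sprintf("chr%d", ch)], 0L) + lp$gap_len
  }, numeric(1))
  if (!is.null(lp$chrom_len)) {
    if (any(chrom_needed > lp$chrom_len)) {
      stop("genes exceed chromosome length: need ",
           max(chrom_needed), " bp, chrom_len = ", lp$chrom_len)
    }
    chrom_len <- rep_len(as.integer(lp$chrom_len), n_chrom)
  } else {
    chrom_len <- as.integer(chrom_needed)
  }

  sequences <- vapply(chrom_len, function(L) {
    paste(sample(BASES, L, replace = TRUE, prob = base_probs), collapse = "")
  }, character(1))
  names(sequences) <- sprintf("chr%d", seq_len(n_chrom))

  # plant homopolymer runs
  polyruns <- NULL
  runs <- list()
  for (ch in seq_len(n_chrom)) {
    n_runs <- stats::rpois(1L, polyrun_rate * chrom_len[ch] / 1000)
    if (n_runs == 0L) next
    occupied <- integer(0)
    for (k in seq_len(n_runs)) {
      len <- 7L + stats::rpois(1L, 1.2)
      st <- sample.int(chrom_len[ch] - len, 1L)
      if (any(abs(st - occupied) < 40L)) next  # keep planted runs separated
      occupied <- c(occupied, st)
      b <- sample(BASES, 1L)
      substring(sequences[ch], st, st + len - 1L) <- strrep(b, len)
      runs[[length(runs) + 1L]] <- data.frame(
        chrom = sprintf("chr%d", ch), start = st, end = st + len - 1L,
        base = b, stringsAsFactors = FALSE
      )
    }
  }
  if (length(runs)) polyruns <- do.call(rbind, runs)

  genome_annotation(sequences, intervals, polyruns = polyruns)
}
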
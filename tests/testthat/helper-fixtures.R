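# Shared fixtures: tiny hand-built genomes, annotations and candidate rows.

random_seq <- function(n, gc = 0.42, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# one chromosome, two non-overlapping genes plus an overlapping pair
tiny_annotation <- function(seed = 11, chrom_len = 1200) {
  seqs <- c(chr1 = random_seq(chrom_len, seed = seed))
  intervals <- data.frame(
    gene_id = c("gA", "gA", "gB", "gB", "gC", "gD"),
    chrom = "chr1",
    strand = c("+", "+", "-", "-", "+", "-"),
    start = c(101L, 161L, 401L, 481L, 701L, 781L),
    end = c(150L, 260L, 460L, 560L, 820L, 900L),
    type = c("UTR", "exon", "exon", "UTR", "exon", "exon"),
    stringsAsFactors = FALSE
  )
  genome_annotation(seqs, intervals)
}

# a candidate table with sensible defaults, overridable per column
make_candidates <- function(n = 1, ..., seed = 1) {
  set.seed(seed)
  over <- list(...)
  cand <- data.table::data.table(
    accession = rep("acc001", n),
    chrom = rep("chr1", n),
    pos = seq(10L, by = 29L, length.out = n),
    ref = rep("C", n),
    alt = rep("T", n),
    ref_count = rep(30L, n),
    alt_count = rep(10L, n),
    coverage = rep(40L, n),
    ref_read_pos = replicate(n, sample.int(94L, 30L, TRUE) - 1L, simplify = FALSE),
    ref_mapq = replicate(n, rep(60, 30L), simplify = FALSE),
    ref_baseq = replicate(n, pmin(41, pmax(2, round(rnorm(30L, 36, 2)))),
                          simplify = FALSE),
    ref_strand = replicate(n, rbinom(30L, 1L, 0.5), simplify = FALSE),
    alt_read_pos = replicate(n, sample.int(94L, 10L, TRUE) - 1L, simplify = FALSE),
    alt_mapq = replicate(n, rep(60, 10L), simplify = FALSE),
    alt_baseq = replicate(n, pmin(41, pmax(2, round(rnorm(10L, 36, 2)))),
                          simplify = FALSE),
    alt_strand = replicate(n, rbinom(10L, 1L, 0.5), simplify = FALSE)
  )
  for (f in somarna:::FLAG_NAMES) cand[, (f) := FALSE]
  for (nm in names(over)) cand[[nm]] <- over[[nm]]
  cand
}

# pileup row constructor (counts + optional quality vectors)
make_pileup_row <- function(accession = "acc001", chrom = "chr1", pos = 100L,
                            ref = "C", counts = c(A = 0L, C = 34L, G = 0L, T = 6L),
                            baseq_ref = NULL, baseq_alt = NULL,
                            read_len = 94L) {
  cov <- sum(counts)
  nonref <- counts[setdiff(names(counts), ref)]
  alt <- if (any(nonref > 0)) names(nonref)[which.max(nonref)] else ""
  nref <- counts[[ref]]
  nalt <- if (nzchar(alt)) counts[[alt]] else 0L
  if (is.null(baseq_ref)) baseq_ref <- rep(36L, nref)
  if (is.null(baseq_alt)) baseq_alt <- rep(36L, nalt)
  join <- function(x) paste(x, collapse = ",")
  data.table::data.table(
    accession = accession, chrom = chrom, pos = pos, ref = ref, cov = cov,
    n_A = counts[["A"]], n_C = counts[["C"]], n_G = counts[["G"]],
    n_T = counts[["T"]],
    n_hq = sum(baseq_ref >= 30L) + sum(baseq_alt >= 30L),
    alt = alt,
    ref_read_pos = join(seq_len(nref) %% read_len),
    ref_mapq = join(rep(60L, nref)),
    ref_baseq = join(baseq_ref),
    ref_strand = join(rep_len(c(0L, 1L), nref)),
    alt_read_pos = if (nalt) join(seq_len(nalt) %% read_len) else "",
    alt_mapq = if (nalt) join(rep(60L, nalt)) else "",
    alt_baseq = if (nalt) join(baseq_alt) else "",
    alt_strand = if (nalt) join(rep_len(c(0L, 1L), nalt)) else ""
  )
}

flag_matrix <- function(candidates) {
  as.matrix(candidates[, somarna:::FLAG_NAMES, with = FALSE])
}
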
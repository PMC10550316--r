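# Candidate selection, germline removal and the artifact filters.

test_that("candidate selection enforces coverage, quality and minor count", {
  pu <- rbind(
    make_pileup_row(pos = 100L, counts = c(A = 0L, C = 34L, G = 0L, T = 6L)),   # boundary: emitted
    make_pileup_row(pos = 200L, counts = c(A = 0L, C = 33L, G = 0L, T = 6L)),   # cov 39: dropped
    make_pileup_row(pos = 300L, counts = c(A = 5L, C = 90L, G = 0L, T = 5L)),   # 3 calls: dropped
    make_pileup_row(pos = 400L, counts = c(A = 0L, C = 35L, G = 0L, T = 5L)),   # minor 5: dropped
    make_pileup_row(pos = 500L, counts = c(A = 0L, C = 40L, G = 0L, T = 0L))    # monoallelic: dropped
  )
  cand <- select_candidate_sites(pu)
  expect_identical(cand$pos, 100L)
  expect_identical(cand$ref, "C")
  expect_identical(cand$alt, "T")
  expect_identical(cand$ref_count, 34L)
  expect_identical(cand$alt_count, 6L)
})

test_that("allele support is counted over bases at or above the Phred threshold", {
  # 7 alt reads but one low-quality: high-quality minor count drops to 6
  r1 <- make_pileup_row(pos = 100L, counts = c(A = 0L, C = 40L, G = 0L, T = 7L),
                        baseq_alt = c(rep(36L, 6L), 12L))
  # 6 alt reads, two low-quality: minor count 4, dropped
  r2 <- make_pileup_row(pos = 200L, counts = c(A = 0L, C = 40L, G = 0L, T = 6L),
                        baseq_alt = c(rep(36L, 4L), 12L, 5L))
  cand <- select_candidate_sites(rbind(r1, r2))
  expect_identical(cand$pos, 100L)
  expect_identical(cand$alt_count, 6L)
})

test_that("germline matching is position-exact and by position only", {
  cand <- make_candidates(3, pos = c(100L, 200L, 300L))
  vcf <- data.frame(chrom = "chr1", pos = c(200L, 301L),
                    ref = c("C", "C"), alt = c("G", "A"))
  cand <- remove_germline(cand, vcf)
  expect_identical(cand$germline, c(FALSE, TRUE, FALSE))  # pos +/- 1 not flagged
  cand2 <- remove_germline(make_candidates(2), data.frame(
    chrom = character(0), pos = integer(0)))
  expect_false(any(cand2$germline))
})

test_that("region masks follow BED half-open convention at the boundaries", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", bed)  # 0-based half-open [10, 20)
  regions <- read_bed(bed)
  cand <- make_candidates(3, pos = c(11L, 20L, 21L))  # 1-based positions
  cand <- region_mask_filter(cand, regions, "blacklist")
  expect_identical(cand$blacklist, c(TRUE, TRUE, FALSE))
})

test_that("region masks agree with a brute-force membership scan", {
  set.seed(31)
  n <- 1000
  starts <- sample.int(5000, 50)
  ends <- starts + sample.int(40, 50, TRUE)
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends))
  pos <- sample.int(5200, n, TRUE)
  cand <- make_candidates(n, pos = pos)
  cand <- region_mask_filter(cand, regions, "rna_edit")
  brute <- vapply(pos, function(p) any(p >= starts & p <= ends), logical(1))
  expect_identical(cand$rna_edit, brute)
})

test_that("splice-junction proximity is measured to the terminal exonic base", {
  b <- data.frame(chrom = "chr1", pos = c(100L, 250L))
  cand <- make_candidates(4, pos = c(100L, 106L, 107L, 243L))
  cand <- splice_junction_filter(cand, b, min_distance = 7L)
  # distance 0 and 6 flagged; exactly 7 kept
  expect_identical(cand$splice_junction, c(TRUE, TRUE, FALSE, FALSE))

  set.seed(32)
  bpos <- sort(sample.int(10000, 40))
  pos <- sample.int(10000, 500, TRUE)
  cand2 <- make_candidates(500, pos = pos)
  cand2 <- splice_junction_filter(cand2, data.frame(chrom = "chr1", pos = bpos))
  brute <- vapply(pos, function(p) min(abs(p - bpos)) < 7, logical(1))
  expect_identical(cand2$splice_junction, brute)
})

test_that("binomial sequencing-error test matches a pmf-summation oracle", {
  expect_true(sequencing_error_test(40L, 0L))        # certain event
  expect_false(sequencing_error_test(40L, 6L))       # far above error rate
  expect_true(sequencing_error_test(10000L, 6L))     # mean np = 10, big tail
  expect_error(sequencing_error_test(0L, 0L), "positive")

  set.seed(33)
  n <- sample(40:500, 200, TRUE)
  k <- vapply(n, function(x) sample.int(min(x, 30L), 1L), integer(1))
  oracle <- mapply(function(n, k) sum(dbinom(k:n, n, 0.001)) >= 1e-4, n, k)
  expect_identical(sequencing_error_test(n, k), unname(oracle))
})

test_that("VAF test flags counts consistent with a true VAF of one half", {
  expect_true(vaf_test(0L, 40L))    # all reads alternate
  expect_false(vaf_test(34L, 6L))   # far below half
  expect_true(vaf_test(20L, 20L))   # exactly half
  set.seed(34)
  rn <- sample(10:200, 200, TRUE)
  rk <- vapply(rn, function(x) sample.int(x, 1L), integer(1))
  oracle <- mapply(function(n, k) sum(dbinom(0:k, n, 0.5)) > 0.05, rn, rk)
  expect_identical(vaf_test(rn - rk, rk), unname(oracle))
})

test_that("Mann-Whitney implementation agrees with wilcox.test", {
  set.seed(35)
  for (i in 1:20) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1))
    expect_equal(mann_whitney_u(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(15)
    expect_equal(mann_whitney_u(x, y),
                 wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  expect_equal(mann_whitney_u(rep(60, 10), rep(60, 25)), 1)  # total tie
  expect_true(is.na(mann_whitney_u(numeric(0), rnorm(5))))
})

test_that("bias tests flag shifted attributes and keep degenerate ties", {
  # alt read positions all 0 vs uniform ref: read-position flag set
  set.seed(36)
  rp_ref <- sample.int(94, 20, TRUE) - 1
  fl <- bias_tests(rep(0, 20), rep(60, 20), rep(36, 20), rbinom(20, 1, .5),
                   rp_ref, rep(60, 20), rep(36, 20), rbinom(20, 1, .5))
  expect_true(fl[["read_pos_bias"]])
  expect_false(fl[["map_qual_bias"]])  # total tie keeps the candidate

  # shifted mapping quality flags
  fl2 <- bias_tests(sample.int(94, 15, TRUE) - 1, rep(40, 15), rep(36, 15),
                    rbinom(15, 1, .5),
                    sample.int(94, 40, TRUE) - 1, rep(60, 40), rep(36, 40),
                    rbinom(40, 1, .5))
  expect_true(fl2[["map_qual_bias"]])

  # empty alt side: tests skipped, nothing flagged
  fl3 <- bias_tests(numeric(0), numeric(0), numeric(0), numeric(0),
                    rp_ref, rep(60, 20), rep(36, 20), rbinom(20, 1, .5))
  expect_false(any(fl3))
})

test_that("bias tests are calibrated under identical attribute distributions", {
  set.seed(37)
  pass <- replicate(200, {
    nref <- 40L; nalt <- 12L
    rp <- sample.int(94, nref, TRUE) - 1
    mq <- rep(60, nref)
    bq <- pmin(41, pmax(2, round(rnorm(nref, 36, 2))))
    st <- rbinom(nref, 1, 0.5)
    i <- sample.int(nref, nalt)  # alt values are a subsample of the ref values
    !any(bias_tests(rp[i], mq[i], bq[i], st[i], rp, mq, bq, st))
  })
  expect_gte(mean(pass), 0.9)
})

test_that("polynucleotide proximity agrees with a brute-force run scan", {
  seqs <- c(chr1 = paste0(random_seq(200, seed = 38), strrep("A", 8),
                          random_seq(200, seed = 39)))
  ann <- genome_annotation(seqs, data.frame(
    gene_id = "g1", chrom = "chr1", strand = "+", start = 1L,
    end = nchar(seqs), type = "exon"))
  run <- find_homopolymer_runs(seqs[["chr1"]])
  run <- run[run$end - run$start + 1 >= 8, ][1, ]  # the planted run

  cand <- make_candidates(3, pos = c(run$start - 5L, run$start - 21L,
                                     run$start + 2L))
  cand <- polynucleotide_filter(cand, ann)
  expect_identical(cand$polynucleotide, c(TRUE, FALSE, TRUE))

  set.seed(40)
  pos <- sample.int(nchar(seqs), 300, TRUE)
  cand2 <- polynucleotide_filter(make_candidates(300, pos = pos), ann)
  runs <- find_homopolymer_runs(seqs[["chr1"]])
  brute <- vapply(pos, function(p) {
    any(p >= runs$start - 20L & p <= runs$end + 20L)
  }, logical(1))
  expect_identical(cand2$polynucleotide, brute)

  expect_error(polynucleotide_filter(make_candidates(1, pos = 10000L), ann),
               "outside")
})

test_that("recurrence filter flags loci shared by accessions among survivors", {
  cand <- make_candidates(4,
    accession = c("a1", "a2", "a3", "a4"),
    pos = c(100L, 100L, 200L, 300L))
  cand <- recurrence_filter(cand, n_accessions = 100)
  expect_identical(cand$recurrent, c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(cand$recurrence_fraction))  # threshold ceil(4) = 4 > 2

  # the 4% rule: ceil(0.04 * 671) = 27 accessions
  cand27 <- make_candidates(27, accession = sprintf("a%02d", 1:27), pos = 500L)
  cand27 <- recurrence_filter(cand27, n_accessions = 671)
  expect_true(all(cand27$recurrence_fraction))
  cand26 <- make_candidates(26, accession = sprintf("a%02d", 1:26), pos = 500L)
  cand26 <- recurrence_filter(cand26, n_accessions = 671)
  expect_false(any(cand26$recurrence_fraction))
  expect_true(all(cand26$recurrent))

  # records already flagged by earlier filters do not count as survivors
  cand2 <- make_candidates(2, accession = c("a1", "a2"), pos = 100L,
                           vaf = c(TRUE, FALSE))
  cand2 <- recurrence_filter(cand2, n_accessions = 100)
  expect_identical(cand2$recurrent, c(FALSE, FALSE))
})

test_that("outlier accessions are detected by the groupwise IQR rule", {
  s <- data.frame(accession = sprintf("a%d", 1:5),
                  total_depth = c(100, 101, 102, 103, 104) * 1e3,
                  m = c(5, 5, 5, 5, 50))
  out <- outlier_accession_filter(s, n_groups = 1L)
  expect_identical(out$outlier, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # oracle with the type-7 quantile rule
  q <- quantile(s$m, c(.25, .75), type = 7)
  expect_identical(out$outlier,
                   s$m < q[1] - 1.5 * diff(q) | s$m > q[2] + 1.5 * diff(q))

  # identical mutation counts: nothing flagged in populated groups
  s2 <- data.frame(accession = sprintf("a%d", 1:8),
                   total_depth = seq(1e5, 1.7e5, 1e4), m = rep(3, 8))
  out2 <- outlier_accession_filter(s2, n_groups = 4L)
  populated <- tabulate(out2$depth_group)[out2$depth_group] > 1L
  expect_false(any(out2$outlier[populated]))

  # an accession isolated in the top depth bin is flagged
  s3 <- data.frame(accession = sprintf("a%d", 1:9),
                   total_depth = c(seq(1e5, 1.4e5, length.out = 8), 9e5),
                   m = rep(3, 9))
  out3 <- outlier_accession_filter(s3, n_groups = 4L)
  expect_true(out3$outlier[9])
  expect_false(any(out3$outlier[1:8]))

  expect_error(outlier_accession_filter(
    data.frame(accession = "a", total_depth = 1, m = 0)), "at least")
})

test_that("only unambiguous UTR/exonic positions are retained", {
  ann <- tiny_annotation()
  # gC and gD overlap on [781, 820]
  cand <- make_candidates(4, pos = c(200L, 800L, 350L, 750L))
  cand <- unambiguous_region_filter(cand, ann)
  expect_identical(cand$ambiguous_region, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("filters are idempotent and never clear existing flags", {
  ann <- tiny_annotation()
  cand <- make_candidates(5, pos = c(120L, 200L, 420L, 750L, 800L),
                          germline = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  before <- flag_matrix(cand)
  cand <- unambiguous_region_filter(cand, ann)
  cand <- splice_junction_filter(cand, exon_boundaries(ann))
  once <- flag_matrix(cand)
  expect_true(all(once >= before))
  cand <- unambiguous_region_filter(cand, ann)
  cand <- splice_junction_filter(cand, exon_boundaries(ann))
  expect_identical(flag_matrix(cand), once)
})
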
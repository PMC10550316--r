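#' Default run configuration
#'
#' All pipeline thresholds with their standard values: coverage cutoff 40
#' reads, Phred threshold 30, minor-allele count 6, splice distance 7 bp,
#' binomial sequencing-error test at p = 0.001 / alpha = 1e-4, VAF and bias
#' tests at alpha = 0.05, homopolymer runs of length 7 within a 20 bp
#' window, 4% recurrence fraction, 1.5 x IQR outlier rule over 4 depth
#' groups, and 10 cross-validation folds for the penalized model.
#'
#' @param ... overrides of individual values.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    min_coverage = 40L, min_base_phred = 30L, min_minor_count = 6L,
    splice_min_distance = 7L, seq_error_p = 0.001, seq_error_alpha = 1e-4,
    vaf_alpha = 0.05, bias_alpha = 0.05, polyrun_length = 7L,
    polyrun_window = 20L, recurrence_fraction = 0.04, iqr_k = 1.5,
    n_depth_groups = 4L, cv_folds = 10L, seed = 1L
  )
  utils::modifyList(cfg, list(...))
}

#' Read / write a run configuration as YAML
#' @param path file path.
#' @param config configuration list.
#' @return `read_config` returns the configuration merged over defaults.
#' @export
read_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# ---- FASTA -------------------------------------------------------------------

#' Read / write reference sequences as FASTA
#' @param path file path.
#' @param sequences named character vector of sequences.
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

# ---- GFF3 --------------------------------------------------------------------

#' Write annotation gene intervals as GFF3
#'
#' One feature row per UTR/exon interval (1-based closed, per the GFF3
#' standard), `Parent` carrying the gene id.
#'
#' @param annotation a [genome_annotation()].
#' @param path file path.
#' @export
write_gff3 <- function(annotation, path) {
  g <- annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom, ranges = IRanges::IRanges(g$start, g$end),
    strand = g$strand, type = ifelse(g$type == "exon", "exon", "UTR"),
    ID = sprintf("%s.%s.%d", g$gene_id, tolower(g$type), seq_len(nrow(g))),
    Parent = g$gene_id
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene intervals from GFF3
#'
#' @param path GFF3 file with `exon`/`UTR`-typed features whose `Parent`
#'   names the gene.
#' @param sequences named character vector of reference sequences (needed to
#'   validate bounds and rebuild a [genome_annotation()]).
#' @return A [genome_annotation()] (ambiguity labels recomputed).
#' @export
read_gff3 <- function(path, sequences) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- tolower(gr$type) %in% c("exon", "utr", "five_prime_utr", "three_prime_utr")
  gr <- gr[keep]
  parent <- as.character(gr$Parent)
  intervals <- data.frame(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    type = ifelse(tolower(gr$type) == "exon", "exon", "UTR"),
    stringsAsFactors = FALSE
  )
  genome_annotation(sequences, intervals)
}

# ---- BED / bedGraph ----------------------------------------------------------

#' Read / write 3-column BED mask files
#'
#' BED is 0-based half-open on disk; in memory intervals are 1-based closed
#' GRanges. The conversion happens here and only here.
#'
#' @param path file path.
#' @param regions GRanges.
#' @return `read_bed` returns a GRanges.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  GenomicRanges::granges(gr)
}

#' @rdname read_bed
#' @export
write_bed <- function(regions, path) {
  rtracklayer::export(regions, path, format = "bed")
  invisible(path)
}

#' Read / write 4-column bedGraph signal tracks
#'
#' @param path file path.
#' @param track GRanges with a numeric `score`.
#' @return `read_bedgraph` returns a GRanges with `score`.
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}

# ---- VCF ---------------------------------------------------------------------

#' Write germline variants as a minimal VCF 4.2
#'
#' @param variants data.frame with `chrom`, `pos` (1-based), `ref`, `alt`
#'   (comma-separated for multi-allelic records).
#' @param path file path.
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##source=somarna", as.character(utils::packageVersion("somarna"))),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(variants)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                       variants$chrom, as.integer(variants$pos),
                       variants$ref, variants$alt), con)
  }
  invisible(path)
}

#' Read variant positions from VCF
#'
#' Multi-allelic records are split into one row per alternate allele;
#' positions stay 1-based. Germline matching downstream is by position only.
#'
#' @param path VCF file.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fx) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  }
  alts <- strsplit(fx$ALT, ",", fixed = TRUE)
  n <- lengths(alts)
  data.frame(
    chrom = rep(fx$CHROM, n),
    pos = rep(as.integer(fx$POS), n),
    ref = rep(fx$REF, n),
    alt = unlist(alts),
    stringsAsFactors = FALSE
  )
}

# ---- pileup / candidate / truth TSV -----------------------------------------

PILEUP_SCHEMA <- "#somarna_pileup_v1"
CANDIDATE_SCHEMA <- "#somarna_candidates_v1"

#' Read / write the pileup TSV
#'
#' One row per accession x site; per-read attribute vectors are
#' comma-joined fields. The first line is a schema-version comment.
#'
#' @param pileup pileup data.table.
#' @param path file path.
#' @return `read_pileup` returns the pileup data.table.
#' @export
write_pileup <- function(pileup, path) {
  con <- file(path, "w")
  writeLines(PILEUP_SCHEMA, con)
  close(con)
  data.table::fwrite(pileup, path, sep = "\t", append = TRUE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, PILEUP_SCHEMA)) {
    stop("not a somarna pileup file (schema line missing): ", path)
  }
  dt <- data.table::fread(path, sep = "\t", skip = 1L, header = TRUE,
                          colClasses = list(character = c(
                            "ref_read_pos", "ref_mapq", "ref_baseq", "ref_strand",
                            "alt_read_pos", "alt_mapq", "alt_baseq", "alt_strand",
                            "alt")),
                          na.strings = NULL)
  dt[is.na(alt), alt := ""]
  dt[]
}

#' Write a flag-annotated candidate table as TSV
#'
#' Attribute list-columns are comma-joined; a logical `PASS` column (no flag
#' set) is appended.
#'
#' @param candidates candidate table from [call_somatic_mutations()].
#' @param path file path.
#' @export
write_candidates <- function(candidates, path) {
  out <- data.table::copy(candidates)
  vec_cols <- grep("^(ref|alt)_(read_pos|mapq|baseq|strand)$", names(out), value = TRUE)
  for (cc in vec_cols) {
    out[, (cc) := vapply(out[[cc]], join_num, character(1))]
  }
  out[, PASS := candidate_passes(candidates)]
  con <- file(path, "w")
  writeLines(CANDIDATE_SCHEMA, con)
  close(con)
  data.table::fwrite(out, path, sep = "\t", append = TRUE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, CANDIDATE_SCHEMA)) {
    stop("not a somarna candidate file (schema line missing): ", path)
  }
  dt <- data.table::fread(path, sep = "\t", skip = 1L, header = TRUE,
                          na.strings = NULL)
  vec_cols <- grep("^(ref|alt)_(read_pos|mapq|baseq|strand)$", names(dt), value = TRUE)
  for (cc in vec_cols) {
    dt[, (cc) := parse_vec(as.character(dt[[cc]]))]
  }
  dt[]
}
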
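#' Run the full simulate - call - features - model pipeline
#'
#' Simulates a genome, tracks, germline variants and pileup, writes every
#' stage's inputs and outputs in their standard formats under `outdir`
#' (FASTA, GFF3, VCF, BED, bedGraph, TSV), runs the calling cascade from the
#' files on disk, derives the modeling table and fits the penalized Poisson
#' model per mutation type, and records a provenance manifest (input
#' checksums, resolved configuration, seed, package version). Re-running
#' with an identical configuration reproduces identical outputs.
#'
#' @param config configuration list (see [default_config()]); recognised
#'   simulation entries: `n_chrom`, `n_genes`, `n_accessions`,
#'   `mean_coverage`, `truth_spec` overrides, `fit_models` (logical).
#' @param outdir output directory (created).
#' @return Invisibly, a list with the stage outputs (`annotation`, `sim`,
#'   `called`, `features`, `fits`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  cfg <- utils::modifyList(default_config(), config)
  cfg$n_chrom <- cfg$n_chrom %||% 2L
  cfg$n_genes <- cfg$n_genes %||% 20L
  cfg$n_accessions <- cfg$n_accessions %||% 50L
  cfg$mean_coverage <- cfg$mean_coverage %||% 100
  cfg$fit_models <- cfg$fit_models %||% TRUE
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed

  # ---- simulate --------------------------------------------------------------
  ann <- simulate_genome(n_chrom = cfg$n_chrom, n_genes = cfg$n_genes,
                         seed = seed)
  trk <- simulate_tracks(ann, seed = seed)
  germ <- simulate_germline(ann, seed = seed)
  sim <- simulate_pileup(ann,
                         truth_spec = cfg$truth_spec %||% list(),
                         n_accessions = cfg$n_accessions,
                         depth_params = list(mean_coverage = cfg$mean_coverage),
                         germline = germ,
                         masks = list(trk$blacklist, trk$rna_edit),
                         seed = seed)

  write_fasta(ann$sequences, file.path(outdir, "reference.fa"))
  write_gff3(ann, file.path(outdir, "annotation.gff3"))
  write_vcf(germ, file.path(outdir, "germline.vcf"))
  write_bed(trk$blacklist, file.path(outdir, "blacklist.bed"))
  write_bed(trk$rna_edit, file.path(outdir, "rna_edit.bed"))
  write_bedgraph(trk$tracks$replication_timing$early,
                 file.path(outdir, "replication_timing_early.bedGraph"))
  write_bedgraph(trk$tracks$replication_timing$late,
                 file.path(outdir, "replication_timing_late.bedGraph"))
  for (tr in CHROMATIN_TRACKS) {
    write_bedgraph(trk$tracks[[tr]], file.path(outdir, paste0(tr, ".bedGraph")))
  }
  write_pileup(sim$pileup, file.path(outdir, "pileup.tsv"))
  data.table::fwrite(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t")
  write_config(cfg[order(names(cfg))], file.path(outdir, "config_resolved.yaml"))

  # ---- call from the files on disk ------------------------------------------
  sequences <- read_fasta(file.path(outdir, "reference.fa"))
  ann2 <- read_gff3(file.path(outdir, "annotation.gff3"), sequences)
  pileup <- read_pileup(file.path(outdir, "pileup.tsv"))
  called <- call_somatic_mutations(
    pileup, ann2,
    germline = read_vcf(file.path(outdir, "germline.vcf")),
    blacklist = read_bed(file.path(outdir, "blacklist.bed")),
    rna_edit = read_bed(file.path(outdir, "rna_edit.bed")),
    config = cfg
  )
  write_candidates(called$candidates, file.path(outdir, "candidates.tsv"))
  utils::write.table(called$accession_summary,
                     file.path(outdir, "accession_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- features --------------------------------------------------------------
  sp <- site_pass_table(pileup, min_coverage = cfg$min_coverage)
  feats <- build_feature_table(called$pass, ann2, trk$tracks, sp)
  data.table::fwrite(feats, file.path(outdir, "model_features.tsv"), sep = "\t")

  # ---- model -----------------------------------------------------------------
  fits <- NULL
  if (isTRUE(cfg$fit_models)) {
    fits <- lapply(MUTATION_TYPES, function(mt) {
      rows <- feats[feats$mutation_type == mt & feats$d_star > 0, ]
      if (nrow(rows) < 2L * cfg$cv_folds || sum(rows$m) == 0L) return(NULL)
      fit <- tryCatch(
        suppressWarnings(fit_poisson_lasso(rows, folds = cfg$cv_folds,
                                           seed = seed)),
        error = function(e) NULL)
      fit
    })
    names(fits) <- MUTATION_TYPES
    keep <- !vapply(fits, is.null, logical(1))
    if (any(keep)) {
      coefs <- do.call(rbind, lapply(fits[keep], coef))
      utils::write.table(
        data.frame(mutation_type = rownames(coefs), coefs,
                   check.names = FALSE),
        file.path(outdir, "model_fit.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # ---- manifest --------------------------------------------------------------
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = "somarna",
    version = as.character(utils::packageVersion("somarna")),
    seed = seed,
    config = cfg[order(names(cfg))],
    files = as.list(tools::md5sum(file.path(outdir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(annotation = ann2, sim = sim, tracks = trk, called = called,
                 features = feats, fits = fits, manifest = manifest))
}

#' Summarize pipeline recovery against planted truth
#'
#' Joins the flag-annotated candidate table with the simulation truth and
#' reports, per planted class, how many records passed every filter, were
#' flagged, or never reached candidacy.
#'
#' @param called result of [call_somatic_mutations()].
#' @param truth truth table from [simulate_pileup()].
#' @return data.table with per-class counts `n`, `pass`, `flagged`,
#'   `not_selected`.
#' @export
recovery_summary <- function(called, truth) {
  tr <- data.table::as.data.table(truth)
  cand <- called$candidates
  if (nrow(cand)) {
    cd <- data.table::data.table(
      accession = cand$accession, chrom = cand$chrom, pos = cand$pos,
      selected = TRUE, pass = candidate_passes(cand)
    )
    tr <- merge(tr, cd, by = c("accession", "chrom", "pos"), all.x = TRUE)
  } else {
    tr[, `:=`(selected = NA, pass = NA)]
  }
  tr[is.na(selected), selected := FALSE]
  tr[is.na(pass), pass := FALSE]
  tr[, .(n = .N, pass = sum(pass), flagged = sum(selected & !pass),
         not_selected = sum(!selected)), by = class]
}
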
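#' Default covariate specification for track simulation
#'
#' One row per signal track: the genewise target mean and standard deviation,
#' plus (via `cor`) the target correlation matrix across tracks. Chromatin
#' tracks (accessibility, methylation, histone marks) live on `[0, 1]`;
#' `replication_timing` is the latent log2 late/early ratio realized as a
#' pair of strictly positive early/late tracks.
#'
#' @param cor optional named correlation matrix over the track names; default
#'   identity.
#' @return list with elements `tracks` (data.frame `name`, `mean`, `sd`) and
#'   `cor`.
#' @export
default_covariate_spec <- function(cor = NULL) {
  nm <- c("replication_timing", CHROMATIN_TRACKS)
  tracks <- data.frame(
    name = nm,
    mean = c(0, rep(0.4, length(CHROMATIN_TRACKS))),
    sd = c(0.8, rep(0.12, length(CHROMATIN_TRACKS))),
    stringsAsFactors = FALSE
  )
  if (is.null(cor)) {
    cor <- diag(length(nm))
    dimnames(cor) <- list(nm, nm)
  }
  list(tracks = tracks, cor = cor)
}

#' Simulate genomic signal tracks and mask regions
#'
#' Draws a per-gene latent multivariate normal with the requested correlation
#' structure and realizes it as piecewise-constant bedGraph-style region
#' signals: each gene span is split into 2-3 adjacent regions carrying the
#' gene's value (which also exercises split-invariance of downstream
#' aggregation), and intergenic space receives independent draws. Chromatin
#' signals are clamped to `[0, 1]`; replication timing is emitted as an
#' early/late track pair with early fixed at 1 and late = 2^latent, so the
#' genewise log2 late/early feature recovers the latent value.
#'
#' @param annotation a [genome_annotation()].
#' @param covariate_spec see [default_covariate_spec()]; its correlation
#'   matrix must be positive definite.
#' @param n_blacklist,n_rna_edit number of blacklist intervals / RNA-edit
#'   positions to scatter over gene space.
#' @param seed integer seed.
#' @return list with `tracks` (named list of GRanges with `score`;
#'   `replication_timing` is itself a list with `early` and `late`),
#'   `blacklist` and `rna_edit` (GRanges), and `gene_values` (the latent
#'   per-gene track values, for calibration checks).
#' @export
simulate_tracks <- function(annotation, covariate_spec = default_covariate_spec(),
                            n_blacklist = 4L, n_rna_edit = 6L, seed = 1L) {
  tracks <- covariate_spec$tracks
  cormat <- covariate_spec$cor
  nm <- tracks$name
  stopifnot(identical(sort(rownames(cormat)), sort(nm)))
  cormat <- cormat[nm, nm]
  ch <- tryCatch(chol(cormat), error = function(e) {
    stop("covariate correlation matrix is not positive definite")
  })
  set.seed(sub_seed(seed, "tracks"))

  g <- annotation$genes
  gene_ids <- unique(g$gene_id)
  spans <- do.call(rbind, lapply(gene_ids, function(id) {
    gi <- g[g$gene_id == id, ]
    data.frame(gene_id = id, chrom = gi$chrom[1],
               start = min(gi$start), end = max(gi$end),
               stringsAsFactors = FALSE)
  }))

  # latent per-gene values with requested correlation
  z <- matrix(stats::rnorm(nrow(spans) * length(nm)), nrow(spans)) %*% ch
  colnames(z) <- nm
  gene_values <- sweep(sweep(z, 2L, tracks$sd, `*`), 2L, tracks$mean, `+`)
  rownames(gene_values) <- spans$gene_id

  chrom_len <- nchar(annotation$sequences)

  region_table <- function(track) {
    regs <- list()
    for (cn in names(chrom_len)) {
      sp <- spans[spans$chrom == cn, ]
      sp <- sp[order(sp$start), ]
      # merge overlapping gene spans into blocks; a block's regions carry the
      # mean latent value of its genes
      cur <- 1L
      blocks <- list()
      if (nrow(sp)) {
        bstart <- sp$start[1]; bend <- sp$end[1]; members <- sp$gene_id[1]
        for (i in seq_len(nrow(sp))[-1]) {
          if (sp$start[i] <= bend) {
            bend <- max(bend, sp$end[i]); members <- c(members, sp$gene_id[i])
          } else {
            blocks[[length(blocks) + 1L]] <- list(start = bstart, end = bend, members = members)
            bstart <- sp$start[i]; bend <- sp$end[i]; members <- sp$gene_id[i]
          }
        }
        blocks[[length(blocks) + 1L]] <- list(start = bstart, end = bend, members = members)
      }
      prev_end <- 0L
      for (b in blocks) {
        if (b$start > prev_end + 1L) {
          regs[[length(regs) + 1L]] <- data.frame(
            chrom = cn, start = prev_end + 1L, end = b$start - 1L,
            value = stats::rnorm(1L, mean(gene_values[, track]), stats::sd(gene_values[, track]) + 1e-9),
            stringsAsFactors = FALSE
          )
        }
        val <- mean(gene_values[b$members, track])
        # split the block into 2-3 adjacent regions with the same value
        k <- sample(2:3, 1L)
        cuts <- sort(sample((b$start + 1L):(b$end - 1L), k - 1L))
        bounds <- c(b$start, cuts, b$end + 1L)
        for (j in seq_len(k)) {
          regs[[length(regs) + 1L]] <- data.frame(
            chrom = cn, start = bounds[j], end = bounds[j + 1L] - 1L,
            value = val, stringsAsFactors = FALSE
          )
        }
        prev_end <- b$end
      }
      if (prev_end < chrom_len[cn]) {
        regs[[length(regs) + 1L]] <- data.frame(
          chrom = cn, start = prev_end + 1L, end = chrom_len[cn],
          value = stats::rnorm(1L, mean(gene_values[, track]), stats::sd(gene_values[, track]) + 1e-9),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, regs)
  }

  as_granges <- function(df, score) {
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                           score = score)
  }

  out_tracks <- list()
  for (track in nm) {
    df <- region_table(track)
    if (track == "replication_timing") {
      out_tracks[[track]] <- list(
        early = as_granges(df, score = rep(1, nrow(df))),
        late = as_granges(df, score = 2^df$value)
      )
    } else {
      out_tracks[[track]] <- as_granges(df, score = pmin(1, pmax(0, df$value)))
    }
  }

  # masks: small intervals / single positions scattered over gene space
  all_pos <- annotation_positions(annotation)
  bl <- NULL
  if (n_blacklist > 0L && nrow(all_pos)) {
    idx <- sample.int(nrow(all_pos), min(n_blacklist, nrow(all_pos)))
    bl <- GenomicRanges::reduce(GenomicRanges::GRanges(
      all_pos$chrom[idx],
      IRanges::IRanges(all_pos$pos[idx], all_pos$pos[idx] + sample(10:40, length(idx), TRUE))
    ))
  } else {
    bl <- GenomicRanges::GRanges()
  }
  re <- NULL
  if (n_rna_edit > 0L && nrow(all_pos)) {
    idx <- sample.int(nrow(all_pos), min(n_rna_edit, nrow(all_pos)))
    re <- GenomicRanges::GRanges(all_pos$chrom[idx],
                                 IRanges::IRanges(all_pos$pos[idx], all_pos$pos[idx]))
  } else {
    re <- GenomicRanges::GRanges()
  }

  list(tracks = out_tracks, blacklist = bl, rna_edit = re,
       gene_values = gene_values)
}

#' Simulate annotated germline variants
#'
#' Picks positions inside annotated gene intervals and assigns a random
#' non-reference alternate allele; these stand for the imputed germline
#' variant catalog that the germline-removal step consumes.
#'
#' @param annotation a [genome_annotation()].
#' @param n_variants number of variants.
#' @param seed integer seed.
#' @return data.frame with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @export
simulate_germline <- function(annotation, n_variants = 40L, seed = 1L) {
  set.seed(sub_seed(seed, "germline"))
  all_pos <- annotation_positions(annotation)
  all_pos <- unique(all_pos[, .(chrom, pos, ref)])
  idx <- sample.int(nrow(all_pos), min(n_variants, nrow(all_pos)))
  out <- as.data.frame(all_pos[idx])
  out$alt <- vapply(out$ref, function(r) sample(setdiff(BASES, r), 1L), character(1))
  out[order(out$chrom, out$pos), ]
}
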
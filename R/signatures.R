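#' Names of the 96 trinucleotide mutation channels
#'
#' Six pyrimidine mutation types by 16 flanking-base contexts, in the
#' conventional order `A[C>A]A` ... `T[T>G]T`.
#'
#' @return Character vector of length 96.
#' @export
catalog_channels <- function() {
  out <- character(0)
  for (mt in MUTATION_TYPES) {
    ref <- substr(mt, 1L, 1L)
    for (five in BASES) for (three in BASES) {
      out <- c(out, paste0(five, "[", mt, "]", three))
    }
  }
  out
}

#' Build a 96-channel trinucleotide mutational catalog
#'
#' Each mutation is collapsed to its pyrimidine representation; for
#' purine-reference mutations the flanking context is reverse-complemented.
#' Mutations whose flank falls off a chromosome end are skipped.
#'
#' @param mutations data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   (when `by` is used) the grouping column.
#' @param annotation a [genome_annotation()] providing reference sequences.
#' @param by optional column name (e.g. `"accession"`); when given, returns
#'   a groups x 96 count matrix, otherwise a single named count vector.
#' @return Named integer vector of length 96, or a matrix with one row per
#'   group.
#' @export
build_catalog <- function(mutations, annotation, by = NULL) {
  mut <- as.data.frame(mutations)
  channels <- catalog_channels()
  lens <- nchar(annotation$sequences)[match(mut$chrom, names(annotation$sequences))]
  valid <- mut$pos > 1L & mut$pos < lens
  if (any(!valid)) {
    message(sum(!valid), " mutation(s) skipped: flank off chromosome end")
    mut <- mut[valid, , drop = FALSE]
  }
  if (nrow(mut) == 0L) {
    v <- stats::setNames(integer(96L), channels)
    if (is.null(by)) return(v)
    return(matrix(integer(0), 0L, 96L, dimnames = list(NULL, channels)))
  }
  tri <- substring(annotation$sequences[mut$chrom], mut$pos - 1L, mut$pos + 1L)
  ref <- mut$ref; alt <- mut$alt
  is_pur <- !(ref %in% PYRIMIDINES)
  tri[is_pur] <- revcomp(tri[is_pur])
  ref[is_pur] <- comp_base(ref[is_pur])
  alt[is_pur] <- comp_base(alt[is_pur])
  ch <- paste0(substr(tri, 1L, 1L), "[", ref, ">", alt, "]", substr(tri, 3L, 3L))
  if (is.null(by)) {
    v <- table(factor(ch, levels = channels))
    return(stats::setNames(as.integer(v), channels))
  }
  tab <- table(factor(mut[[by]]), factor(ch, levels = channels))
  m <- matrix(as.integer(tab), nrow(tab), 96L,
              dimnames = list(rownames(tab), channels))
  m
}

#' Cosine similarity of two nonnegative vectors
#'
#' @param a,b equal-length nonnegative vectors, not both zero.
#' @return `dot(a, b) / (|a| |b|)`, in `[0, 1]` for nonnegative input.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Extract mutational signatures by deterministic KL nonnegative factorization
#'
#' Factorizes a samples x 96 catalog matrix `V' ~ W H` (signatures x
#' exposures) by multiplicative updates minimizing generalized
#' Kullback-Leibler divergence, from a seeded random initialization, and
#' renormalizes each signature to a probability vector. This is a
#' deterministic factorization; it reports the cosine similarity between
#' the aggregate observed catalog and its reconstruction.
#'
#' @param catalog matrix (samples x 96) or single named 96-vector.
#' @param k number of signatures (>= 1, at most the number of channels).
#' @param seed seed for the initialization.
#' @param n_iter maximum multiplicative-update iterations.
#' @param tol relative change in KL divergence for early stopping.
#' @return list with `signatures` (k x 96, rows sum to 1), `exposures`
#'   (samples x k, estimated mutation counts per signature) and
#'   `reconstruction_cosine`.
#' @export
extract_signatures <- function(catalog, k = 2L, seed = 1L, n_iter = 2000L,
                               tol = 1e-10) {
  if (is.null(dim(catalog))) catalog <- matrix(catalog, 1L,
                                               dimnames = list(NULL, names(catalog)))
  v <- t(catalog)  # channels x samples
  if (k > nrow(v)) stop("k exceeds the number of channels")
  if (k < 1L) stop("k must be >= 1")
  set.seed(sub_seed(seed, "nmf"))
  n <- nrow(v); s <- ncol(v)
  w <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  h <- matrix(stats::runif(k * s, 0.1, 1), k, s)
  eps <- 1e-12
  kl <- function(v, wh) sum(ifelse(v > 0, v * log(v / wh), 0) - v + wh)
  last <- Inf
  for (it in seq_len(n_iter)) {
    wh <- w %*% h + eps
    h <- h * (t(w) %*% (v / wh)) / (colSums(w) + eps)
    wh <- w %*% h + eps
    w <- w * ((v / wh) %*% t(h)) / matrix(rowSums(h), n, k, byrow = TRUE)
    if (it %% 20L == 0L) {
      cur <- kl(v, w %*% h + eps)
      if (is.finite(last) && abs(last - cur) < tol * (abs(last) + eps)) break
      last <- cur
    }
  }
  scale_w <- colSums(w)
  w <- sweep(w, 2L, scale_w, `/`)
  h <- sweep(h, 1L, scale_w, `*`)
  recon <- w %*% h
  agg <- rowSums(v)
  sig <- t(w)
  colnames(sig) <- rownames(v)
  rownames(sig) <- paste0("signature", seq_len(k))
  list(
    signatures = sig,
    exposures = t(h),
    reconstruction_cosine = cosine_similarity(agg, rowSums(recon))
  )
}

#' Match extracted signatures to a reference set
#'
#' Greedy best-match assignment by cosine similarity, e.g. against planted
#' signatures in simulations or a user-supplied reference signature table.
#'
#' @param signatures k x 96 matrix (rows sum to 1).
#' @param reference r x 96 matrix of reference signatures.
#' @return data.frame with `signature`, `reference`, `cosine`.
#' @export
match_signatures <- function(signatures, reference) {
  sims <- matrix(NA_real_, nrow(signatures), nrow(reference))
  for (i in seq_len(nrow(signatures))) {
    for (j in seq_len(nrow(reference))) {
      sims[i, j] <- cosine_similarity(signatures[i, ], reference[j, ])
    }
  }
  out <- list()
  avail <- seq_len(nrow(reference))
  for (i in order(-apply(sims, 1L, max))) {
    j <- avail[which.max(sims[i, avail])]
    avail <- setdiff(avail, j)
    out[[length(out) + 1L]] <- data.frame(
      signature = rownames(signatures)[i] %||% i,
      reference = rownames(reference)[j] %||% j,
      cosine = sims[i, j]
    )
    if (!length(avail)) break
  }
  do.call(rbind, out)
}
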
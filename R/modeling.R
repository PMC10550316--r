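#' Fit the penalized Poisson mutation-rate model for one mutation type
#'
#' Maximizes the Poisson log-likelihood of genewise mutation counts with
#' offset `log(b)` and linear predictor
#' `alpha + kappa * log(d_star) + gamma * 1[template] + X beta`,
#' under an L1 penalty on `kappa`, `gamma` and `beta` (the intercept is
#' unpenalized). The penalty weight is chosen on a log-spaced grid from the
#' smallest value zeroing all penalized coefficients down to 1e-4 of it, by
#' K-fold cross-validation minimizing mean held-out Poisson deviance.
#' Covariates are expected pre-standardized; `log(d_star)` and the strand
#' indicator enter unstandardized so `kappa` and `gamma` keep their units.
#'
#' @param rows modeling table for one mutation type (see
#'   [build_feature_table()]): columns `m`, `b` (> 0), `d_star` (> 0),
#'   `strand_class` and covariates.
#' @param folds number of cross-validation folds (default 10).
#' @param lambda optional user lambda grid (passed to glmnet).
#' @param covariates covariate column names (defaults to the package's
#'   standard set intersected with `rows`).
#' @param seed seed controlling the fold assignment.
#' @return A `model_fit`: list with `alpha`, `kappa`, `gamma`, `beta` (named
#'   vector), `lambda`, `cv` (lambda grid and mean held-out deviance),
#'   `mutation_type` and the fitted glmnet object.
#' @export
fit_poisson_lasso <- function(rows, folds = 10L, lambda = NULL,
                              covariates = NULL, seed = 1L) {
  rows <- data.table::as.data.table(rows)
  stopifnot(all(rows$b > 0), all(rows$d_star > 0))
  if (is.null(covariates)) {
    covariates <- intersect(COVARIATE_NAMES, names(rows))
  }
  x <- cbind(
    log_d_star = log(rows$d_star),
    template = as.numeric(rows$strand_class == "template"),
    as.matrix(rows[, covariates, with = FALSE])
  )
  if (any(!is.finite(x))) stop("non-finite covariates in modeling table")
  y <- rows$m
  off <- log(rows$b)
  mt <- if ("mutation_type" %in% names(rows)) rows$mutation_type[1] else NA_character_

  if (all(y == 0)) {
    warning("all mutation counts are zero; returning degenerate fit")
    beta <- stats::setNames(rep(0, length(covariates)), covariates)
    return(structure(list(alpha = -Inf, kappa = 0, gamma = 0, beta = beta,
                          lambda = NA_real_, cv = NULL, mutation_type = mt,
                          glmnet_fit = NULL),
                     class = "model_fit"))
  }

  set.seed(sub_seed(seed, "cvfolds"))
  foldid <- sample(rep_len(seq_len(folds), nrow(x)))
  cvfit <- glmnet::cv.glmnet(
    x, y, family = "poisson", offset = off, foldid = foldid,
    lambda = lambda, nlambda = 100L, lambda.min.ratio = 1e-4,
    standardize = FALSE, type.measure = "deviance"
  )
  co <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  names(co) <- rownames(stats::coef(cvfit, s = "lambda.min"))
  beta <- co[covariates]
  structure(list(
    alpha = co[["(Intercept)"]],
    kappa = co[["log_d_star"]],
    gamma = co[["template"]],
    beta = beta,
    lambda = cvfit$lambda.min,
    cv = data.frame(lambda = cvfit$lambda, mean_deviance = cvfit$cvm),
    mutation_type = mt,
    glmnet_fit = cvfit
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Penalized Poisson mutation-rate model",
      if (!is.na(x$mutation_type)) paste0("(", x$mutation_type, ")"), "\n")
  cat(sprintf("  alpha = %.4f  kappa = %.4f  gamma = %.4f  lambda = %.4g\n",
              x$alpha, x$kappa, x$gamma, x$lambda))
  nz <- sum(x$beta != 0)
  cat("  covariates:", length(x$beta), "(", nz, "nonzero )\n")
  invisible(x)
}

#' Coefficients of a penalized mutation-rate model
#' @param object a `model_fit`.
#' @param ... unused.
#' @return Named numeric vector: alpha, kappa, gamma and the covariates.
#' @export
coef.model_fit <- function(object, ...) {
  c(alpha = object$alpha, kappa = object$kappa, gamma = object$gamma,
    object$beta)
}

#' Partial-correlation t-values of covariates with normalized mutation count
#'
#' For each covariate x, the partial correlation of x with `y = m / b`
#' conditioned on `z = log(d_star)`:
#' `r = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`,
#' `t = r sqrt(n - 3) / sqrt(1 - r^2)`.
#' A covariate collinear with the conditioning variable is reported as 0
#' with a warning; zero-variance inputs give `NA`.
#'
#' @param rows modeling table for one mutation type.
#' @param covariates covariate columns (default: standard set plus the
#'   template-strand indicator).
#' @return data.frame with `covariate`, `r`, `t`.
#' @export
partial_correlation_tvalues <- function(rows, covariates = NULL) {
  rows <- data.table::as.data.table(rows)
  n <- nrow(rows)
  if (n < 4L) stop("need at least 4 rows")
  if (is.null(covariates)) {
    covariates <- intersect(COVARIATE_NAMES, names(rows))
    if ("strand_class" %in% names(rows)) covariates <- c("template", covariates)
  }
  y <- rows$m / rows$b
  z <- log(rows$d_star)
  dat <- rows
  if ("strand_class" %in% names(rows)) {
    dat <- data.table::copy(rows)[, template := as.numeric(strand_class == "template")]
  }
  res <- lapply(covariates, function(cc) {
    x <- dat[[cc]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0) {
      return(data.frame(covariate = cc, r = NA_real_, t = NA_real_))
    }
    rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
    if (abs(rxz) >= 1 - 1e-12) {
      warning("covariate ", cc, " is collinear with log normalized depth")
      return(data.frame(covariate = cc, r = 0, t = 0))
    }
    r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    t <- r * sqrt(n - 3) / sqrt(1 - r^2)
    data.frame(covariate = cc, r = r, t = t)
  })
  do.call(rbind, res)
}

#' Per-locus recurrence table
#'
#' For each locus: the number of accessions with nonzero coverage `c`, the
#' summed depth `d`, the cross-accession mutation count `m` and the
#' per-alternate-allele accession counts.
#'
#' @param pileup site-observation table.
#' @param mutations data.frame of mutation records (`accession`, `chrom`,
#'   `pos`, `alt`), typically candidates surviving the pre-recurrence
#'   filters.
#' @param min_mutations keep only loci with at least this many mutations
#'   (default 0 keeps every covered locus).
#' @return data.table with `chrom`, `pos`, `c`, `d`, `m` and `alt_counts`
#'   (list of named accession counts per alternate base).
#' @export
locus_recurrence_table <- function(pileup, mutations, min_mutations = 0L) {
  pu <- data.table::as.data.table(pileup)
  loci <- pu[cov > 0L, .(c = .N, d = sum(as.numeric(cov))), by = .(chrom, pos)]
  mut <- data.table::as.data.table(mutations)
  if (nrow(mut)) {
    mc <- mut[, .(m = length(unique(accession)),
                  alt_counts = list(table(alt))), by = .(chrom, pos)]
    loci <- merge(loci, mc, by = c("chrom", "pos"), all.x = TRUE)
    loci[is.na(m), m := 0L]
    loci[vapply(alt_counts, is.null, logical(1)), alt_counts := list(list(NULL))]
  } else {
    loci[, m := 0L]
    loci[, alt_counts := list(list(NULL))]
  }
  loci[m >= min_mutations]
}

#' Poisson model of locus-level mutation recurrence
#'
#' Models the cross-accession mutation count at each locus as
#' `E[m] / c = exp(alpha + beta log(d / c))`, i.e. a Poisson regression of
#' `m` with offset `log(c)` on the log mean depth per covered accession.
#'
#' @param loci table from [locus_recurrence_table()] (requires `c >= 1`,
#'   `d > 0`).
#' @return list with `alpha`, `beta`, `expected` (per-locus expected counts
#'   at the MLE) and the `glm` fit.
#' @export
fit_recurrence_model <- function(loci) {
  loci <- data.table::as.data.table(loci)
  stopifnot(all(loci$c >= 1L), all(loci$d > 0))
  df <- data.frame(m = loci$m, x = log(loci$d / loci$c), off = log(loci$c))
  fit <- stats::glm(m ~ x + offset(off), family = stats::poisson(), data = df)
  co <- stats::coef(fit)
  list(alpha = unname(co[1]), beta = unname(co[2]),
       expected = as.numeric(stats::predict(fit, type = "response")),
       fit = fit)
}

#' Alternate-allele entropy of a recurrent locus
#'
#' `-sum_b p(b) log p(b)` over the non-reference bases, where `p(b)` is the
#' fraction of mutation-carrying accessions whose alternate allele is `b`
#' (natural logarithm; `0 log 0 = 0`). A locus where every accession carries
#' the same alternate allele has entropy 0; the uniform three-allele limit
#' is `log(3)`, approximately 1.10.
#'
#' @param alt_counts numeric vector of accession counts per alternate base
#'   (names optional), e.g. `c(A = 2, G = 1)`; must sum to >= 1.
#' @return Entropy in nats.
#' @export
alt_allele_entropy <- function(alt_counts) {
  alt_counts <- alt_counts[alt_counts > 0]
  if (length(alt_counts) == 0L || sum(alt_counts) < 1) {
    stop("entropy undefined for a locus with no mutations")
  }
  p <- alt_counts / sum(alt_counts)
  -sum(p * log(p))
}

#' Correlate effect sizes between two fitted models
#'
#' Pools coefficient pairs across mutation types, aligned by covariate name,
#' and reports Pearson and Spearman correlations; used to compare fits from
#' different datasets.
#'
#' @param fit_a,fit_b either a single `model_fit`, a list of `model_fit`s
#'   (one per mutation type), or a named coefficient vector / list thereof.
#' @param include names to include (default: kappa, gamma and all shared
#'   covariates; alpha is excluded).
#' @return list with `pearson`, `spearman`, `n` (pairs) and the pooled pair
#'   table.
#' @export
compare_effect_sizes <- function(fit_a, fit_b, include = NULL) {
  pull <- function(f) {
    if (inherits(f, "model_fit")) return(list(coef(f)))
    if (is.numeric(f)) return(list(f))
    lapply(f, function(x) if (inherits(x, "model_fit")) coef(x) else x)
  }
  la <- pull(fit_a); lb <- pull(fit_b)
  stopifnot(length(la) == length(lb))
  pairs <- do.call(rbind, lapply(seq_along(la), function(i) {
    shared <- intersect(names(la[[i]]), names(lb[[i]]))
    shared <- setdiff(shared, "alpha")
    if (!is.null(include)) shared <- intersect(shared, include)
    data.frame(name = shared, a = unname(la[[i]][shared]),
               b = unname(lb[[i]][shared]))
  }))
  if (nrow(pairs) < 3L) stop("fewer than 3 shared coefficients")
  list(pearson = stats::cor(pairs$a, pairs$b, method = "pearson"),
       spearman = stats::cor(pairs$a, pairs$b, method = "spearman"),
       n = nrow(pairs), pairs = pairs)
}
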
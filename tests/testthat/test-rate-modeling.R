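# Penalized Poisson model, partial correlations, recurrence model, entropy,
# catalogs and signatures.

sim_model_rows <- function(n = 600, kappa = 0.5, gamma = 0.1,
                           beta = c(gc_content = -0.3), alpha = -6,
                           seed = 1) {
  set.seed(seed)
  covs <- somarna:::COVARIATE_NAMES
  X <- matrix(rnorm(n * length(covs)), n, length(covs),
              dimnames = list(NULL, covs))
  b <- round(exp(rnorm(n, 6, 0.8)))
  tmpl <- rbinom(n, 1, 0.5)
  d_star <- exp(rnorm(n, 4, 0.5))
  bvec <- setNames(rep(0, length(covs)), covs)
  bvec[names(beta)] <- beta
  eta <- alpha + kappa * log(d_star) + gamma * tmpl + X %*% bvec + log(b)
  data.frame(m = rpois(n, exp(eta)), b = b, d_star = d_star,
             strand_class = ifelse(tmpl == 1, "template", "coding"),
             X, check.names = FALSE)
}

test_that("a saturating penalty reduces to the intercept-only closed form", {
  rows <- sim_model_rows(n = 300, seed = 60)
  fit <- fit_poisson_lasso(rows, folds = 5, lambda = c(1e6, 9e5), seed = 60)
  expect_equal(fit$kappa, 0)
  expect_equal(fit$gamma, 0)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$alpha, log(sum(rows$m) / sum(rows$b)), tolerance = 1e-6)
})

test_that("the unpenalized limit matches the IRLS (glm) solution", {
  rows <- sim_model_rows(n = 800, seed = 61)
  fit <- fit_poisson_lasso(rows, folds = 5, seed = 61)
  co <- coef(fit$glmnet_fit, s = 0)  # end of the path: effectively lambda = 0
  oracle <- glm(m ~ log(d_star) + I(strand_class == "template") + gc_content +
                  replication_timing + dna_methylation,
                offset = log(b), family = poisson(), data = rows)
  # compare the shared coefficients (remaining covariates are noise)
  expect_equal(co["log_d_star", 1], unname(coef(oracle)[2]), tolerance = 5e-2)
  expect_equal(co["gc_content", 1], unname(coef(oracle)[4]), tolerance = 5e-2)

  # agreement at lambda = 0 on a model with a single covariate
  rows2 <- rows[, c("m", "b", "d_star", "strand_class", "gc_content")]
  fit2 <- fit_poisson_lasso(rows2, folds = 5, covariates = "gc_content",
                            lambda = c(1, 0.1, 0.01, 0), seed = 61)
  co2 <- coef(fit2$glmnet_fit, s = 0)
  oracle2 <- glm(m ~ log(d_star) + I(strand_class == "template") + gc_content,
                 offset = log(b), family = poisson(), data = rows2)
  expect_equal(as.numeric(co2[, 1]), unname(coef(oracle2)), tolerance = 1e-5)
})

test_that("doubling the offset shifts the intercept by -log(2) only", {
  rows <- sim_model_rows(n = 800, seed = 62)
  rows2 <- rows; rows2$b <- rows$b * 2
  f1 <- fit_poisson_lasso(rows, folds = 5, covariates = "gc_content", seed = 62)
  f2 <- fit_poisson_lasso(rows2, folds = 5, covariates = "gc_content", seed = 62)
  c1 <- coef(f1$glmnet_fit, s = 0); c2 <- coef(f2$glmnet_fit, s = 0)
  expect_equal(c2["(Intercept)", 1] - c1["(Intercept)", 1], -log(2),
               tolerance = 1e-3)
  expect_equal(c1["log_d_star", 1], c2["log_d_star", 1], tolerance = 1e-3)
  expect_equal(c1["gc_content", 1], c2["gc_content", 1], tolerance = 1e-3)
})

test_that("the active set shrinks as the penalty grows", {
  rows <- sim_model_rows(n = 600, beta = c(gc_content = -0.3,
                                           replication_timing = 0.3,
                                           H3K36me3 = -0.4), seed = 63)
  fit <- fit_poisson_lasso(rows, folds = 5, seed = 63)
  path <- fit$glmnet_fit$glmnet.fit
  nz <- path$df  # nonzero count along decreasing lambda
  expect_true(all(diff(nz) >= 0 | diff(path$lambda) < 0))
  # weak monotonicity: cumulative max is the sequence itself up to small dips
  expect_gte(nz[length(nz)], nz[1])
})

test_that("partial correlations match the residual-regression oracle", {
  set.seed(64)
  n <- 6
  rows <- data.frame(
    m = c(0, 1, 3, 2, 5, 4), b = c(10, 12, 30, 25, 50, 40),
    d_star = c(20, 25, 40, 35, 80, 60),
    strand_class = rep("coding", n),
    gc_content = c(0.3, 0.45, 0.41, 0.38, 0.5, 0.47)
  )
  pc <- partial_correlation_tvalues(rows, covariates = "gc_content")
  y <- rows$m / rows$b; z <- log(rows$d_star); x <- rows$gc_content
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  r_oracle <- cor(rx, ry)
  t_oracle <- r_oracle * sqrt(n - 3) / sqrt(1 - r_oracle^2)
  expect_equal(pc$r, r_oracle, tolerance = 1e-10)
  expect_equal(pc$t, t_oracle, tolerance = 1e-10)
})

test_that("a covariate collinear with log depth gives zero with a warning", {
  rows <- sim_model_rows(n = 50, seed = 65)
  rows$bad <- log(rows$d_star)
  expect_warning(pc <- partial_correlation_tvalues(rows, covariates = "bad"),
                 "collinear")
  expect_equal(pc$r, 0)
})

test_that("partial-correlation t-values are calibrated under the null", {
  set.seed(66)
  hits <- replicate(200, {
    n <- 1000
    z <- rnorm(n)
    y <- 0.5 * z + rnorm(n)   # y depends on z only
    x <- rnorm(n)             # x independent of both
    rows <- data.frame(m = exp(y), b = 1, d_star = exp(z),
                       strand_class = "coding", x = x)
    pc <- partial_correlation_tvalues(rows, covariates = "x")
    abs(pc$t) < 1.96
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("the locus recurrence model recovers its parameters", {
  set.seed(67)
  n <- 10000
  c_l <- sample(50:600, n, TRUE)
  mean_depth <- exp(rnorm(n, 4, 0.7))
  d_l <- c_l * mean_depth
  alpha <- -6; beta <- 0.7
  m <- rpois(n, c_l * exp(alpha + beta * log(d_l / c_l)))
  loci <- data.table::data.table(chrom = "chr1", pos = seq_len(n),
                                 c = c_l, d = d_l, m = m)
  fit <- fit_recurrence_model(loci)
  expect_lt(abs(fit$beta - 0.7), 0.1)
  expect_lt(abs(fit$alpha - alpha), 0.2)
  # Poisson score equation: expected counts sum to observed counts
  expect_equal(sum(fit$expected), sum(m), tolerance = 1e-8)

  # constant-rate data: alpha recovered, beta near zero
  m0 <- rpois(n, c_l * exp(-4))
  fit0 <- fit_recurrence_model(data.table::data.table(c = c_l, d = d_l, m = m0))
  expect_lt(abs(fit0$alpha - (-4)), 0.05)
  expect_lt(abs(fit0$beta), 0.05)
})

test_that("alternate-allele entropy behaves at its limits", {
  expect_equal(alt_allele_entropy(c(A = 5)), 0)
  expect_equal(alt_allele_entropy(c(A = 1, C = 1, G = 1)), log(3))
  expect_equal(round(alt_allele_entropy(c(1, 1, 1)), 2), 1.10)
  expect_equal(alt_allele_entropy(c(A = 1, G = 1)), log(2))
  # uniform maximizes entropy over three alternates
  set.seed(68)
  for (i in 1:20) {
    p <- as.numeric(rmultinom(1, 30, runif(3)))
    expect_lte(alt_allele_entropy(p + 1e-9), log(3) + 1e-12)
  }
  expect_error(alt_allele_entropy(c(A = 0)), "undefined")
})

test_that("trinucleotide catalogs count pyrimidine-context channels", {
  seqs <- c(chr1 = "TTACATT")
  ann <- genome_annotation(seqs, data.frame(
    gene_id = "g1", chrom = "chr1", strand = "+", start = 1L, end = 7L,
    type = "exon"))
  # C at position 4 in ACA context
  cat1 <- build_catalog(data.frame(chrom = "chr1", pos = 4L, ref = "C",
                                   alt = "T"), ann)
  expect_identical(sum(cat1), 1L)
  expect_identical(cat1[["A[C>T]A"]], 1L)

  # G>A at a purine site counts in the reverse-complement pyrimidine channel
  seqs2 <- c(chr1 = "AATGTAA")
  ann2 <- genome_annotation(seqs2, data.frame(
    gene_id = "g1", chrom = "chr1", strand = "+", start = 1L, end = 7L,
    type = "exon"))
  cat2 <- build_catalog(data.frame(chrom = "chr1", pos = 4L, ref = "G",
                                   alt = "A"), ann2)
  # TGT on + strand -> ACA on -; G>A -> C>T
  expect_identical(cat2[["A[C>T]A"]], 1L)

  # conservation and off-end skipping
  muts <- data.frame(chrom = "chr1", pos = c(2L, 4L, 7L),
                     ref = c("T", "C", "T"), alt = c("G", "A", "C"))
  expect_message(cat3 <- build_catalog(muts, ann), "skipped")
  expect_identical(sum(cat3), 2L)
})

test_that("cosine similarity matches the direct formula", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  set.seed(69)
  for (i in 1:10) {
    a <- runif(96); b <- runif(96)
    expect_equal(cosine_similarity(a, b),
                 sum(a * b) / sqrt(sum(a^2) * sum(b^2)), tolerance = 1e-12)
  }
  expect_error(cosine_similarity(rep(0, 3), c(1, 2, 3)), "zero")
})

test_that("rank-1 factorization recovers marginal channel frequencies", {
  set.seed(70)
  catalog <- matrix(rpois(5 * 96, 20), 5, 96,
                    dimnames = list(NULL, catalog_channels()))
  res <- extract_signatures(catalog, k = 1, seed = 1)
  marg <- colSums(catalog) / sum(catalog)
  expect_gt(cosine_similarity(res$signatures[1, ], marg), 0.999)
})

test_that("exact two-signature mixtures are recovered", {
  set.seed(71)
  ch <- catalog_channels()
  s1 <- setNames(rep(0, 96), ch); s1[1:32] <- runif(32); s1 <- s1 / sum(s1)
  s2 <- setNames(rep(0, 96), ch); s2[60:96] <- runif(37); s2 <- s2 / sum(s2)
  w <- cbind(runif(40, 50, 400), runif(40, 50, 400))
  v <- w %*% rbind(s1, s2)  # exact mixture, no noise
  res <- extract_signatures(v, k = 2, seed = 3)
  expect_gte(res$reconstruction_cosine, 0.99)
  mm <- match_signatures(res$signatures, rbind(sig1 = s1, sig2 = s2))
  expect_true(all(mm$cosine >= 0.95))
})

test_that("effect-size comparison pools coefficients across fits", {
  co <- c(kappa = 0.5, gamma = 0.1, gc_content = -0.3, H3K36me3 = -0.4)
  res <- compare_effect_sizes(co, co)
  expect_equal(res$pearson, 1)
  expect_equal(res$spearman, 1)
  res2 <- compare_effect_sizes(co, -co)
  expect_equal(res2$pearson, -1)
  set.seed(72)
  a <- setNames(rnorm(10), letters[1:10])
  b <- setNames(rnorm(10), letters[1:10])
  res3 <- compare_effect_sizes(a, b)
  expect_equal(res3$pearson, cor(a, b), tolerance = 1e-12)
  expect_equal(res3$spearman, cor(a, b, method = "spearman"), tolerance = 1e-12)
  expect_error(compare_effect_sizes(a[1:2], b[1:2]), "fewer than 3")
})
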
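test_that("moderated t reduces to ordinary t when prior df is 0", {
  fx <- make_matrix(n_per_group = 8, p = 50, seed = 2)
  res <- fit_moderated_contrasts(fx$mat, fx$meta,
                                 contrasts = "healthy_vs_active",
                                 prior = list(d0 = 0, s0_sq = 1))
  oracle <- apply(fx$mat$values, 2, oracle_contrast_t, meta = fx$meta)
  expect_equal(unname(res$t), unname(oracle), tolerance = 1e-10)
})

test_that("infinite prior df shrinks every posterior variance to s0^2", {
  fx <- make_matrix(n_per_group = 8, p = 50, seed = 3)
  res <- fit_moderated_contrasts(fx$mat, fx$meta,
                                 prior = list(d0 = Inf, s0_sq = 2.5))
  expect_equal(unname(attr(res, "s2_post")), rep(2.5, 50),
               tolerance = 1e-12)
  expect_true(all(is.infinite(res$df)))
})

test_that("estimated posterior variance lies strictly between s2 and s0^2", {
  fx <- make_matrix(n_per_group = 8, p = 200, seed = 4)
  res <- fit_moderated_contrasts(fx$mat, fx$meta)
  prior <- attr(res, "prior")
  expect_gt(prior$d0, 0)
  s2 <- attr(res, "s2"); s2p <- attr(res, "s2_post")
  off <- abs(s2 - prior$s0_sq) > 1e-8
  expect_true(all((s2p[off] - s2[off]) * (s2p[off] - prior$s0_sq) < 0))
})

test_that("variance prior estimation recovers known hyperparameters", {
  # simulate gene-wise variances from the scaled-F model itself
  set.seed(10)
  d <- 10; d0_true <- 8; s0_true <- 1.5
  n_genes <- 20000
  sigma2 <- d0_true * s0_true / rchisq(n_genes, d0_true)
  s2 <- sigma2 * rchisq(n_genes, d) / d
  prior <- triomics:::estimate_variance_prior(s2, d)
  expect_lt(abs(prior$d0 - d0_true) / d0_true, 0.15)
  expect_lt(abs(prior$s0_sq - s0_true) / s0_true, 0.05)
})

test_that("moderated fit agrees with the limma reference", {
  skip_if_not_installed("limma")
  fx <- make_matrix(n_per_group = 8, p = 150, shift_idx = 1:10,
                    shift = 1.5, seed = 5)
  res <- fit_moderated_contrasts(fx$mat, fx$meta,
                                 contrasts = "healthy_vs_active")
  design <- model.matrix(~ 0 + group + age + sex,
                         data = transform(fx$meta,
                                          age = age - mean(age)))
  colnames(design) <- sub("^group", "", colnames(design))
  fit <- limma::lmFit(t(fx$mat$values), design)
  cm <- limma::makeContrasts(healthy - active, levels = design)
  fit2 <- limma::eBayes(limma::contrasts.fit(fit, cm))
  expect_equal(unname(res$estimate), unname(fit2$coefficients[, 1]),
               tolerance = 1e-8)
  expect_equal(unname(res$t), unname(fit2$t[, 1]), tolerance = 1e-4)
  expect_equal(unname(res$p), unname(fit2$p.value[, 1]),
               tolerance = 1e-4)
  prior <- attr(res, "prior")
  expect_equal(prior$d0, fit2$df.prior, tolerance = 0.01)
  expect_equal(prior$s0_sq, fit2$s2.prior, tolerance = 1e-4)
})

test_that("planted log2 shifts are recovered by the contrast estimates", {
  fx <- make_matrix(n_per_group = 12, p = 300, shift_idx = 1:30,
                    shift = -2, shift_groups = "active", seed = 6)
  res <- fit_moderated_contrasts(fx$mat, fx$meta,
                                 contrasts = "healthy_vs_active")
  expect_lt(abs(mean(res$estimate[1:30]) - 2), 0.1)
  expect_lt(abs(mean(res$estimate[31:300])), 0.1)
})

test_that("age and sex confounding is adjusted away", {
  # group-correlated confounders would fake effects in a naive t-test;
  # the adjusted model must stay null
  set.seed(20)
  n <- 36
  group <- rep(c("healthy", "remission", "active"), each = 12)
  age <- 30 + 10 * (group == "active") + runif(n, 0, 10)
  sex <- rbinom(n, 1, 0.5)
  p <- 400
  x <- matrix(rnorm(n * p), n, p) + outer(age, rep(0.2, p)) +
    outer(sex, rep(1, p)) + 20
  meta <- sample_meta(sprintf("S%03d", 1:n), group, age, sex)
  rownames(x) <- meta$sample_id
  m <- analyte_matrix(x, block = "metabolite", scale = "log2")
  res <- fit_moderated_contrasts(m, meta,
                                 contrasts = "healthy_vs_active")
  expect_lt(mean(res$p < 0.05), 0.08)
  expect_lt(abs(mean(res$estimate)), 0.15)
})

test_that("rank-deficient designs and tiny groups are rejected", {
  fx <- make_matrix(n_per_group = 6, p = 10)
  meta <- fx$meta
  meta$age <- 50  # constant age column collinear after centring
  expect_error(fit_moderated_contrasts(fx$mat, meta), "rank deficient")
  meta2 <- fx$meta[c(1, 7:18), ]
  m2 <- subset_samples_for_test(fx$mat, c(1, 7:18))
  expect_error(fit_moderated_contrasts(m2, meta2), "2 samples")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.1, NaN)), "NA")
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_bh(p), oracle_bh(p), tolerance = 1e-14)
  }
  # permutation equivariance
  p <- runif(30)
  perm <- sample(30)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
})

test_that("Welch t-tests match hand computation and are antisymmetric", {
  vals <- matrix(c(1, 2, 3, 0, 0, 0, 4, 5, 6), ncol = 1)
  meta <- sample_meta(sprintf("S%d", 1:9),
                      rep(c("healthy", "remission", "active"), each = 3),
                      age = rep(40, 9), sex = rep(0:1, length.out = 9))
  rownames(vals) <- meta$sample_id
  m <- analyte_matrix(vals, block = "protein", scale = "log2")
  res <- two_sided_ttests(m, meta, "healthy", "active")
  # Welch for {1,2,3} vs {4,5,6}: t = -3/sqrt(2/3), df = 4
  t_hand <- -3 / sqrt(2 / 3)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(t_hand, 4), tolerance = 1e-10)
  expect_equal(res$p, 0.0213, tolerance = 1e-2)
  rev <- two_sided_ttests(m, meta, "active", "healthy")
  expect_equal(rev$t, -res$t)
  expect_equal(rev$p, res$p)
  # identical groups: t = 0, p = 1
  same <- analyte_matrix(matrix(rep(c(1, 2, 3), 3), ncol = 1,
                                dimnames = list(meta$sample_id, "a")),
                         block = "protein", scale = "log2")
  res0 <- two_sided_ttests(same, meta, "healthy", "active")
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
})

test_that("sample PCA matches an SVD oracle and its invariants", {
  set.seed(9)
  x <- matrix(rnorm(80), 10, 8) + 20
  m <- analyte_matrix(x, block = "metabolite", scale = "log2")
  pc <- pca_samples(m, n_components = 5, unit_scale = FALSE)
  sv <- svd(scale(x, scale = FALSE))
  for (k in 1:5) {
    expect_equal(abs(pc$loadings[, k]), abs(sv$v[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(abs(pc$scores[, k]), abs(sv$u[, k] * sv$d[k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  expect_equal(pc$var_explained[1:5],
               (sv$d^2 / sum(sv$d^2))[1:5], tolerance = 1e-10)
  # orthonormal loadings, sign convention, reconstruction
  expect_equal(crossprod(pc$loadings), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (k in 1:5)
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, k])), k], 0)
  full <- pca_samples(m, n_components = 8, unit_scale = FALSE)
  rec <- full$scores %*% t(full$loadings)
  expect_equal(rec, scale(x, scale = FALSE), tolerance = 1e-8,
               ignore_attr = TRUE)
  # rank-1 data: PC1 explains everything
  r1 <- outer(1:10, rep(1, 4)) + matrix(0, 10, 4)
  m1 <- analyte_matrix(r1 * 1.0, block = "metabolite", scale = "log2")
  p1 <- pca_samples(m1, 1, unit_scale = FALSE)
  expect_equal(p1$var_explained[1], 1, tolerance = 1e-12)
  expect_error(pca_samples(m, 20), "exceeds")
})
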
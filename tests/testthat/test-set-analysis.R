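# analyte-level statistics table for a universe of nulls plus an
# optional strong coherent set
make_stats <- function(n_universe = 500, strong_idx = integer(0),
                       strong_p = 0.001, seed = 1,
                       contrast = "healthy_vs_active") {
  set.seed(seed)
  p <- runif(n_universe)
  est <- rnorm(n_universe)
  p[strong_idx] <- strong_p
  est[strong_idx] <- abs(est[strong_idx])  # same direction
  data.frame(analyte_id = sprintf("a%04d", 1:n_universe),
             block = "protein", contrast = contrast, estimate = est,
             t = est, df = 10, p = p, adj_p = p, significant = FALSE,
             stringsAsFactors = FALSE)
}

as_subnet <- function(members, block = "protein", K = 2)
  structure(list(members = members, block = block, K = K),
            class = "subnetwork")

test_that("a coherent strong sub-network gets a small permutation p", {
  st <- make_stats(500, strong_idx = 1:5)
  sn <- as_subnet(sprintf("a%04d", 1:5))
  res <- test_subnetwork(sn, st, "healthy_vs_active", n_perm = 1000,
                         seed = 3)
  expect_lte(res$p, 0.01)
  expect_gt(res$stat, 0)
})

test_that("balanced null members give S = 0 and p near 1", {
  st <- make_stats(100, seed = 2)
  st$p[1:4] <- 0.5
  st$estimate[1:4] <- c(1, -1, 2, -2)
  sn <- as_subnet(sprintf("a%04d", 1:4))
  res <- test_subnetwork(sn, st, "healthy_vs_active", n_perm = 500,
                         seed = 4)
  expect_equal(res$stat, 0, tolerance = 1e-12)
  expect_gt(res$p, 0.5)
})

test_that("permutation p is stable under doubling n_perm", {
  st <- make_stats(400, strong_idx = 1:6, strong_p = 0.02, seed = 5)
  sn <- as_subnet(sprintf("a%04d", 1:6))
  p1 <- test_subnetwork(sn, st, "healthy_vs_active", n_perm = 2000,
                        seed = 6)$p
  p2 <- test_subnetwork(sn, st, "healthy_vs_active", n_perm = 4000,
                        seed = 7)$p
  se <- sqrt(p1 * (1 - p1) / 2000)
  expect_lt(abs(p1 - p2), 3 * se + 1e-6)
})

test_that("permutation p-values are uniform under the null", {
  st <- make_stats(300, seed = 8)
  set.seed(9)
  pvals <- vapply(1:200, function(i) {
    sn <- as_subnet(sample(st$analyte_id, 6))
    test_subnetwork(sn, st, "healthy_vs_active", n_perm = 2000,
                    seed = i)$p
  }, 1)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("sub-network test rejects degenerate input", {
  st <- make_stats(50)
  expect_error(test_subnetwork(as_subnet("a0001"), st,
                               "healthy_vs_active"), "2 members")
  st$p[1] <- 0
  expect_warning(test_subnetwork(as_subnet(c("a0001", "a0002")), st,
                                 "healthy_vs_active", n_perm = 100),
                 "clipped")
})

test_that("choose_K takes the argmax, resolving ties to the stable middle", {
  fake_sweep <- structure(list(grid = c(1, 1.5, 2),
                               by_K = list()), class = "k_sweep")
  assoc <- data.frame(
    K = c(1, 1, 1, 1.5, 1.5, 1.5, 1.5, 1.5, 2, 2, 2, 2, 2),
    significant = c(TRUE, TRUE, TRUE,
                    TRUE, TRUE, TRUE, TRUE, TRUE,
                    TRUE, TRUE, TRUE, TRUE, TRUE))
  # counts: K=1 -> 3, K=1.5 -> 5, K=2 -> 5: maximal run {1.5, 2},
  # middle rounds toward the smaller value
  ch <- choose_K(fake_sweep, assoc)
  expect_equal(ch$K, 1.5)
  expect_identical(unname(ch$counts), c(3L, 5L, 5L))
  # a flat plateau resolves to its interior, not the dense end
  sw5 <- structure(list(grid = c(1, 1.5, 2, 2.5, 3),
                        by_K = list()), class = "k_sweep")
  flat <- data.frame(K = c(1, 1.5, 2, 2.5, 3), significant = TRUE)
  expect_equal(choose_K(sw5, flat)$K, 2)
  # a maximal run at the dense end still wins when its count is higher
  spike <- data.frame(K = c(1, 1, 1.5, 1.5, 2, 2.5, 3),
                      significant = TRUE)
  expect_equal(choose_K(sw5, spike)$K, 1)
  # all zero -> sentinel
  assoc$significant <- FALSE
  ch0 <- choose_K(fake_sweep, assoc)
  expect_true(is.na(ch0$K))
  # single-K grid -> that K
  sw1 <- structure(list(grid = 2, by_K = list()), class = "k_sweep")
  ch1 <- choose_K(sw1, data.frame(K = 2, significant = TRUE))
  expect_equal(ch1$K, 2)
})

test_that("significant counts equal the flags in the association table", {
  # planted correlated set that also carries a group shift, so its
  # sub-network associates with a contrast
  set.seed(12)
  n <- 90
  group <- rep(c("healthy", "remission", "active"), each = 30)
  x <- matrix(rnorm(n * 30), n, 30)
  f <- rnorm(n)
  x[, 1:6] <- 0.9 * f + sqrt(1 - 0.81) * x[, 1:6]
  x[group == "active", 1:6] <- x[group == "active", 1:6] + 2
  meta <- sample_meta(sprintf("S%03d", 1:n), group,
                      age = runif(n, 25, 65), sex = rbinom(n, 1, 0.5))
  rownames(x) <- meta$sample_id
  mat <- analyte_matrix(x + 20, block = "protein", scale = "log2")
  res <- fit_moderated_contrasts(mat, meta)
  sw <- sweep_K(list(protein = zscore_by_analyte(mat)),
                grid = c(1.5, 3))
  assoc <- test_all_subnetworks(sw, list(protein = res), n_perm = 500,
                                seed = 1)
  ch <- choose_K(sw, assoc)
  for (K in sw$grid)
    expect_equal(unname(ch$counts[as.character(K)]),
                 sum(assoc$significant[assoc$K == K]))
})

test_that("the 75% rule decides between one and two components", {
  n <- 500
  set.seed(13)
  # perfectly correlated pair -> PC1 fraction 1 -> one component
  a <- rnorm(n)
  m1 <- analyte_matrix(cbind(x = a, y = 2 * a + 3) + 20,
                       block = "protein", scale = "log2")
  s1 <- summarize_pcs(zscore_by_analyte(m1), as_subnet(c("x", "y")))
  expect_equal(ncol(s1$scores), 1L)
  expect_equal(s1$var_explained[1], 1, tolerance = 1e-12)
  # independent pair -> fraction near 0.5 -> two components
  m2 <- analyte_matrix(cbind(x = rnorm(n), y = rnorm(n)) + 20,
                       block = "protein", scale = "log2")
  s2 <- summarize_pcs(zscore_by_analyte(m2), as_subnet(c("x", "y")))
  expect_equal(ncol(s2$scores), 2L)
  expect_lt(abs(s2$var_explained[1] - 0.5), 0.1)
})

test_that("a PC1 fraction of exactly 0.75 keeps one component (strict rule)", {
  # two standardized analytes with correlation r have PC1 fraction
  # (1 + r) / 2; r = 0.5 puts the fraction exactly at 0.75
  r <- 0.5
  n <- 400
  set.seed(14)
  z1 <- scale(rnorm(n))[, 1]
  z2r <- scale(resid(lm(rnorm(n) ~ z1)))[, 1]
  z2 <- r * z1 + sqrt(1 - r^2) * z2r  # empirical correlation exactly r
  m <- analyte_matrix(cbind(x = z1, y = z2), block = "protein",
                      scale = "zscore")
  expect_equal(cor(m$values)[1, 2], r, tolerance = 1e-12)
  s <- summarize_pcs(m, as_subnet(c("x", "y")))
  expect_equal(s$var_explained[1], 0.75, tolerance = 1e-10)
  expect_equal(ncol(s$scores), 1L)
})

test_that("sub-network PC scores are invariant to member order up to sign", {
  fx <- make_matrix(n_per_group = 20, p = 6, seed = 15)
  z <- zscore_by_analyte(fx$mat)
  ids <- colnames(z$values)[1:4]
  s1 <- summarize_pcs(z, as_subnet(ids))
  s2 <- summarize_pcs(z, as_subnet(rev(ids)))
  for (k in seq_len(ncol(s1$scores)))
    expect_equal(abs(s1$scores[, k]), abs(s2$scores[, k]),
                 tolerance = 1e-10, ignore_attr = TRUE)
})
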
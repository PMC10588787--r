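# shared fixtures, built in code

# a small complete log2 matrix with optional group shifts
make_matrix <- function(n_per_group = 10, p = 20, block = "protein",
                        shift_idx = integer(0), shift = 0,
                        shift_groups = "active", noise_sd = 1,
                        seed = 1) {
  set.seed(seed)
  n <- 3 * n_per_group
  group <- rep(c("healthy", "remission", "active"), each = n_per_group)
  x <- matrix(rnorm(n * p, sd = noise_sd), n, p) + 20
  if (length(shift_idx))
    x[group %in% shift_groups, shift_idx] <-
      x[group %in% shift_groups, shift_idx] + shift
  meta <- sample_meta(sprintf("S%03d", 1:n), group,
                      age = runif(n, 25, 65), sex = rbinom(n, 1, 0.5))
  rownames(x) <- meta$sample_id
  list(mat = analyte_matrix(x, block = block, scale = "log2"),
       meta = meta)
}

# keep a subset of samples (rows) of an analyte_matrix
subset_samples_for_test <- function(m, i) {
  analyte_matrix(m$values[i, , drop = FALSE], block = m$block,
                 scale = m$scale,
                 missing_mask = m$missing_mask[i, , drop = FALSE],
                 below_lod_mask = m$below_lod_mask[i, , drop = FALSE])
}

# ordinary (unmoderated) contrast t from first principles, for one
# analyte: OLS with group indicators + centred age + sex
oracle_contrast_t <- function(y, meta, a = "healthy", b = "active") {
  X <- stats::model.matrix(~ 0 + group + age + sex,
                           data = transform(meta,
                                            age = age - mean(age)))
  fit <- lm.fit(X, y)
  s2 <- sum(fit$residuals^2) / fit$df.residual
  cvec <- as.numeric(grepl(a, colnames(X))) -
    as.numeric(grepl(b, colnames(X)))
  XtXinv <- solve(crossprod(X))
  est <- sum(cvec * fit$coefficients)
  est / sqrt(s2 * drop(t(cvec) %*% XtXinv %*% cvec))
}

# brute-force Benjamini-Hochberg by its step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  # adjusted p_(i) = min_{j >= i} min(1, m * p_(j) / j)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- running
  }
  adj
}

# partial correlation of columns i and j given all others, by
# correlating the residuals of the two regressions
oracle_partial_cor <- function(X, i, j) {
  others <- X[, -c(i, j), drop = FALSE]
  ri <- lm.fit(cbind(1, others), X[, i])$residuals
  rj <- lm.fit(cbind(1, others), X[, j])$residuals
  cor(ri, rj)
}

# adjusted Rand index between two labelings (vectors of equal length);
# singleton handling: give each "background" element a unique label
# before calling
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

# component labels (singletons unique) from a list of subnetworks over a
# fixed analyte universe
component_labels <- function(subnets, universe) {
  lab <- paste0("single_", universe)
  names(lab) <- universe
  for (i in seq_along(subnets))
    lab[subnets[[i]]$members] <- paste0("comp_", i)
  unname(lab)
}
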
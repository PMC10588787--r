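# Stage 1: per-analyte linear models with age/sex adjustment, empirical
# Bayes variance moderation and Benjamini-Hochberg correction; plus plain
# Welch t-tests and sample-level PCA for exploratory reporting.
#
# The moderation follows the canonical hierarchical model for gene-wise
# variances: s_g^2 ~ s0^2 * F(d_g, d0) under the prior
# 1/sigma_g^2 ~ (1/(d0 s0^2)) * chi^2_d0. The prior (d0, s0^2) is
# estimated by moment matching on log s^2 (digamma/trigamma inversion),
# and the posterior variance s~^2 = (d0 s0^2 + d s^2) / (d0 + d) replaces
# s^2 in the t-statistic, which then has d0 + d degrees of freedom.

# the three pairwise group contrasts, estimate = mean(a) - mean(b)
CONTRASTS <- list(
  healthy_vs_active    = list(a = "healthy",   b = "active"),
  healthy_vs_remission = list(a = "healthy",   b = "remission"),
  remission_vs_active  = list(a = "remission", b = "active"))

#' The three pairwise group contrasts
#'
#' @return named list; each element has the two compared groups \code{a}
#'   and \code{b}. Estimates are reported as \code{mean(a) - mean(b)} on
#'   the log2 scale.
#' @export
contrast_specs <- function() CONTRASTS

# Newton inversion of the trigamma function (decreasing, convex on x>0);
# needed to solve trigamma(d0/2) = v for the prior df
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

# moment-matching estimate of the scaled-F prior for gene-wise variances:
# z = log s^2; e = z - digamma(d/2) + log(d/2) has
# E[e] = log s0^2 - digamma(d0/2) + log(d0/2),
# Var[e] = trigamma(d/2) + trigamma(d0/2)
estimate_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 4)
    stop("prior estimation needs at least 4 analytes with positive ",
         "residual variance")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(ebar)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# design matrix: one indicator per group (no intercept) + centred age + sex
build_design <- function(meta) {
  X <- stats::model.matrix(~ 0 + group + age + sex,
                           data = transform(meta, age = age - mean(age)))
  colnames(X) <- sub("^group", "", colnames(X))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient; check group/age/sex columns ",
         "for collinearity")
  X
}

#' Fit confounder-adjusted moderated contrasts
#'
#' Fits one ordinary least-squares model per analyte with group indicators
#' plus age and sex, then moderates the residual variances with an
#' empirical-Bayes scaled-F prior estimated across analytes, and tests the
#' three pairwise group contrasts with moderated t-statistics. P-values
#' are Benjamini-Hochberg adjusted per contrast.
#'
#' @param matrix a complete (imputed) \code{analyte_matrix} on the log2
#'   scale.
#' @param meta matching \code{sample_meta}; needs at least 2 samples per
#'   group.
#' @param contrasts subset of [contrast_specs()] names; default all three.
#' @param q FDR level for the significance flag (default 0.05).
#' @param moderate set \code{FALSE} to skip shrinkage (ordinary t).
#' @param prior optional list \code{(d0, s0_sq)} overriding the
#'   estimated variance prior; \code{d0 = 0} gives ordinary t,
#'   \code{d0 = Inf} full shrinkage to \code{s0_sq}.
#' @return a \code{data.frame} with one row per analyte and contrast:
#'   \code{analyte_id}, \code{block}, \code{contrast}, \code{estimate}
#'   (log2 fold-change), \code{t}, \code{df}, \code{p}, \code{adj_p},
#'   \code{significant}; the estimated prior is attached as attribute
#'   \code{"prior"}.
#' @export
fit_moderated_contrasts <- function(matrix, meta,
                                    contrasts = names(CONTRASTS),
                                    q = 0.05, moderate = TRUE,
                                    prior = NULL) {
  stopifnot(inherits(matrix, "analyte_matrix"))
  check_samples_match(matrix, meta)
  if (anyNA(matrix$values))
    stop("model fitting requires a complete matrix; impute first")
  contrasts <- match.arg(contrasts, names(CONTRASTS),
                         several.ok = TRUE)
  if (any(table(meta$group) < 2))
    stop("need at least 2 samples per group")
  X <- build_design(meta)
  Y <- matrix$values
  n <- nrow(Y); p_design <- ncol(X)
  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, Y)            # coefficients x analytes
  resid <- Y - X %*% B
  df_resid <- n - p_design
  s2 <- colSums(resid^2) / df_resid
  if (is.null(prior)) {
    if (moderate && ncol(Y) >= 4) {
      prior <- estimate_variance_prior(s2, df_resid)
    } else {
      if (moderate)
        warning("fewer than 4 analytes: falling back to ordinary t")
      prior <- list(d0 = 0, s0_sq = NA_real_)
    }
  }
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) rep(prior$s0_sq, length(s2))
             else if (d0 == 0) s2
             else (d0 * prior$s0_sq + df_resid * s2) / (d0 + df_resid)
  df_total <- if (is.infinite(d0)) Inf else d0 + df_resid

  out <- lapply(contrasts, function(cn) {
    ct <- CONTRASTS[[cn]]
    cvec <- rep(0, p_design)
    names(cvec) <- colnames(X)
    cvec[ct$a] <- 1; cvec[ct$b] <- -1
    est <- drop(cvec %*% B)
    v_c <- drop(t(cvec) %*% XtXinv %*% cvec)
    tstat <- est / sqrt(s2_post * v_c)
    pval <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
    adj <- adjust_bh(pval)
    data.frame(analyte_id = colnames(Y), block = matrix$block,
               contrast = cn, estimate = est, t = tstat,
               df = df_total, p = pval, adj_p = adj,
               significant = adj <= q, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "prior") <- prior
  attr(res, "s2") <- s2
  attr(res, "s2_post") <- s2_post
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1); a validated wrapper
#' around \code{stats::p.adjust(method = "BH")}.
#'
#' @param raw_p numeric vector of p-values in [0, 1]; \code{NaN}/\code{NA}
#'   entries are an error.
#' @return adjusted p-values in input order.
#' @export
adjust_bh <- function(raw_p) {
  if (anyNA(raw_p)) stop("NA/NaN p-values are not allowed")
  if (any(raw_p < 0 | raw_p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(raw_p, method = "BH")
}

#' Per-analyte Welch two-sample t-tests
#'
#' Plain (unmoderated, unadjusted-for-confounders) two-sided Welch t-tests
#' between two groups, as used for volcano-style group comparisons.
#'
#' @param matrix a complete \code{analyte_matrix}.
#' @param meta matching \code{sample_meta}.
#' @param group_a,group_b the two groups; estimate is
#'   \code{mean(a) - mean(b)}.
#' @param q FDR level for the significance flag.
#' @return a \code{data.frame} shaped like [fit_moderated_contrasts()]
#'   output.
#' @export
two_sided_ttests <- function(matrix, meta, group_a, group_b, q = 0.05) {
  stopifnot(inherits(matrix, "analyte_matrix"))
  check_samples_match(matrix, meta)
  group_a <- match.arg(group_a, GROUP_LEVELS)
  group_b <- match.arg(group_b, GROUP_LEVELS)
  ia <- meta$group == group_a; ib <- meta$group == group_b
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("both groups need at least 2 samples")
  res <- apply(matrix$values, 2, function(v) {
    tt <- stats::t.test(v[ia], v[ib], var.equal = FALSE)
    c(estimate = unname(diff(rev(tt$estimate))), t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value)
  })
  res <- as.data.frame(t(res))
  adj <- adjust_bh(res$p)
  data.frame(analyte_id = colnames(matrix$values), block = matrix$block,
             contrast = paste0(group_a, "_vs_", group_b),
             estimate = res$estimate, t = res$t, df = res$df, p = res$p,
             adj_p = adj, significant = adj <= q, row.names = NULL,
             stringsAsFactors = FALSE)
}

# deterministic sign convention: the largest-magnitude loading of each
# component is positive
fix_signs <- function(rotation, scores) {
  for (k in seq_len(ncol(rotation))) {
    i <- which.max(abs(rotation[, k]))
    if (rotation[i, k] < 0) {
      rotation[, k] <- -rotation[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(rotation = rotation, scores = scores)
}

#' Principal component analysis of samples
#'
#' PCA of the samples-by-analytes matrix with analytes centred and, by
#' default, unit-scaled. Loadings are orthonormal with a deterministic
#' sign convention (the largest-magnitude loading of each component is
#' positive).
#'
#' @param matrix a complete \code{analyte_matrix}.
#' @param n_components number of components to return; at most
#'   \code{min(samples - 1, analytes)}.
#' @param unit_scale scale analytes to unit variance before PCA
#'   (default \code{TRUE}).
#' @return list with \code{scores} (samples x components),
#'   \code{loadings} (analytes x components) and \code{var_explained}
#'   (fractions of total variance).
#' @export
pca_samples <- function(matrix, n_components = 2, unit_scale = TRUE) {
  stopifnot(inherits(matrix, "analyte_matrix"))
  if (anyNA(matrix$values)) stop("PCA requires a complete matrix")
  max_k <- min(nrow(matrix$values) - 1L, ncol(matrix$values))
  if (n_components > max_k)
    stop("n_components exceeds min(samples - 1, analytes) = ", max_k)
  pc <- stats::prcomp(matrix$values, center = TRUE, scale. = unit_scale)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  k <- seq_len(n_components)
  fixed <- fix_signs(pc$rotation[, k, drop = FALSE],
                     pc$x[, k, drop = FALSE])
  list(scores = fixed$scores, loadings = fixed$rotation,
       var_explained = var_frac[k])
}
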
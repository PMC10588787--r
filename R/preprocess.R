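# Block-specific preprocessing: valid-value filtering, Gaussian
# down-shift imputation for the protein block, below-detection-limit
# imputation (minimum over sqrt(2), then log2) for the eicosanoid block,
# and per-analyte z-scoring.

#' Filter analytes by valid values per group
#'
#' Retains exactly those analytes with at least \code{min_valid}
#' non-missing values in at least one sample group; the order of retained
#' analytes is preserved. The default of 3 matches plasma profiling; use 5
#' for tissue.
#'
#' @param matrix an \code{analyte_matrix}.
#' @param meta matching \code{sample_meta}.
#' @param min_valid minimum count of valid (non-masked) values required in
#'   at least one group; at least 1.
#' @return the filtered \code{analyte_matrix}.
#' @export
filter_by_valid_values <- function(matrix, meta, min_valid = 3) {
  stopifnot(inherits(matrix, "analyte_matrix"), min_valid >= 1)
  check_samples_match(matrix, meta)
  observed <- !(matrix$missing_mask | matrix$below_lod_mask)
  keep <- rep(FALSE, ncol(matrix$values))
  for (g in levels(meta$group)) {
    in_g <- meta$group == g
    if (!any(in_g)) next
    keep <- keep | colSums(observed[in_g, , drop = FALSE]) >= min_valid
  }
  if (!any(keep))
    warning("no analyte has ", min_valid,
            " valid values in any group; all analytes removed")
  subset_analytes(matrix, which(keep))
}

#' Gaussian down-shift imputation of missing values
#'
#' Each missing cell of analyte \code{c} is drawn from
#' \code{Normal(mu_c - shift * sigma_c, (width * sigma_c)^2)} where
#' \code{mu_c} and \code{sigma_c} are the mean and standard deviation of
#' the analyte's observed log2 values. This emulates low-abundance
#' dropout: imputed values land in the left tail of the observed
#' distribution. Columns with fewer than two observed values fall back to
#' the whole-matrix standard deviation.
#'
#' @param matrix an \code{analyte_matrix} on the log2 scale.
#' @param shift down-shift in standard-deviation multiples (default 1.8).
#' @param width width of the imputation distribution in
#'   standard-deviation multiples (default 0.3).
#' @param seed integer seed; imputation is deterministic given it.
#' @return an \code{analyte_matrix} with no missing cells; imputed-cell
#'   provenance is kept in attribute \code{"imputed_mask"}.
#' @export
impute_gaussian_downshift <- function(matrix, shift = 1.8, width = 0.3,
                                      seed = 1L) {
  stopifnot(inherits(matrix, "analyte_matrix"))
  if (matrix$scale == "raw")
    stop("down-shift imputation expects log2-transformed data")
  vals <- matrix$values
  todo <- matrix$missing_mask | matrix$below_lod_mask
  if (!any(todo)) {
    out <- matrix
    attr(out, "imputed_mask") <- todo
    return(out)
  }
  set.seed(as.integer(seed))
  global_sd <- stats::sd(vals[!todo])
  for (j in which(colSums(todo) > 0)) {
    obs <- vals[!todo[, j], j]
    mu <- mean(obs)
    sdv <- if (length(obs) >= 2) stats::sd(obs) else global_sd
    if (!is.finite(sdv) || sdv == 0) sdv <- global_sd
    m <- sum(todo[, j])
    vals[todo[, j], j] <- stats::rnorm(m, mu - shift * sdv, width * sdv)
  }
  out <- analyte_matrix(vals, block = matrix$block, scale = matrix$scale)
  attr(out, "imputed_mask") <- todo
  out
}

#' Below-LOD imputation by minimum over sqrt(2), then log2 transform
#'
#' Every below-detection-limit cell of an analyte is set to the analyte's
#' minimum observed raw value divided by \code{sqrt(2)}; the whole matrix
#' is then log2-transformed. Observed raw values are preserved exactly
#' before the transform. Analytes with no observed value cannot be imputed
#' and are dropped with a warning.
#'
#' @param matrix an \code{analyte_matrix} on the raw scale with below-LOD
#'   cells flagged.
#' @return an \code{analyte_matrix} on the log2 scale with no below-LOD
#'   cells; imputed-cell provenance in attribute \code{"imputed_mask"}.
#' @export
impute_lod_min_over_sqrt2 <- function(matrix) {
  stopifnot(inherits(matrix, "analyte_matrix"))
  if (matrix$scale != "raw")
    stop("LOD imputation is defined on the raw scale")
  vals <- matrix$values
  masked <- matrix$missing_mask | matrix$below_lod_mask
  n_obs <- colSums(!masked)
  if (any(n_obs == 0)) {
    warning(sum(n_obs == 0),
            " analyte(s) with no observed value dropped")
    keep <- which(n_obs > 0)
    return(impute_lod_min_over_sqrt2(subset_analytes(matrix, keep)))
  }
  for (j in which(colSums(matrix$below_lod_mask) > 0)) {
    mn <- min(vals[!masked[, j], j])
    vals[matrix$below_lod_mask[, j], j] <- mn / sqrt(2)
  }
  if (any(vals <= 0, na.rm = TRUE))
    stop("non-positive raw values cannot be log2-transformed")
  out <- analyte_matrix(log2(vals), block = matrix$block, scale = "log2",
                        missing_mask = matrix$missing_mask)
  attr(out, "imputed_mask") <- matrix$below_lod_mask
  out
}

#' Z-score each analyte across samples
#'
#' Centres and scales every analyte to mean 0, sd 1 using the sample
#' (n - 1 denominator) standard deviation. Zero-variance analytes are set
#' to 0 with a warning. Idempotent.
#'
#' @param matrix an \code{analyte_matrix} without missing values.
#' @return the z-scored \code{analyte_matrix} (scale flag
#'   \code{"zscore"}).
#' @export
zscore_by_analyte <- function(matrix) {
  stopifnot(inherits(matrix, "analyte_matrix"))
  if (anyNA(matrix$values))
    stop("z-scoring requires a complete matrix; impute first")
  vals <- scale(matrix$values)
  zero_var <- attr(vals, "scaled:scale") == 0 |
    !is.finite(attr(vals, "scaled:scale"))
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance analyte(s) set to 0")
    vals[, zero_var] <- 0
  }
  vals <- vals[, , drop = FALSE]  # strip scaling attributes
  attr(vals, "scaled:center") <- NULL
  attr(vals, "scaled:scale") <- NULL
  analyte_matrix(vals, block = matrix$block, scale = "zscore")
}
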
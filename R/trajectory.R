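# Trajectory classification: where does each analyte's remission level
# sit on the healthy -> remission -> active axis after confounder
# correction?  Classes: "normalising" (remission close to healthy),
# "non_normalising" (remission stuck close to active), "exceptional"
# (healthy or active in between the other two), plus two sentinels for
# patterns the taxonomy does not cover.

#' Confounder-corrected group mean z-scores
#'
#' Per analyte: residualise the log2 values on (centred) age and sex by
#' least squares, z-score the residuals across all samples, and return
#' the mean z-score per group.
#'
#' @param matrix a complete \code{analyte_matrix} (log2 scale).
#' @param meta matching \code{sample_meta}.
#' @return \code{data.frame} with \code{analyte_id}, \code{block},
#'   \code{z_healthy}, \code{z_remission}, \code{z_active}.
#' @export
corrected_group_zscores <- function(matrix, meta) {
  stopifnot(inherits(matrix, "analyte_matrix"))
  check_samples_match(matrix, meta)
  if (anyNA(matrix$values)) stop("requires a complete matrix")
  X <- cbind(1, meta$age - mean(meta$age), meta$sex)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  resid <- matrix$values - H %*% matrix$values
  sds <- apply(resid, 2, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance analyte(s): z-scores set to 0")
    sds[zero] <- 1
  }
  Z <- sweep(sweep(resid, 2, colMeans(resid)), 2, sds, "/")
  Z[, zero] <- 0
  gz <- vapply(GROUP_LEVELS, function(g)
    colMeans(Z[meta$group == g, , drop = FALSE]),
    numeric(ncol(Z)))
  data.frame(analyte_id = colnames(matrix$values),
             block = matrix$block,
             z_healthy = gz[, "healthy"], z_remission = gz[, "remission"],
             z_active = gz[, "active"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify one analyte trajectory
#'
#' Deterministic rule on the corrected group mean z-scores
#' \code{(z_h, z_r, z_a)}, scaled by the healthy-to-active span:
#' \itemize{
#'   \item \code{normalising} when
#'     \code{|z_r - z_h| <= delta * |z_a - z_h|} (remission close to
#'     healthy);
#'   \item otherwise \code{non_normalising} when
#'     \code{|z_r - z_a| <= delta * |z_a - z_h|} (remission stuck near
#'     active);
#'   \item otherwise \code{exceptional} when \code{z_h} lies strictly
#'     between \code{z_r} and \code{z_a} (sub-type
#'     \code{healthy_between}) or \code{z_a} lies strictly between
#'     \code{z_h} and \code{z_r} (sub-type \code{active_between});
#'   \item otherwise the \code{intermediate} sentinel; and
#'     \code{no_signal} when \code{z_h == z_a}.
#' }
#' Closeness is decided before betweenness so that sampling noise around
#' an endpoint cannot convert a (non-)normalising pattern into an
#' in-between one.
#'
#' @param z_h,z_r,z_a group mean z-scores (healthy, remission, active).
#' @param delta closeness fraction of the healthy-to-active span
#'   (default 1/3).
#' @return list with \code{class} and \code{subtype} (\code{NA} unless
#'   exceptional).
#' @export
classify_trajectory <- function(z_h, z_r, z_a, delta = 1/3) {
  stopifnot(delta >= 0)
  span <- abs(z_a - z_h)
  if (span == 0)
    return(list(class = "no_signal", subtype = NA_character_))
  strictly_between <- function(x, lo, hi)
    x > min(lo, hi) && x < max(lo, hi)
  # closeness classes are decided first: a remission level within
  # delta * span of one endpoint is that endpoint's class even if noise
  # pushes it a hair past the endpoint (which would otherwise read as an
  # "in between" pattern)
  if (abs(z_r - z_h) <= delta * span)
    return(list(class = "normalising", subtype = NA_character_))
  if (abs(z_r - z_a) <= delta * span)
    return(list(class = "non_normalising", subtype = NA_character_))
  if (strictly_between(z_h, z_r, z_a))
    return(list(class = "exceptional", subtype = "healthy_between"))
  if (strictly_between(z_a, z_h, z_r))
    return(list(class = "exceptional", subtype = "active_between"))
  list(class = "intermediate", subtype = NA_character_)
}

#' Classify all analyte trajectories of a block
#'
#' @param matrix a complete \code{analyte_matrix} (log2 scale).
#' @param meta matching \code{sample_meta}.
#' @param delta passed to [classify_trajectory()].
#' @return \code{data.frame}: analyte id, block, the three corrected
#'   group z-scores, \code{class}, \code{subtype} and the \code{delta}
#'   used.
#' @export
classify_trajectories <- function(matrix, meta, delta = 1/3) {
  z <- corrected_group_zscores(matrix, meta)
  cls <- mapply(function(h, r, a)
    classify_trajectory(h, r, a, delta = delta),
    z$z_healthy, z$z_remission, z$z_active, SIMPLIFY = FALSE)
  z$class <- vapply(cls, function(x) x$class, "")
  z$subtype <- vapply(cls, function(x) x$subtype, "")
  z$delta <- delta
  z
}
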
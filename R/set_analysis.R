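# Stage 2b: directional set-level association of each sub-network with
# each contrast, selection of the penalty K that maximises the number of
# contrast-specific significant sub-networks, and principal-component
# summarisation of the chosen sub-networks under the 75% rule.

# signed Stouffer statistic over member analytes: combines each member's
# raw p-value and regulation direction into one directional z
stouffer_stat <- function(p, sign_est) {
  p <- pmax(p, .Machine$double.xmin)
  # upper-tail form stays finite for p down to the double minimum
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  sum(sign(sign_est) * z) / sqrt(length(p))
}

#' Test one sub-network's association with a contrast
#'
#' Combines the member analytes' raw p-values and regulation directions
#' into a signed Stouffer statistic
#' \code{S = (1/sqrt(m)) * sum(sign(estimate_j) * qnorm(1 - p_j / 2))}
#' and calibrates it two-sided against a permutation null built by
#' resampling m analytes from the block's analyte universe.
#'
#' @param subnet a \code{subnetwork} (at least 2 members).
#' @param analyte_stats a [fit_moderated_contrasts()] result for the
#'   sub-network's block.
#' @param contrast contrast name to test.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the resampling.
#' @return one-row \code{data.frame}: \code{members}, \code{size},
#'   \code{contrast}, \code{stat}, \code{p}.
#' @export
test_subnetwork <- function(subnet, analyte_stats, contrast,
                            n_perm = 1000, seed = 1L) {
  stopifnot(inherits(subnet, "subnetwork"))
  m <- length(subnet$members)
  if (m < 2) stop("sub-network must have at least 2 members")
  st <- analyte_stats[analyte_stats$contrast == contrast, ]
  if (!all(subnet$members %in% st$analyte_id))
    stop("missing analyte statistics for some sub-network members")
  if (any(st$p == 0))
    warning("p-values of 0 clipped to the machine minimum")
  idx <- match(subnet$members, st$analyte_id)
  S <- stouffer_stat(st$p[idx], st$estimate[idx])
  set.seed(as.integer(seed))
  null_S <- replicate(n_perm, {
    i <- sample.int(nrow(st), m)
    stouffer_stat(st$p[i], st$estimate[i])
  })
  # two-sided permutation p with the +1 correction
  p_perm <- (1 + sum(abs(null_S) >= abs(S))) / (n_perm + 1)
  data.frame(members = paste(subnet$members, collapse = ";"),
             size = m, block = subnet$block, contrast = contrast,
             stat = S, p = p_perm, stringsAsFactors = FALSE)
}

#' Test every sub-network of a K sweep against every contrast
#'
#' Runs [test_subnetwork()] for each (sub-network, contrast) pair at each
#' K, then BH-adjusts within each (K, contrast) stratum at level
#' \code{q}.
#'
#' @param sweep a [sweep_K()] result.
#' @param analyte_stats named list of [fit_moderated_contrasts()] results
#'   per block.
#' @param contrasts contrast names to test (default all three).
#' @param n_perm,seed passed to [test_subnetwork()].
#' @param q FDR level within each (K, contrast) stratum.
#' @return \code{data.frame} with one row per (K, sub-network, contrast):
#'   association statistics plus \code{adj_p} and \code{significant}.
#' @export
test_all_subnetworks <- function(sweep, analyte_stats,
                                 contrasts = names(CONTRASTS),
                                 n_perm = 1000, seed = 1L, q = 0.05) {
  stopifnot(inherits(sweep, "k_sweep"))
  rows <- list()
  for (K in names(sweep$by_K)) {
    for (b in names(sweep$by_K[[K]])) {
      subs <- sweep$by_K[[K]][[b]]$subnetworks
      for (s_i in seq_along(subs)) {
        for (ct in contrasts) {
          r <- test_subnetwork(subs[[s_i]], analyte_stats[[b]], ct,
                               n_perm = n_perm,
                               seed = as.integer(seed) + s_i)
          r$K <- as.numeric(K)
          r$subnetwork_id <- paste0(b, "_K", K, "_sn", s_i)
          rows[[length(rows) + 1L]] <- r
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(members = character(0), size = integer(0),
                      block = character(0), contrast = character(0),
                      stat = numeric(0), p = numeric(0), K = numeric(0),
                      subnetwork_id = character(0), adj_p = numeric(0),
                      significant = logical(0)))
  out <- do.call(rbind, rows)
  out$adj_p <- NA_real_
  for (K in unique(out$K)) for (ct in unique(out$contrast)) {
    i <- out$K == K & out$contrast == ct
    out$adj_p[i] <- adjust_bh(out$p[i])
  }
  out$significant <- out$adj_p <= q
  out
}

#' Choose the penalty K maximising contrast-specific sub-networks
#'
#' K* is the grid value with the largest count of (sub-network, contrast)
#' pairs significant at the FDR level. Because the count is typically
#' flat over an interval of K (the selected components, and hence the
#' association tests, are identical there), ties are broken to the middle
#' of the longest contiguous run of maximal counts, rounding toward
#' smaller K — the interior of the stable region rather than either
#' noisy extreme. When no sub-network is significant at any K the
#' sentinel \code{NA} is returned and the pipeline proceeds with single
#' analytes only.
#'
#' @param sweep a [sweep_K()] result.
#' @param associations a [test_all_subnetworks()] result over the same
#'   grid.
#' @return list with \code{K} (chosen value or \code{NA}),
#'   \code{counts} (named significant-pair count per K) and
#'   \code{subnetworks} (the significant sub-networks at K*, as rows of
#'   \code{associations}).
#' @export
choose_K <- function(sweep, associations) {
  stopifnot(inherits(sweep, "k_sweep"))
  counts <- vapply(sweep$grid, function(K)
    sum(associations$significant[associations$K == K], na.rm = TRUE),
    1L)
  names(counts) <- as.character(sweep$grid)
  if (all(counts == 0))
    return(list(K = NA_real_, counts = counts,
                subnetworks = associations[0, ]))
  # middle of the longest contiguous maximal-count run
  is_max <- counts == max(counts)
  runs <- rle(is_max)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best <- which(runs$values)
  best <- best[which.max(runs$lengths[best])]  # longest run, first tie
  run_idx <- starts[best]:ends[best]
  K_star <- sweep$grid[run_idx[ceiling(length(run_idx) / 2)]]
  sig <- associations[associations$K == K_star &
                        associations$significant, ]
  list(K = K_star, counts = counts, subnetworks = sig)
}

#' Summarise a sub-network by principal components (75% rule)
#'
#' PCA of the member-analyte submatrix (analytes standardised). PC1 alone
#' represents the sub-network when it explains at least 75% of the
#' variance; strictly below 75%, PC1 and PC2 are both kept.
#'
#' @param matrix a complete \code{analyte_matrix} containing the members.
#' @param subnet a \code{subnetwork} (at least 2 members).
#' @param pc1_threshold explained-variance fraction below which a second
#'   component is added (default 0.75, strict).
#' @return a \code{subnetwork_summary}: list with \code{scores} (samples
#'   x 1 or 2), \code{loadings}, \code{var_explained}, \code{members},
#'   \code{block}.
#' @export
summarize_pcs <- function(matrix, subnet, pc1_threshold = 0.75) {
  stopifnot(inherits(matrix, "analyte_matrix"),
            inherits(subnet, "subnetwork"))
  if (length(subnet$members) < 2)
    stop("sub-network must have at least 2 members")
  if (!all(subnet$members %in% colnames(matrix$values)))
    stop("sub-network members absent from matrix")
  sub <- subset_analytes(matrix, subnet$members)
  pc <- pca_samples(sub, n_components = min(2, ncol(sub$values),
                                            nrow(sub$values) - 1L),
                    unit_scale = TRUE)
  # strict "below threshold" rule, with a float guard so a fraction that
  # equals the threshold up to rounding counts as meeting it
  n_comp <- if (pc$var_explained[1] < pc1_threshold - 1e-10 &&
                length(pc$var_explained) >= 2) 2L else 1L
  structure(list(scores = pc$scores[, seq_len(n_comp), drop = FALSE],
                 loadings = pc$loadings[, seq_len(n_comp), drop = FALSE],
                 var_explained = pc$var_explained[seq_len(n_comp)],
                 members = subnet$members, block = subnet$block),
            class = "subnetwork_summary")
}
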
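# Synthetic three-block omics study generator with known ground truth.
#
# The generator emulates the structure of a three-group plasma multiomics
# study: correlated analyte sub-networks planted through a shared latent
# factor, group mean shifts per contrast, age/sex confounding, left
# censoring of the eicosanoid block at a detection limit and
# missing-at-random cells in the protein block. Everything planted is
# returned as ground truth so downstream stages can be scored.

#' Simulation configuration for a synthetic three-block study
#'
#' @param n_per_group samples per group (healthy, remission, active);
#'   single integer or length-3 vector, each at least 3.
#' @param block_sizes named analyte counts per block; defaults to a
#'   down-scaled study (60 proteins, 24 eicosanoids, 90 metabolites) that
#'   keeps tests fast; full-size studies are available by overriding.
#' @param planted_blocks list of planted sub-networks, each a list with
#'   \code{block}, \code{idx} (analyte indices within the block) and
#'   \code{loading} (latent-factor loading rho in (0, 1]). Analytes in a
#'   planted set get \code{x_j = rho * f + sqrt(1 - rho^2) * e_j} with one
#'   shared standard-normal factor \code{f} per sample, so the expected
#'   pairwise correlation within the set is \code{rho^2}.
#' @param effects list of planted group effects, each a list with
#'   \code{block}, \code{idx}, \code{shift} (log2 units) and \code{groups},
#'   the character subset of groups receiving the shift.
#' @param trajectory_profiles optional named list mapping
#'   \code{"<block>:<index>"} to an intended trajectory class
#'   (\code{normalising}, \code{non_normalising}, \code{exceptional});
#'   recorded as ground truth for scoring the trajectory classifier.
#' @param age_effect,sex_effect per-analyte confounder slopes: either a
#'   single number applied to every analyte or a named list of per-block
#'   vectors. Age enters centred (years minus 45) so slopes are per-year
#'   log2 change.
#' @param lod_quantile left-censoring quantile for the eicosanoid block,
#'   in [0, 1).
#' @param missing_rate missing-completely-at-random cell rate for the
#'   protein block, in [0, 1).
#' @param noise_sd residual standard deviation on the log2 scale (> 0).
#' @param base_log2 baseline log2 abundance added to every analyte before
#'   exponentiation to the raw scale.
#' @param mnar if \code{TRUE}, protein missingness is intensity dependent
#'   (lower values more likely missing) instead of uniform; off by default.
#' @param seed integer seed; every draw is deterministic given it.
#' @return a \code{sim_config} list, validated.
#' @export
sim_config <- function(n_per_group = c(11, 12, 16),
                       block_sizes = c(protein = 60, eicosanoid = 24,
                                       metabolite = 90),
                       planted_blocks = list(),
                       effects = list(),
                       trajectory_profiles = list(),
                       age_effect = 0, sex_effect = 0,
                       lod_quantile = 0.1, missing_rate = 0.05,
                       noise_sd = 1, base_log2 = 20, mnar = FALSE,
                       seed = 1L) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 3)
  stopifnot(length(n_per_group) == 3, all(n_per_group >= 3))
  names(n_per_group) <- GROUP_LEVELS
  stopifnot(all(BLOCK_LEVELS %in% names(block_sizes)),
            lod_quantile >= 0, lod_quantile < 1,
            missing_rate >= 0, missing_rate < 1, noise_sd > 0)
  for (pb in planted_blocks) {
    stopifnot(pb$block %in% BLOCK_LEVELS,
              all(pb$idx >= 1), all(pb$idx <= block_sizes[[pb$block]]),
              pb$loading > 0, pb$loading <= 1)
  }
  # planted sets within one block must be pairwise disjoint
  for (b in BLOCK_LEVELS) {
    idx <- unlist(lapply(planted_blocks,
                         function(pb) if (pb$block == b) pb$idx))
    if (anyDuplicated(idx))
      stop("planted blocks within block '", b, "' overlap")
  }
  for (ef in effects) {
    stopifnot(ef$block %in% BLOCK_LEVELS,
              all(ef$idx >= 1), all(ef$idx <= block_sizes[[ef$block]]),
              all(ef$groups %in% GROUP_LEVELS))
  }
  structure(list(n_per_group = n_per_group,
                 block_sizes = block_sizes[BLOCK_LEVELS],
                 planted_blocks = planted_blocks, effects = effects,
                 trajectory_profiles = trajectory_profiles,
                 age_effect = age_effect, sex_effect = sex_effect,
                 lod_quantile = lod_quantile, missing_rate = missing_rate,
                 noise_sd = noise_sd, base_log2 = base_log2, mnar = mnar,
                 seed = as.integer(seed)),
            class = "sim_config")
}

slopes_for_block <- function(spec, block, p) {
  if (is.list(spec)) {
    v <- spec[[block]]
    if (is.null(v)) rep(0, p) else rep_len(v, p)
  } else rep_len(spec, p)
}

#' Generate a synthetic three-block study
#'
#' Samples group labels, age (uniform on 25--65 years) and sex (balanced
#' Bernoulli), then builds each block on the log2 scale as latent-factor
#' structure plus planted group shifts, confounder terms and independent
#' Gaussian noise. The eicosanoid block is exponentiated to the raw scale
#' and left-censored at the configured quantile; the protein block receives
#' missing-at-random cells. All planted structure is returned in
#' \code{$truth}.
#'
#' @param config a [sim_config()].
#' @return a \code{synthetic_study} list with elements \code{blocks} (named
#'   list of three \code{analyte_matrix}), \code{meta} (a
#'   \code{sample_meta}) and \code{truth} (planted effect sets, partition
#'   and trajectory classes).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- sum(config$n_per_group)
  group <- factor(rep(GROUP_LEVELS, times = config$n_per_group),
                  levels = GROUP_LEVELS)
  age <- stats::runif(n, 25, 65)
  sex <- stats::rbinom(n, 1, 0.5)
  ids <- sprintf("S%03d", seq_len(n))
  meta <- sample_meta(ids, group, age, sex)

  blocks <- list()
  truth_partition <- list()
  for (b in BLOCK_LEVELS) {
    p <- config$block_sizes[[b]]
    eps <- matrix(stats::rnorm(n * p), n, p)
    x <- config$noise_sd * eps
    part <- rep(0L, p)
    k <- 0L
    for (pb in config$planted_blocks) {
      if (pb$block != b) next
      k <- k + 1L
      f <- stats::rnorm(n)
      rho <- pb$loading
      # correlated structure has unit marginal variance times noise_sd
      x[, pb$idx] <- config$noise_sd *
        (rho * f + sqrt(1 - rho^2) * eps[, pb$idx, drop = FALSE])
      part[pb$idx] <- k
    }
    for (ef in config$effects) {
      if (ef$block != b) next
      in_g <- group %in% ef$groups
      x[in_g, ef$idx] <- x[in_g, ef$idx, drop = FALSE] + ef$shift
    }
    a_slope <- slopes_for_block(config$age_effect, b, p)
    s_slope <- slopes_for_block(config$sex_effect, b, p)
    x <- x + outer(age - 45, a_slope) + outer(sex, s_slope)
    x <- x + config$base_log2
    dimnames(x) <- list(ids, sprintf("%s_%04d", substr(b, 1, 3),
                                     seq_len(p)))
    truth_partition[[b]] <- part
    blocks[[b]] <- analyte_matrix(x, block = b, scale = "log2")
  }

  # eicosanoid block: back-transform to raw intensities, then censor
  ei <- blocks$eicosanoid
  ei_raw <- analyte_matrix(2^ei$values, block = "eicosanoid",
                           scale = "raw")
  blocks$eicosanoid <- censor_below_lod(ei_raw, config$lod_quantile)
  # protein block: missing-at-random (or intensity-dependent) cells
  blocks$protein <- apply_missingness(blocks$protein,
                                      rate = config$missing_rate,
                                      seed = config$seed + 1L,
                                      mnar = config$mnar)

  true_effect_sets <- lapply(CONTRASTS, function(ct) {
    hits <- character(0)
    for (ef in config$effects) {
      # an analyte has a true effect under a contrast when the planted
      # shift differs between the two compared groups
      in_a <- ct$a %in% ef$groups
      in_b <- ct$b %in% ef$groups
      if (xor(in_a, in_b))
        hits <- c(hits, colnames(blocks[[ef$block]]$values)[ef$idx])
    }
    unique(hits)
  })
  names(true_effect_sets) <- names(CONTRASTS)

  truth <- list(true_effect_sets = true_effect_sets,
                true_partition = truth_partition,
                true_trajectory = config$trajectory_profiles)
  structure(list(blocks = blocks, meta = meta, truth = truth,
                 config = config),
            class = "synthetic_study")
}

#' Left-censor an analyte matrix at a per-analyte detection limit
#'
#' Values strictly below the analyte's empirical \code{lod_quantile}
#' (type-7 quantile of the observed values) are flagged below-LOD and
#' their numeric value removed. With tied values either all or none of a
#' tie group is flagged, never a proper subset, because censoring uses a
#' strict comparison against one per-analyte threshold.
#'
#' @param matrix an \code{analyte_matrix} on the raw (positive) scale.
#' @param lod_quantile fraction in [0, 1).
#' @return the censored \code{analyte_matrix}.
#' @export
censor_below_lod <- function(matrix, lod_quantile) {
  stopifnot(inherits(matrix, "analyte_matrix"))
  if (lod_quantile >= 1) stop("lod_quantile must be < 1")
  if (matrix$scale != "raw")
    stop("censoring is defined on the raw scale")
  if (lod_quantile <= 0) return(matrix)
  vals <- matrix$values
  lod <- apply(vals, 2, stats::quantile, probs = lod_quantile,
               na.rm = TRUE, names = FALSE)
  flag <- sweep(vals, 2, lod, "<")
  flag[is.na(flag)] <- FALSE
  flag <- flag & !matrix$missing_mask
  analyte_matrix(vals, block = matrix$block, scale = "raw",
                 missing_mask = matrix$missing_mask,
                 below_lod_mask = flag)
}

#' Mask cells of an analyte matrix at random
#'
#' Each observed cell is independently masked with probability
#' \code{rate}; in MNAR mode the per-cell probability is scaled by the
#' cell's within-analyte rank so that low-intensity values are more likely
#' to drop out (mean rate preserved).
#'
#' @param matrix an \code{analyte_matrix}.
#' @param rate fraction in [0, 1).
#' @param seed integer seed.
#' @param mnar logical; intensity-dependent missingness.
#' @return the masked \code{analyte_matrix}.
#' @export
apply_missingness <- function(matrix, rate, seed, mnar = FALSE) {
  stopifnot(inherits(matrix, "analyte_matrix"), rate >= 0, rate < 1)
  if (rate == 0) return(matrix)
  set.seed(as.integer(seed))
  vals <- matrix$values
  if (mnar) {
    # rank 1 (lowest) gets probability ~2*rate, highest ~0; mean = rate
    pr <- apply(vals, 2, function(v) {
      r <- rank(v, ties.method = "average")
      2 * rate * (1 - (r - 0.5) / length(v))
    })
    pr <- pmin(pr, 0.99)
  } else {
    pr <- matrix(rate, nrow(vals), ncol(vals))
  }
  mask <- matrix(stats::runif(length(vals)) < pr, nrow(vals), ncol(vals))
  mask <- mask & !matrix$below_lod_mask
  mask <- mask | matrix$missing_mask
  analyte_matrix(vals, block = matrix$block, scale = matrix$scale,
                 missing_mask = mask,
                 below_lod_mask = matrix$below_lod_mask)
}

#' Demonstration study configuration
#'
#' A fully featured synthetic study exercising every pipeline stage:
#' planted correlated sub-networks with group effects in two blocks, a
#' structure-only sub-network in the eicosanoid block, independent
#' significant single analytes, three age-driven analytes (an "age hub"
#' whose partial correlation with age survives full conditioning),
#' sex effects, left censoring and missing values. Group sizes follow
#' the cohort (11 healthy, 12 remission, 16 active).
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
demo_study_config <- function(seed = 1L) {
  p_protein <- 60
  # one strongly age-driven analyte: with a single such analyte the
  # age association is not explained away by conditioning on proxies,
  # so the age--analyte partial correlation survives the |R| cutoff
  age_slopes <- rep(0.01, p_protein)
  age_slopes[30] <- 0.1
  sim_config(
    n_per_group = c(11, 12, 16),
    block_sizes = c(protein = p_protein, eicosanoid = 24,
                    metabolite = 90),
    planted_blocks = list(
      list(block = "protein", idx = 1:5, loading = 0.9),
      list(block = "metabolite", idx = 1:6, loading = 0.9),
      list(block = "eicosanoid", idx = 1:4, loading = 0.9)),
    effects = list(
      list(block = "protein", idx = 1:5, shift = 2, groups = "active"),
      list(block = "metabolite", idx = 1:6, shift = -2,
           groups = "active"),
      list(block = "metabolite", idx = 10:12, shift = 2,
           groups = c("remission", "active")),
      list(block = "protein", idx = 40:42, shift = -1.5,
           groups = "active"),
      list(block = "protein", idx = 30, shift = 1.5,
           groups = "active")),
    trajectory_profiles = c(
      setNames(rep("normalising", 5), sprintf("pro_%04d", 1:5)),
      setNames(rep("non_normalising", 3), sprintf("met_%04d", 10:12))),
    age_effect = list(protein = age_slopes, eicosanoid = 0.01,
                      metabolite = 0.01),
    sex_effect = 0.3,
    lod_quantile = 0.1, missing_rate = 0.05, noise_sd = 1,
    seed = seed)
}

#' Write a synthetic study to a directory
#'
#' Blocks are written as delimited matrix tables (with mask side-tables),
#' metadata as a delimited table and ground truth as JSON.
#'
#' @param study a \code{synthetic_study}.
#' @param dir output directory, created if needed.
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in names(study$blocks))
    write_analyte_matrix(study$blocks[[b]],
                         file.path(dir, paste0(b, ".tsv")))
  write_sample_meta(study$meta, file.path(dir, "samples.tsv"))
  truth <- study$truth
  # a named atomic vector would lose its names in JSON; keep the map
  truth$true_trajectory <- as.list(truth$true_trajectory)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
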
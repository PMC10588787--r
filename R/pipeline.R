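# Orchestration: preprocess -> moderated contrasts -> GGM sweep + set
# analysis -> integration networks -> trajectory classification, from one
# configuration, with every intermediate table written out and a JSON run
# report. All randomness fans out from one seed via fixed per-stage
# offsets so each stage is individually reproducible.

#' Pipeline configuration
#'
#' Bundles every tunable constant of the analysis. Defaults are the
#' study's operating points: valid-value filter of 3 per group (plasma),
#' down-shift imputation at 1.8 sigma with width 0.3 sigma, K grid 1 to 6
#' in 0.5 steps, 5% FDR everywhere, 75% explained-variance rule for
#' sub-network PCs, strict |R| > 0.6 edge cutoff, trajectory closeness
#' delta = 1/3.
#'
#' @param min_valid valid values required in at least one group.
#' @param shift,width Gaussian down-shift imputation parameters
#'   (sd multiples).
#' @param k_grid penalty-multiplier grid for the GGM sweep.
#' @param ggm_family neighbourhood symmetrisation for [select_graph()].
#'   The pipeline defaults to \code{"neighborhood_or"}: under AND
#'   symmetrisation a correlated analyte set loses single edges
#'   asymmetrically just before it dissolves, splitting into fragments
#'   that can dominate the K-selection count; OR keeps sets intact until
#'   they dissolve, which the K-selection rule requires (see the methods
#'   vignette).
#' @param q FDR level for all selection steps.
#' @param pc1_threshold explained-variance rule for sub-network PCs.
#' @param edge_threshold strict absolute partial-correlation cutoff.
#' @param delta trajectory closeness fraction.
#' @param n_perm permutations for set association (10000 for production
#'   runs; reduce for quick checks).
#' @param seed master seed.
#' @param out_dir output directory, or \code{NULL} to skip writing.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(min_valid = 3, shift = 1.8, width = 0.3,
                            k_grid = seq(1, 6, by = 0.5),
                            ggm_family = "neighborhood_or",
                            q = 0.05, pc1_threshold = 0.75,
                            edge_threshold = 0.6, delta = 1/3,
                            n_perm = 10000, seed = 1L,
                            out_dir = NULL) {
  stopifnot(min_valid >= 1, shift >= 0, width >= 0,
            all(k_grid > 0), all(diff(k_grid) > 0),
            q > 0, q < 1, pc1_threshold > 0, pc1_threshold <= 1,
            edge_threshold >= 0, delta >= 0, n_perm >= 1)
  structure(list(min_valid = min_valid, shift = shift, width = width,
                 k_grid = k_grid, ggm_family = ggm_family, q = q,
                 pc1_threshold = pc1_threshold,
                 edge_threshold = edge_threshold, delta = delta,
                 n_perm = n_perm, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# block-specific preprocessing to complete log2 matrices
preprocess_blocks <- function(blocks, meta, config) {
  out <- list()
  for (b in names(blocks)) {
    m <- blocks[[b]]
    m <- filter_by_valid_values(m, meta, min_valid = config$min_valid)
    if (m$scale == "raw") {
      m <- impute_lod_min_over_sqrt2(m)
    }
    if (anyNA(m$values)) {
      m <- impute_gaussian_downshift(m, shift = config$shift,
                                     width = config$width,
                                     seed = config$seed + 101L)
    }
    out[[b]] <- m
  }
  out
}

write_tsv <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full integration pipeline
#'
#' Executes every stage in order on three preprocessed-or-raw omics
#' blocks: preprocessing, moderated contrasts per block, the GGM penalty
#' sweep with set-level association and K selection, per-contrast
#' variable pooling with partial-correlation networks, and trajectory
#' classification. Identical config + seed gives identical outputs.
#'
#' @param blocks named list of \code{analyte_matrix} objects
#'   (\code{protein}, \code{eicosanoid}, \code{metabolite}); a
#'   \code{synthetic_study} is also accepted.
#' @param meta \code{sample_meta}; taken from the study when
#'   \code{blocks} is one.
#' @param config a [pipeline_config()].
#' @return a \code{pipeline_result}: list with \code{processed} (complete
#'   log2 matrices), \code{contrast_results}, \code{sweep},
#'   \code{associations}, \code{chosen} (K selection), \code{summaries},
#'   \code{networks} (one \code{integration_network} per contrast),
#'   \code{trajectories} and \code{report}.
#' @export
run_pipeline <- function(blocks, meta = NULL,
                         config = pipeline_config()) {
  if (inherits(blocks, "synthetic_study")) {
    meta <- blocks$meta
    blocks <- blocks$blocks
  }
  stopifnot(inherits(config, "pipeline_config"), !is.null(meta))
  dir <- config$out_dir
  if (!is.null(dir)) dir.create(dir, recursive = TRUE,
                                showWarnings = FALSE)

  processed <- preprocess_blocks(blocks, meta, config)

  contrast_results <- lapply(processed, function(m)
    fit_moderated_contrasts(m, meta, q = config$q))
  for (b in names(contrast_results))
    write_tsv(contrast_results[[b]], dir,
              paste0("contrasts_", b, ".tsv"))

  zmats <- lapply(processed, zscore_by_analyte)
  sweep <- sweep_K(zmats, grid = config$k_grid,
                   family = config$ggm_family)
  associations <- test_all_subnetworks(sweep, contrast_results,
                                       n_perm = config$n_perm,
                                       seed = config$seed + 202L,
                                       q = config$q)
  chosen <- choose_K(sweep, associations)
  write_tsv(associations, dir, "subnetwork_associations.tsv")
  write_tsv(data.frame(K = names(chosen$counts),
                       significant_pairs = chosen$counts), dir,
            "k_selection.tsv")

  # summarise each distinct significant sub-network at K* once
  summaries <- list()
  if (!is.na(chosen$K)) {
    sig <- chosen$subnetworks
    for (id in unique(sig$subnetwork_id)) {
      row <- sig[sig$subnetwork_id == id, ][1, ]
      sn <- structure(list(members = strsplit(row$members, ";")[[1]],
                           block = row$block, K = chosen$K),
                      class = "subnetwork")
      summaries[[id]] <- summarize_pcs(zmats[[row$block]], sn,
                                       pc1_threshold =
                                         config$pc1_threshold)
    }
  }

  networks <- list()
  for (ct in names(CONTRASTS)) {
    sig_ids <- if (is.na(chosen$K)) character(0) else
      unique(chosen$subnetworks$subnetwork_id[
        chosen$subnetworks$contrast == ct])
    vs <- build_variable_set(contrast_results, summaries[sig_ids],
                             processed, meta, ct)
    # a covariate-only set (no significant variables) has nothing to
    # condition on: emit a node-only network
    if (ncol(vs$data) < 3) {
      pcm <- diag(ncol(vs$data))
      dimnames(pcm) <- list(colnames(vs$data), colnames(vs$data))
    } else pcm <- partial_correlations(vs)
    attrs <- vs$provenance
    fc <- do.call(rbind, contrast_results)
    fc <- fc[fc$contrast == ct, c("analyte_id", "estimate")]
    attrs$log2fc <- fc$estimate[match(attrs$column, fc$analyte_id)]
    networks[[ct]] <- build_network(pcm, attrs,
                                    threshold = config$edge_threshold)
    if (!is.null(dir))
      write_network(networks[[ct]], file.path(dir,
                                              paste0("network_", ct)))
  }

  trajectories <- do.call(rbind, lapply(processed, function(m)
    classify_trajectories(m, meta, delta = config$delta)))
  rownames(trajectories) <- NULL
  write_tsv(trajectories, dir, "trajectories.tsv")

  report <- list(
    n_samples = nrow(meta),
    n_analytes = vapply(processed, function(m) ncol(m$values), 1L),
    chosen_K = chosen$K,
    significant_pairs_per_K = as.list(chosen$counts),
    n_significant_subnetworks = length(summaries),
    n_significant_analytes = lapply(names(CONTRASTS), function(ct)
      sum(vapply(contrast_results, function(r)
        sum(r$significant[r$contrast == ct]), 1L))),
    network_edges = lapply(networks, function(nw) nrow(nw$edges)),
    trajectory_classes = as.list(table(trajectories$class)),
    config = config[setdiff(names(config), "out_dir")],
    seed = config$seed)
  names(report$n_significant_analytes) <- names(CONTRASTS)
  if (!is.null(dir))
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)

  structure(list(processed = processed,
                 contrast_results = contrast_results, sweep = sweep,
                 associations = associations, chosen = chosen,
                 summaries = summaries, networks = networks,
                 trajectories = trajectories, report = report),
            class = "pipeline_result")
}

#' @exportS3Method print pipeline_result
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("pipeline run:", r$n_samples, "samples;",
      paste(names(r$n_analytes), r$n_analytes, sep = "=",
            collapse = ", "), "analytes\n")
  cat("  chosen K:", ifelse(is.na(r$chosen_K), "none (sentinel)",
                            r$chosen_K),
      "with", r$n_significant_subnetworks,
      "significant sub-network(s)\n")
  for (ct in names(r$network_edges))
    cat(sprintf("  %s: %d significant analytes, %d network edges\n",
                ct, r$n_significant_analytes[[ct]],
                r$network_edges[[ct]]))
  invisible(x)
}
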
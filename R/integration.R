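# Stages 3-4: pool significant single analytes, sub-network principal
# components, age and sex into one variable set per contrast; compute
# full-order partial correlations; threshold into the integration
# network.

#' Assemble the per-contrast variable set
#'
#' Collects, for one contrast, the log2 values of every significant
#' single analyte across blocks, the principal-component scores of every
#' significant sub-network, and the age and sex covariates — one row per
#' sample. An analyte that is both individually significant and a member
#' of a summarised sub-network enters only through the sub-network PC
#' (de-duplication).
#'
#' @param results named list (per block) of [fit_moderated_contrasts()]
#'   results.
#' @param summaries named list of \code{subnetwork_summary} objects for
#'   the sub-networks significant under this contrast (may be empty).
#' @param matrices named list of complete \code{analyte_matrix} objects
#'   (log2 scale) per block.
#' @param meta \code{sample_meta} in matrix sample order.
#' @param contrast contrast name.
#' @return a \code{variable_set}: list with \code{data} (numeric matrix,
#'   samples x variables), \code{provenance} (data.frame: column, kind,
#'   block, members).
#' @export
build_variable_set <- function(results, summaries, matrices, meta,
                               contrast) {
  cols <- list()
  prov <- list()
  in_subnet <- unique(unlist(lapply(summaries, function(s) s$members)))
  for (b in names(results)) {
    st <- results[[b]]
    st <- st[st$contrast == contrast & st$significant, ]
    singles <- setdiff(st$analyte_id, in_subnet)
    for (a in singles) {
      cols[[a]] <- matrices[[b]]$values[, a]
      prov[[a]] <- data.frame(column = a, kind = "analyte", block = b,
                              members = a, stringsAsFactors = FALSE)
    }
  }
  for (sn in names(summaries)) {
    s <- summaries[[sn]]
    for (k in seq_len(ncol(s$scores))) {
      cn <- paste0(sn, "_PC", k)
      cols[[cn]] <- s$scores[, k]
      prov[[cn]] <- data.frame(column = cn, kind = "subnetwork_pc",
                               block = s$block,
                               members = paste(s$members,
                                               collapse = ";"),
                               stringsAsFactors = FALSE)
    }
  }
  cols[["age"]] <- meta$age
  cols[["sex"]] <- meta$sex
  for (cv in c("age", "sex"))
    prov[[cv]] <- data.frame(column = cv, kind = "covariate",
                             block = NA_character_, members = cv,
                             stringsAsFactors = FALSE)
  if (anyDuplicated(names(cols))) stop("duplicate variable-set columns")
  dat <- do.call(cbind, cols)
  rownames(dat) <- meta$sample_id
  structure(list(data = dat, provenance = do.call(rbind, prov),
                 contrast = contrast),
            class = "variable_set")
}

#' Full-order partial correlations of a variable set
#'
#' The partial correlation of each pair of columns given all remaining
#' columns, computed from the inverse of the correlation matrix:
#' \code{R_ij = -P_ij / sqrt(P_ii * P_jj)}. When the system is
#' ill-conditioned (columns approaching the sample count, or an exactly
#' singular correlation matrix), a small ridge term can be added to the
#' correlation diagonal.
#'
#' @param varset a \code{variable_set} or plain numeric matrix with at
#'   least 3 columns.
#' @param ridge ridge term added to the correlation diagonal;
#'   \code{NULL} (default) enables 1e-3 automatically when
#'   \code{n_samples <= n_columns + 2}, \code{0} disables regularisation.
#' @return symmetric partial-correlation matrix with unit diagonal;
#'   attribute \code{"ridge"} records the term used.
#' @export
partial_correlations <- function(varset, ridge = NULL) {
  X <- if (inherits(varset, "variable_set")) varset$data else varset
  stopifnot(is.matrix(X), ncol(X) >= 3)
  if (anyNA(X)) stop("variable set must be complete")
  n <- nrow(X); p <- ncol(X)
  if (is.null(ridge)) ridge <- if (n <= p + 2) 1e-3 else 0
  C <- stats::cor(X)
  if (ridge > 0) {
    C <- C + diag(ridge, p)
    C <- stats::cov2cor(C)
  }
  P <- tryCatch(solve(C), error = function(e)
    stop("correlation matrix is singular; set a positive ridge ",
         "(e.g. ridge = 1e-3)", call. = FALSE))
  D <- 1 / sqrt(diag(P))
  R <- -P * outer(D, D)
  diag(R) <- 1
  R <- (R + t(R)) / 2
  dimnames(R) <- dimnames(C)
  attr(R, "ridge") <- ridge
  R
}

#' Build the thresholded integration network
#'
#' Keeps an edge exactly where the absolute partial correlation strictly
#' exceeds the threshold; isolated nodes are retained so the network
#' always shows every pooled variable. Node attributes carry the node
#' kind, block, the contrast's log2 fold-change (for single analytes) and
#' sub-network membership (for PC nodes, used for pie rendering).
#'
#' @param pcm a [partial_correlations()] matrix.
#' @param node_attrs data.frame with one row per node (columns
#'   \code{column}, \code{kind}, \code{block}, \code{members}, optionally
#'   \code{log2fc}); typically the variable set's provenance joined with
#'   fold-changes.
#' @param threshold strict absolute-partial-correlation cutoff
#'   (default 0.6).
#' @return an \code{integration_network}: list with \code{nodes},
#'   \code{edges} (from, to, R) and \code{threshold}.
#' @export
build_network <- function(pcm, node_attrs, threshold = 0.6) {
  ids <- colnames(pcm)
  stopifnot(all(ids %in% node_attrs$column))
  node_attrs <- node_attrs[match(ids, node_attrs$column), ]
  keep <- abs(pcm) > threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      R = pcm[idx], stringsAsFactors = FALSE)
  structure(list(nodes = node_attrs, edges = edges,
                 threshold = threshold),
            class = "integration_network")
}

#' @exportS3Method print integration_network
print.integration_network <- function(x, ...) {
  cat(sprintf("integration network: %d nodes, %d edges (|R| > %g)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Write an integration network as node/edge tables and GraphML
#'
#' @param network an \code{integration_network}.
#' @param path base path; writes \code{<path>.nodes.tsv},
#'   \code{<path>.edges.tsv} and \code{<path>.graphml}.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$nodes, paste0(path, ".nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(network$edges, paste0(path, ".edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = FALSE,
    vertices = network$nodes$column)
  if (nrow(network$edges) > 0)
    igraph::E(g)$R <- network$edges$R
  igraph::V(g)$kind <- network$nodes$kind
  igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  invisible(path)
}
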
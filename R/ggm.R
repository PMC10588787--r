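# Stage 2a: Gaussian-graphical-model structure learning per block.
#
# Edges are estimated by Meinshausen-Buhlmann neighbourhood selection:
# each analyte is lasso-regressed on all others with the K-scaled
# universal penalty lambda_j(K) = K * sigma_j * sqrt(2 log(p) / n), and
# the node-wise neighbourhoods are symmetrised by AND (default) or OR.
# K plays the role of a scalar penalty multiplier: K = 1 is the
# theoretical universal penalty, larger K gives sparser graphs.

#' Select a Gaussian graphical model by neighbourhood lasso
#'
#' @param matrix a complete \code{analyte_matrix}; values are
#'   standardised internally.
#' @param K penalty multiplier (> 0); the per-node lasso penalty is
#'   \code{K * sd(residual proxy) * sqrt(2 * log(p) / n)} on the
#'   standardised scale.
#' @param family neighbourhood symmetrisation: \code{"neighborhood_and"}
#'   keeps an edge only when both incident nodes select it (conservative,
#'   default); \code{"neighborhood_or"} keeps it when either does.
#' @return a \code{ggm_graph}: list with \code{adjacency} (symmetric
#'   logical matrix, zero diagonal), \code{K}, \code{family},
#'   \code{block}.
#' @export
select_graph <- function(matrix, K,
                         family = c("neighborhood_and",
                                    "neighborhood_or")) {
  stopifnot(inherits(matrix, "analyte_matrix"), K > 0)
  family <- match.arg(family)
  X <- matrix$values
  if (anyNA(X)) stop("graph selection requires a complete matrix")
  n <- nrow(X); p <- ncol(X)
  if (n < 5) stop("need at least 5 samples")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant analyte(s) present: ",
         paste(colnames(X)[sds == 0], collapse = ", "),
         "; filter before graph selection")
  Z <- scale(X)
  selected <- matrix(FALSE, p, p, dimnames = list(colnames(X),
                                                  colnames(X)))
  if (p >= 2 && is.finite(K)) {
    lam_base <- sqrt(2 * log(p) / n)
    for (j in seq_len(p)) {
      y <- Z[, j]
      lam <- K * stats::sd(y) * lam_base
      # short decreasing path ending at the target penalty for a
      # well-converged single-lambda solution
      path <- lam * c(8, 4, 2, 1)
      fit <- glmnet::glmnet(Z[, -j, drop = FALSE], y, family = "gaussian",
                            lambda = path, standardize = FALSE,
                            intercept = FALSE)
      beta <- as.numeric(fit$beta[, length(path)])
      selected[j, -j] <- beta != 0
    }
  }
  adj <- if (family == "neighborhood_and") selected & t(selected)
         else selected | t(selected)
  diag(adj) <- FALSE
  structure(list(adjacency = adj, K = K, family = family,
                 block = matrix$block),
            class = "ggm_graph")
}

#' Extract sub-networks (connected components) from a selected graph
#'
#' @param graph a \code{ggm_graph}.
#' @param min_size smallest component size kept (default 2; isolated
#'   nodes are "single analytes" and are handled downstream).
#' @return list of \code{subnetwork} objects (fields \code{members},
#'   \code{block}, \code{K}), sorted by decreasing size then first member
#'   id.
#' @export
extract_subnetworks <- function(graph, min_size = 2) {
  stopifnot(inherits(graph, "ggm_graph"), min_size >= 1)
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency,
                                           mode = "undirected")
  comp <- igraph::components(g)
  keep <- which(comp$csize >= min_size)
  subs <- lapply(keep, function(k) {
    members <- sort(names(comp$membership)[comp$membership == k])
    structure(list(members = members, block = graph$block, K = graph$K),
              class = "subnetwork")
  })
  if (length(subs) == 0) return(list())
  ord <- order(-vapply(subs, function(s) length(s$members), 1L),
               vapply(subs, function(s) s$members[1], ""))
  subs[ord]
}

#' Sweep the penalty multiplier K over a grid
#'
#' Runs [select_graph()] and [extract_subnetworks()] for every K on every
#' block. The default grid is 1 to 6 in steps of 0.5.
#'
#' @param matrices named list of complete \code{analyte_matrix} objects.
#' @param grid strictly increasing positive K values.
#' @param family passed to [select_graph()].
#' @param min_size passed to [extract_subnetworks()].
#' @return a \code{k_sweep} object: list with \code{grid} and
#'   \code{by_K}, where \code{by_K[[as.character(K)]]} holds per-block
#'   \code{graph} and \code{subnetworks}.
#' @export
sweep_K <- function(matrices, grid = seq(1, 6, by = 0.5),
                    family = "neighborhood_and", min_size = 2) {
  stopifnot(length(grid) >= 1, all(diff(grid) > 0), all(grid > 0))
  by_K <- lapply(grid, function(K) {
    lapply(matrices, function(m) {
      g <- tryCatch(select_graph(m, K, family = family),
                    error = function(e)
                      stop("K = ", K, ", block ", m$block, ": ",
                           conditionMessage(e), call. = FALSE))
      list(graph = g, subnetworks = extract_subnetworks(g, min_size))
    })
  })
  names(by_K) <- as.character(grid)
  structure(list(grid = grid, by_K = by_K), class = "k_sweep")
}

#' @exportS3Method print k_sweep
print.k_sweep <- function(x, ...) {
  cat("K sweep over", length(x$grid), "penalty values\n")
  for (K in names(x$by_K)) {
    counts <- vapply(x$by_K[[K]],
                     function(e) length(e$subnetworks), 1L)
    cat(sprintf("  K = %-4s sub-networks: %s\n", K,
                paste(names(counts), counts, sep = "=",
                      collapse = ", ")))
  }
  invisible(x)
}

#' Write a selected graph as an edge list and GraphML
#'
#' @param graph a \code{ggm_graph}.
#' @param path base output path; writes \code{<path>.edges.tsv} and
#'   \code{<path>.graphml}.
#' @export
write_graph_files <- function(graph, path) {
  g <- igraph::graph_from_adjacency_matrix(graph$adjacency,
                                           mode = "undirected")
  el <- igraph::as_edgelist(g)
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]),
                     paste0(path, ".edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  igraph::write_graph(g, paste0(path, ".graphml"), format = "graphml")
  invisible(path)
}
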
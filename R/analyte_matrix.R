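#' @keywords internal
"_PACKAGE"

GROUP_LEVELS <- c("healthy", "remission", "active")
BLOCK_LEVELS <- c("protein", "eicosanoid", "metabolite")

#' Construct an analyte matrix
#'
#' The basic container for one omics block: a samples-by-analytes numeric
#' matrix together with a missing-value mask, a below-detection-limit mask,
#' a block label and a scale flag. Masked cells carry \code{NA} in
#' \code{values}; the two masks record why a cell is empty and are kept
#' disjoint.
#'
#' @param values numeric matrix, samples in rows, analytes in columns.
#'   Row and column names are used as sample and analyte identifiers and
#'   must be unique.
#' @param block one of \code{"protein"}, \code{"eicosanoid"},
#'   \code{"metabolite"}.
#' @param scale one of \code{"raw"}, \code{"log2"}, \code{"zscore"};
#'   tracks which transformations have been applied.
#' @param missing_mask logical matrix flagging missing-at-random cells;
#'   defaults to all \code{FALSE}.
#' @param below_lod_mask logical matrix flagging cells censored below the
#'   detection limit; defaults to all \code{FALSE}.
#' @return an object of class \code{analyte_matrix}.
#' @export
analyte_matrix <- function(values, block, scale = "raw",
                           missing_mask = NULL, below_lod_mask = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  block <- match.arg(block, BLOCK_LEVELS)
  scale <- match.arg(scale, c("raw", "log2", "zscore"))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("%s_%04d", substr(block, 1, 3),
                                seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("sample ids must be unique")
  if (anyDuplicated(colnames(values)))
    stop("analyte ids must be unique")
  empty <- matrix(FALSE, nrow(values), ncol(values),
                  dimnames = dimnames(values))
  if (is.null(missing_mask)) missing_mask <- empty
  if (is.null(below_lod_mask)) below_lod_mask <- empty
  stopifnot(identical(dim(missing_mask), dim(values)),
            identical(dim(below_lod_mask), dim(values)))
  if (any(missing_mask & below_lod_mask))
    stop("missing_mask and below_lod_mask must be disjoint")
  dimnames(missing_mask) <- dimnames(values)
  dimnames(below_lod_mask) <- dimnames(values)
  values[missing_mask | below_lod_mask] <- NA_real_
  structure(
    list(values = values, missing_mask = missing_mask,
         below_lod_mask = below_lod_mask, block = block, scale = scale),
    class = "analyte_matrix")
}

#' @exportS3Method print analyte_matrix
print.analyte_matrix <- function(x, ...) {
  cat(sprintf("analyte_matrix [%s, %s scale]: %d samples x %d analytes\n",
              x$block, x$scale, nrow(x$values), ncol(x$values)))
  cat(sprintf("  missing: %d cells, below LOD: %d cells\n",
              sum(x$missing_mask), sum(x$below_lod_mask)))
  invisible(x)
}

#' @export
dim.analyte_matrix <- function(x) dim(x$values)

analyte_ids <- function(x) colnames(x$values)
sample_ids  <- function(x) rownames(x$values)

# subset analytes by index or id, preserving masks
subset_analytes <- function(x, j) {
  analyte_matrix(x$values[, j, drop = FALSE], block = x$block,
                 scale = x$scale,
                 missing_mask = x$missing_mask[, j, drop = FALSE],
                 below_lod_mask = x$below_lod_mask[, j, drop = FALSE])
}

#' Construct sample metadata
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group character or factor with levels \code{healthy},
#'   \code{remission}, \code{active}.
#' @param age numeric, years.
#' @param sex 0/1 indicator (or a factor/character coerced to 0/1 with the
#'   first level as 0).
#' @return a \code{data.frame} of class \code{sample_meta}.
#' @export
sample_meta <- function(sample_id, group, age, sex) {
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  group <- factor(as.character(group), levels = GROUP_LEVELS)
  if (anyNA(group)) stop("group must be one of: ",
                         paste(GROUP_LEVELS, collapse = ", "))
  if (!is.numeric(sex)) sex <- as.integer(factor(sex)) - 1L
  if (!all(sex %in% c(0, 1))) stop("sex must be a 0/1 indicator")
  out <- data.frame(sample_id = as.character(sample_id), group = group,
                    age = as.numeric(age), sex = as.numeric(sex),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_meta", "data.frame")
  out
}

# check a matrix/meta pair: every sample has exactly one metadata record,
# in the same order
check_samples_match <- function(matrix, meta) {
  if (!identical(rownames(matrix$values), meta$sample_id))
    stop("sample ordering of matrix and metadata differ")
  invisible(TRUE)
}

#' Write an analyte matrix as delimited text
#'
#' Analytes in rows, samples in columns, first column the analyte id;
#' masked cells are written as empty fields. The two masks are written as
#' parallel \code{<path>.missing.tsv} / \code{<path>.lod.tsv} tables.
#'
#' @param x an \code{analyte_matrix}.
#' @param path output path of the value table (tab-separated).
#' @return \code{path}, invisibly.
#' @export
write_analyte_matrix <- function(x, path) {
  tab <- data.frame(analyte_id = analyte_ids(x),
                    t(x$values), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  for (m in c("missing", "lod")) {
    mask <- if (m == "missing") x$missing_mask else x$below_lod_mask
    mt <- data.frame(analyte_id = analyte_ids(x), t(mask),
                     check.names = FALSE)
    utils::write.table(mt, paste0(path, ".", m, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read an analyte matrix written by [write_analyte_matrix()]
#'
#' @param path path of the value table.
#' @param block block label.
#' @param scale scale flag.
#' @return an \code{analyte_matrix}.
#' @export
read_analyte_matrix <- function(path, block, scale = "raw") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, na.strings = "")
  vals <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(vals) <- tab[[1]]
  read_mask <- function(suffix) {
    p <- paste0(path, ".", suffix, ".tsv")
    if (!file.exists(p)) return(NULL)
    mt <- utils::read.table(p, sep = "\t", header = TRUE,
                            check.names = FALSE)
    mm <- t(as.matrix(mt[, -1, drop = FALSE]))
    colnames(mm) <- mt[[1]]
    mm
  }
  analyte_matrix(vals, block = block, scale = scale,
                 missing_mask = read_mask("missing"),
                 below_lod_mask = read_mask("lod"))
}

#' Write sample metadata as delimited text
#' @param meta a \code{sample_meta}.
#' @param path output path (tab-separated).
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata written by [write_sample_meta()]
#' @param path input path.
#' @export
read_sample_meta <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  sample_meta(tab$sample_id, tab$group, tab$age, tab$sex)
}
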
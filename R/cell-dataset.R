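#' Single-cell expression dataset with trajectory annotation
#'
#' Container pairing a genes x cells count matrix with per-cell metadata
#' (state label, pseudotime, 2-D embedding) and a log-normalised layer.
#' The normalised layer is `log1p` of counts depth-scaled to the median
#' library size, the monotone normalisation used throughout the package
#' for network fitting, differential expression and signature scoring.
#'
#' @param counts genes x cells matrix of non-negative counts with row
#'   (gene) and column (cell) names.
#' @param cells data.frame with one row per cell and columns `cell_id`,
#'   `state`, `pseudotime`, `emb_x`, `emb_y`. `cell_id` must match the
#'   column names of `counts`.
#' @param norm optional pre-computed normalised layer (genes x cells);
#'   computed from `counts` when `NULL`.
#' @return An object of class `cell_dataset`: a list with elements
#'   `counts`, `norm`, `cells` and `genes`.
#' @examples
#' sim <- simulate_trajectory_dataset(trajectory_config(n_cells = 40,
#'   n_tfs = 3, n_targets = 10, seed = 1))
#' sim$dataset
#' @export
cell_dataset <- function(counts, cells, norm = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have gene row names and cell column names")
  req <- c("cell_id", "state", "pseudotime", "emb_x", "emb_y")
  miss <- setdiff(req, names(cells))
  if (length(miss))
    stopf("cells metadata lacks column(s): %s", paste(miss, collapse = ", "))
  if (!identical(as.character(cells$cell_id), colnames(counts)))
    stopf("cells$cell_id must match colnames(counts) in order")
  if (any(!is.finite(cells$pseudotime)))
    stopf("pseudotime must be finite for every cell")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (is.null(norm)) norm <- normalize_depth(counts)
  structure(list(counts = counts, norm = norm,
                 cells = as.data.frame(cells, stringsAsFactors = FALSE),
                 genes = rownames(counts)),
            class = "cell_dataset")
}

#' Depth-scale and log-transform a count matrix
#'
#' Scales each cell's counts to the median library size and applies
#' `log1p`. Cells with zero total counts are left at zero.
#'
#' @param counts genes x cells count matrix.
#' @return Matrix of the same shape, `log1p(count / depth * median depth)`.
#' @export
normalize_depth <- function(counts) {
  depth <- colSums(counts)
  target <- stats::median(depth[depth > 0])
  sf <- ifelse(depth > 0, target / depth, 0)
  log1p(sweep(counts, 2L, sf, `*`))
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("cell_dataset: %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  st <- table(x$cells$state)
  cat("states:", paste(sprintf("%s (%d)", names(st), st), collapse = ", "), "\n")
  cat(sprintf("pseudotime range: [%.3f, %.3f]\n",
              min(x$cells$pseudotime), max(x$cells$pseudotime)))
  invisible(x)
}

#' @export
dim.cell_dataset <- function(x) dim(x$counts)

## Resolve a cell selector (NULL = all, logical, integer, character ids,
## or a character vector of state names) to integer indices.
resolve_cells <- function(dataset, cells) {
  n <- ncol(dataset$counts)
  if (is.null(cells)) return(seq_len(n))
  if (is.logical(cells)) {
    stopifnot(length(cells) == n)
    return(which(cells))
  }
  if (is.numeric(cells)) return(as.integer(cells))
  cells <- as.character(cells)
  if (all(cells %in% dataset$cells$state))
    return(which(dataset$cells$state %in% cells))
  idx <- match(cells, dataset$cells$cell_id)
  if (anyNA(idx))
    stopf("unknown cell ids or states: %s",
          paste(utils::head(cells[is.na(idx)], 3), collapse = ", "))
  idx
}
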
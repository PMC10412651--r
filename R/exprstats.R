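#' Depth-normalize a count matrix to counts per 10,000 and log-transform
#'
#' Scales every cell's counts so they sum to 10,000 (CP10K) and then applies
#' \code{log2(1 + x)}. The raw text-book transform would be \code{log2(x)},
#' but zeros dominate single-nucleus data, so a pseudocount of 1 -- the
#' community default -- is used; set \code{log = FALSE} for the pre-log
#' CP10K values (whose per-cell sums are exactly 10,000).
#'
#' @param counts non-negative matrix or sparse \code{Matrix}, genes in rows,
#'   cells in columns.
#' @param log apply \code{log2(1 + x)} after depth normalization.
#' @return matrix of the same shape and class family as the input.
#' @examples
#' m <- matrix(c(5, 5), 2, 1, dimnames = list(c("MAPT", "other"), "c1"))
#' normalizeCp10k(m, log = FALSE)  # both 5000
#' @export
normalizeCp10k <- function(counts, log = TRUE) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    if (is.null(bad)) bad <- which(lib == 0)
    stop("zero-count cell(s): ", paste(utils::head(bad, 10), collapse = ", "),
         if (sum(lib == 0) > 10) " ..." else "", call. = FALSE)
  }
  norm <- if (is(counts, "Matrix")) {
    counts %*% Matrix::Diagonal(x = 1e4 / lib)
  } else {
    sweep(counts, 2L, lib / 1e4, "/")
  }
  dimnames(norm) <- dimnames(counts)
  if (log) {
    if (is(norm, "sparseMatrix")) {
      norm <- methods::as(norm, "CsparseMatrix")
      norm@x <- log2(1 + norm@x)   # log2(1 + 0) = 0, so zeros stay implicit
    } else {
      norm <- log2(1 + norm)
    }
  }
  norm
}

#' Compare MAPT expression between groups within each cell type
#'
#' For every cell type present in the metadata, runs a two-sided
#' Mann-Whitney U test of the normalized gene values between the two groups
#' (control vs disease). Cell types lacking one of the groups are an error,
#' as is a missing gene.
#'
#' @param norm normalized matrix from \code{\link{normalizeCp10k}}, genes in
#'   rows, cells in columns.
#' @param meta data.frame with columns \code{cell_id}, \code{group},
#'   \code{cell_type}; every column of \code{norm} must have a metadata row.
#' @param gene gene identifier to test (default \code{"MAPT"}).
#' @param alpha significance level (default 0.01).
#' @return data.frame, one row per cell type, with the test columns of
#'   \code{\link{mannWhitney}} plus \code{cell_type}.
#' @export
compareMaptByCelltype <- function(norm, meta, gene = "MAPT", alpha = 0.01) {
  if (!gene %in% rownames(norm))
    stop("gene '", gene, "' not found in the matrix", call. = FALSE)
  need <- c("cell_id", "group", "cell_type")
  if (!all(need %in% names(meta)))
    stop("meta must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (!is.null(colnames(norm))) {
    if (!all(colnames(norm) %in% meta$cell_id))
      stop("every matrix cell needs a metadata row", call. = FALSE)
    meta <- meta[match(colnames(norm), meta$cell_id), , drop = FALSE]
  } else if (nrow(meta) != ncol(norm)) {
    stop("meta rows must match matrix columns", call. = FALSE)
  }
  groups <- unique(meta$group)
  if (length(groups) != 2)
    stop("exactly two groups are required, found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  vals <- as.numeric(norm[gene, ])
  out <- lapply(unique(meta$cell_type), function(ty) {
    inTy <- meta$cell_type == ty
    g1 <- vals[inTy & meta$group == groups[1]]
    g2 <- vals[inTy & meta$group == groups[2]]
    if (!length(g1) || !length(g2))
      stop("cell type '", ty, "' lacks one of the groups", call. = FALSE)
    cbind(data.frame(cell_type = ty, stringsAsFactors = FALSE),
          mannWhitney(g1, g2, alpha = alpha, labels = groups))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
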
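# File formats: multi-page TIFF fields, CSV tables, MatrixMarket count
# matrices. Pixel size and channel order are declared by the caller/config,
# never parsed from TIFF metadata dialects.

#' Write a field to a multi-page TIFF
#'
#' One page per channel, in a declared role order, 16-bit. Intensities are
#' clipped to [0, 1] on write.
#'
#' @param field a \linkS4class{FieldImage}.
#' @param path output path.
#' @param channelOrder roles to write, in page order (defaults to the
#'   channels present, in their stored order).
#' @return invisibly, the path.
#' @export
writeFieldTiff <- function(field, path, channelOrder = names(field@channels)) {
  stopifnot(is(field, "FieldImage"))
  pages <- lapply(channelOrder, function(role) {
    ch <- getChannel(field, role)
    ch[ch < 0] <- 0; ch[ch > 1] <- 1
    ch
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a field from a multi-page TIFF
#'
#' @param path TIFF path.
#' @param umPerPx pixel size in micrometres (from the run configuration).
#' @param channelOrder channel roles of the pages, in page order.
#' @param fieldId,caseId,region,markerType field annotation.
#' @return a \linkS4class{FieldImage}.
#' @export
readFieldTiff <- function(path, umPerPx,
                          channelOrder = c("nucleus", "marker", "transcript", "ptau"),
                          fieldId = basename(path), caseId = "case1",
                          region = "frontal cortex", markerType = "neuron") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < length(channelOrder))
    stop(sprintf("expected %d pages in %s, found %d", length(channelOrder),
                 path, length(pages)), call. = FALSE)
  ch <- lapply(pages[seq_along(channelOrder)], function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    matrix(as.numeric(p), nrow(p), ncol(p))
  })
  names(ch) <- channelOrder
  FieldImage(ch, umPerPx, fieldId = fieldId, caseId = caseId, region = region,
             markerType = markerType)
}

#' Write / read a density table as CSV
#'
#' The CSV carries the documented per-cell columns; provenance travels in a
#' JSON sidecar (\code{<path>.provenance.json}).
#'
#' @param table a \linkS4class{DensityTable}.
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
writeDensityTable <- function(table, path) {
  stopifnot(is(table, "DensityTable"))
  utils::write.csv(records(table), path, row.names = FALSE)
  jsonlite::write_json(provenance(table), paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeDensityTable
#' @export
readDensityTable <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".provenance.json")
  prov <- if (file.exists(side)) jsonlite::read_json(side) else list()
  DensityTable(rec, prov)
}

#' Write manual ROI polygons to CSV
#'
#' Writes the polygon-per-cell format read by \code{\link{importManualRois}}:
#' columns \code{roi_id}, \code{role}, \code{vertex_index}, \code{x_px},
#' \code{y_px} (0-based, x = column, y = row).
#'
#' @param polygons data.frame with those columns.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeManualRois <- function(polygons, path) {
  need <- c("roi_id", "role", "vertex_index", "x_px", "y_px")
  if (!all(need %in% names(polygons)))
    stop("polygons must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  utils::write.csv(polygons[, need], path, row.names = FALSE)
  invisible(path)
}

#' Write / read a count matrix as MatrixMarket + index files
#'
#' Writes \code{matrix.mtx} (genes x cells), \code{genes.txt},
#' \code{barcodes.txt} and \code{meta.csv} (\code{cell_id}, \code{group},
#' \code{cell_type}) into a directory.
#'
#' @param counts integer matrix or sparse \code{Matrix}, genes x cells.
#' @param meta per-cell metadata data.frame.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeExprMatrix <- function(counts, meta, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.txt"))
  writeLines(colnames(counts), file.path(dir, "barcodes.txt"))
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeExprMatrix
#' @export
readExprMatrix <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(counts) <- "integer"
  rownames(counts) <- readLines(file.path(dir, "genes.txt"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.txt"))
  meta <- utils::read.csv(file.path(dir, "meta.csv"), stringsAsFactors = FALSE)
  list(counts = counts, meta = meta)
}

#' Write / read ground truth tables
#'
#' Persists the per-cell truth of a synthetic field as CSV (label matrices
#' are not serialized; regenerate from the config when needed).
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(is(truth, "GroundTruth"))
  utils::write.csv(truthCells(truth), path, row.names = FALSE)
  invisible(path)
}
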
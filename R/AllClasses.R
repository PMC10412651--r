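#' @import methods
NULL

.CHANNEL_ROLES <- c("nucleus", "marker", "transcript", "ptau")
.CELL_TYPES <- c("neuron", "oligodendrocyte", "astrocyte")

#' Multi-channel fluorescence field
#'
#' A single 2D field of view from a multiplex FISH experiment. Channels are
#' stored as numeric matrices (rows = y, columns = x) indexed by role:
#' \code{nucleus} (DAPI), \code{marker} (one cell-type probe among RBFOX3 /
#' Olig2 / ALDH1L1 -- one marker per field, so typing is binary typed/untyped),
#' \code{transcript} (MAPT probe) and optionally \code{ptau} (AT8
#' immunofluorescence; absent for control tissue, where no inclusions occur).
#'
#' @slot channels named list of numeric matrices, one per channel role.
#' @slot umPerPx physical pixel size in micrometres.
#' @slot fieldId,caseId,region provenance identifiers.
#' @slot markerType the cell type the marker channel labels.
#' @exportClass FieldImage
setClass("FieldImage",
  representation(
    channels = "list",
    umPerPx = "numeric",
    fieldId = "character",
    caseId = "character",
    region = "character",
    markerType = "character"
  )
)

setValidity("FieldImage", function(object) {
  ch <- object@channels
  msgs <- character()
  if (is.null(names(ch)) || !all(names(ch) %in% .CHANNEL_ROLES))
    msgs <- c(msgs, sprintf("channel roles must be among: %s",
                            paste(.CHANNEL_ROLES, collapse = ", ")))
  required <- c("nucleus", "marker", "transcript")
  if (!all(required %in% names(ch)))
    msgs <- c(msgs, sprintf("missing required channel(s): %s",
                            paste(setdiff(required, names(ch)), collapse = ", ")))
  if (!all(vapply(ch, is.matrix, logical(1))))
    msgs <- c(msgs, "all channels must be matrices")
  dims <- lapply(ch, dim)
  if (length(dims) > 1L && !all(vapply(dims, identical, logical(1), dims[[1]])))
    msgs <- c(msgs, "all channels must have identical dimensions")
  if (length(object@umPerPx) != 1L || !is.finite(object@umPerPx) ||
      object@umPerPx <= 0)
    msgs <- c(msgs, "umPerPx must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FieldImage
#'
#' @param channels named list of numeric matrices; names are channel roles
#'   (\code{nucleus}, \code{marker}, \code{transcript}, optional \code{ptau}).
#' @param umPerPx pixel size in micrometres per pixel.
#' @param fieldId,caseId,region identifiers carried into downstream tables.
#' @param markerType which cell type the marker channel labels
#'   (\code{"neuron"}, \code{"oligodendrocyte"} or \code{"astrocyte"}).
#' @return a \linkS4class{FieldImage}.
#' @examples
#' ch <- list(nucleus = matrix(0, 8, 8), marker = matrix(0, 8, 8),
#'            transcript = matrix(0, 8, 8))
#' FieldImage(ch, umPerPx = 0.5)
#' @export
FieldImage <- function(channels, umPerPx, fieldId = "field1", caseId = "case1",
                       region = "frontal cortex", markerType = "neuron") {
  new("FieldImage", channels = channels, umPerPx = as.numeric(umPerPx),
      fieldId = as.character(fieldId), caseId = as.character(caseId),
      region = as.character(region), markerType = as.character(markerType))
}

#' Per-field cell segmentation
#'
#' Holds the labelled nucleus and cell masks for one field together with a
#' per-cell table. Label matrices use 0 for background and the integer cell id
#' elsewhere; a cell's nucleus pixels always lie inside its cell mask, and
#' cell masks are pairwise disjoint by construction (contested pixels of
#' overlapping dilations are assigned to the nearest nucleus).
#'
#' @slot nucLabels,cellLabels integer label matrices.
#' @slot cells data.frame with one row per cell: \code{cell_id},
#'   \code{centroid_row}, \code{centroid_col} (1-based pixel coordinates),
#'   \code{nucleus_area_px}, \code{cell_area_px}, \code{cell_type},
#'   \code{source} (\code{auto}/\code{manual}), \code{border} (logical flag for
#'   cells whose mask touches the field boundary).
#' @slot umPerPx pixel size in micrometres.
#' @exportClass SegmentedField
setClass("SegmentedField",
  representation(
    nucLabels = "matrix",
    cellLabels = "matrix",
    cells = "data.frame",
    umPerPx = "numeric"
  )
)

setValidity("SegmentedField", function(object) {
  msgs <- character()
  if (!identical(dim(object@nucLabels), dim(object@cellLabels)))
    msgs <- c(msgs, "nucleus and cell label matrices must have the same dimensions")
  need <- c("cell_id", "centroid_row", "centroid_col", "nucleus_area_px",
            "cell_area_px", "cell_type", "source", "border")
  if (!all(need %in% names(object@cells)))
    msgs <- c(msgs, sprintf("cells table missing column(s): %s",
                            paste(setdiff(need, names(object@cells)), collapse = ", ")))
  if (anyDuplicated(object@cells$cell_id))
    msgs <- c(msgs, "cell ids must be unique")
  # every nucleus pixel must carry the same label in the cell mask
  nz <- object@nucLabels != 0L
  if (any(nz) && !all(object@cellLabels[nz] == object@nucLabels[nz]))
    msgs <- c(msgs, "nucleus masks must be contained in their cell masks")
  if (length(msgs)) msgs else TRUE
})

#' Per-cell transcript area-density table
#'
#' The tabular product of the quantification stage: one row per retained cell
#' with its whole-cell and nuclear MAPT area densities (percent of the ROI area
#' covered by transcript-positive signal), plus provenance (generation
#' parameters, seed, package version) needed to reproduce the table.
#'
#' @slot records data.frame with columns \code{cell_id}, \code{field_id},
#'   \code{case_id}, \code{region}, \code{cell_type}, \code{source},
#'   \code{inclusion}, \code{cell_area_um2}, \code{nuc_area_um2},
#'   \code{mapt_area_um2}, \code{nuc_mapt_area_um2}, \code{density_pct},
#'   \code{nuc_density_pct}.
#' @slot provenance named list (free-form; typically config hash, seed,
#'   package version).
#' @exportClass DensityTable
setClass("DensityTable",
  representation(records = "data.frame", provenance = "list")
)

.DENSITY_COLS <- c("cell_id", "field_id", "case_id", "region", "cell_type",
                   "source", "inclusion", "cell_area_um2", "nuc_area_um2",
                   "mapt_area_um2", "nuc_mapt_area_um2", "density_pct",
                   "nuc_density_pct")

setValidity("DensityTable", function(object) {
  rec <- object@records
  msgs <- character()
  if (!all(.DENSITY_COLS %in% names(rec)))
    msgs <- c(msgs, sprintf("records missing column(s): %s",
                            paste(setdiff(.DENSITY_COLS, names(rec)), collapse = ", ")))
  if (nrow(rec)) {
    key <- paste(rec$case_id, rec$field_id, rec$cell_id, sep = "\r")
    if (anyDuplicated(key))
      msgs <- c(msgs, "cell ids must be unique within (case, field)")
    d <- c(rec$density_pct, rec$nuc_density_pct)
    d <- d[!is.na(d)]
    if (length(d) && (min(d) < 0 || max(d) > 100))
      msgs <- c(msgs, "densities must lie in [0, 100]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a DensityTable
#'
#' @param records data.frame of per-cell records (see
#'   \linkS4class{DensityTable} for the required columns).
#' @param provenance named list recording how the table was produced.
#' @return a \linkS4class{DensityTable}.
#' @export
DensityTable <- function(records, provenance = list()) {
  new("DensityTable", records = as.data.frame(records), provenance = provenance)
}

#' Ground truth for a synthetic field
#'
#' Exported truth of the synthetic generator: per-cell labels, inclusion
#' flags and true densities, plus the truth label matrices and the exact
#' transcript-positive pixel mask, for parameter-recovery tests.
#'
#' @slot cells data.frame: \code{cell_id}, \code{cell_type},
#'   \code{centroid_row}, \code{centroid_col}, \code{inclusion},
#'   \code{true_density_pct}, \code{true_nuc_density_pct}.
#' @slot nucLabels,cellLabels integer truth label matrices (disjoint cells,
#'   nucleus inside cell).
#' @slot transcriptMask logical matrix of truly transcript-positive pixels.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    cells = "data.frame",
    nucLabels = "matrix",
    cellLabels = "matrix",
    transcriptMask = "matrix"
  )
)

setValidity("GroundTruth", function(object) {
  msgs <- character()
  tr <- object@cells
  d <- c(tr$true_density_pct, tr$true_nuc_density_pct)
  d <- d[!is.na(d)]
  if (length(d) && (min(d) < 0 || max(d) > 100))
    msgs <- c(msgs, "true densities must lie in [0, 100]")
  nz <- object@nucLabels != 0L
  if (any(nz) && !all(object@cellLabels[nz] == object@nucLabels[nz]))
    msgs <- c(msgs, "nucleus masks must be contained in their cell masks")
  if (length(msgs)) msgs else TRUE
})

# ---- show methods ----

setMethod("show", "FieldImage", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("FieldImage '%s' (case %s, %s)\n", object@fieldId,
              object@caseId, object@region))
  cat(sprintf("  %d x %d px @ %.3g um/px; channels: %s; marker labels: %s\n",
              d[1], d[2], object@umPerPx,
              paste(names(object@channels), collapse = ", "),
              object@markerType))
})

setMethod("show", "SegmentedField", function(object) {
  cat(sprintf("SegmentedField: %d cells (%d typed, %d border-flagged), %d x %d px\n",
              nrow(object@cells), sum(object@cells$cell_type != "untyped"),
              sum(object@cells$border), nrow(object@nucLabels),
              ncol(object@nucLabels)))
})

setMethod("show", "DensityTable", function(object) {
  rec <- object@records
  cat(sprintf("DensityTable: %d cells", nrow(rec)))
  if (nrow(rec)) {
    cat(sprintf(" (%d with inclusions) from %d field(s)",
                sum(rec$inclusion), length(unique(rec$field_id))))
    cat(sprintf("; mean density %.2f%%", mean(rec$density_pct)))
  }
  cat("\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d synthetic cells (%d inclusion-bearing)\n",
              nrow(object@cells), sum(object@cells$inclusion)))
})

# ---- accessors ----

#' @rdname FieldImage
#' @param x a \linkS4class{FieldImage}.
#' @param role channel role to extract.
#' @export
getChannel <- function(x, role) {
  stopifnot(is(x, "FieldImage"))
  if (!role %in% names(x@channels))
    stop(sprintf("channel role '%s' not present in field '%s'", role, x@fieldId),
         call. = FALSE)
  x@channels[[role]]
}

#' @rdname FieldImage
#' @export
hasChannel <- function(x, role) role %in% names(x@channels)

#' @rdname FieldImage
#' @export
umPerPx <- function(x) {
  if (is(x, "FieldImage") || is(x, "SegmentedField")) x@umPerPx
  else stop("no umPerPx for this object")
}

#' @rdname FieldImage
#' @export
fieldId <- function(x) x@fieldId

#' @rdname SegmentedField-class
#' @param x a \linkS4class{SegmentedField}.
#' @export
cellData <- function(x) { stopifnot(is(x, "SegmentedField")); x@cells }

#' @rdname SegmentedField-class
#' @export
nucleusLabels <- function(x) { stopifnot(is(x, "SegmentedField")); x@nucLabels }

#' @rdname SegmentedField-class
#' @export
cellLabels <- function(x) { stopifnot(is(x, "SegmentedField")); x@cellLabels }

#' @rdname DensityTable
#' @param x a \linkS4class{DensityTable}.
#' @export
records <- function(x) { stopifnot(is(x, "DensityTable")); x@records }

#' @rdname DensityTable
#' @export
provenance <- function(x) { stopifnot(is(x, "DensityTable")); x@provenance }

#' @rdname GroundTruth-class
#' @param x a \linkS4class{GroundTruth}.
#' @export
truthCells <- function(x) { stopifnot(is(x, "GroundTruth")); x@cells }

#' @rdname GroundTruth-class
#' @export
truthTranscriptMask <- function(x) { stopifnot(is(x, "GroundTruth")); x@transcriptMask }

#' @rdname GroundTruth-class
#' @export
truthCellLabels <- function(x) { stopifnot(is(x, "GroundTruth")); x@cellLabels }

#' @rdname GroundTruth-class
#' @export
truthNucleusLabels <- function(x) { stopifnot(is(x, "GroundTruth")); x@nucLabels }
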
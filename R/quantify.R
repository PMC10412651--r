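#' Segment transcript-positive signal
#'
#' Produces the binary mask of transcript-positive pixels on the transcript
#' channel, either by per-field Otsu thresholding (default) or by a fixed
#' global threshold for cross-field comparability. Because RNAscope puncta
#' occur singly or in small confluent clusters, no per-spot counting is
#' attempted anywhere downstream: the measurement is area-based throughout.
#'
#' @param field a \linkS4class{FieldImage}.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param fixedThreshold intensity cut, required iff \code{method = "fixed"};
#'   pixels strictly above it are positive.
#' @return logical matrix of transcript-positive pixels.
#' @export
segmentTranscripts <- function(field, method = c("otsu", "fixed"),
                               fixedThreshold = NULL) {
  stopifnot(is(field, "FieldImage"))
  method <- match.arg(method)
  ch <- getChannel(field, "transcript")
  .assertFinite(ch, "transcript channel")
  if (method == "fixed") {
    if (is.null(fixedThreshold) || !is.finite(fixedThreshold))
      stop("fixedThreshold is required when method = 'fixed'", call. = FALSE)
    return(ch > fixedThreshold)
  }
  rng <- range(ch)
  if (diff(rng) == 0)
    stop("degenerate threshold: transcript channel has uniform intensity; ",
         "use method = 'fixed'", call. = FALSE)
  th <- EBImage::otsu(EBImage::Image(ch), range = rng)
  ch > th
}

#' Whole-cell and nuclear area density for one cell
#'
#' Area density is the total transcript-positive area within a region of
#' interest divided by the area of that region, expressed as a percentage:
#' \code{100 * |mask & roi| / |roi|}. Being a pixel-count ratio it is
#' independent of the physical pixel size.
#'
#' @param cellMask,nucleusMask logical matrices for one cell; the nucleus
#'   mask may be NULL (nuclear density is then NA -- undefined, not zero).
#' @param transcriptMask logical matrix from \code{\link{segmentTranscripts}}.
#' @return named numeric: \code{density_pct}, \code{nuc_density_pct}.
#' @examples
#' cell <- matrix(FALSE, 4, 4); cell[2:3, 2:3] <- TRUE
#' tx <- matrix(FALSE, 4, 4); tx[2, 2:3] <- TRUE
#' areaDensity(cell, NULL, tx)  # 50% whole-cell, NA nuclear
#' @export
areaDensity <- function(cellMask, nucleusMask, transcriptMask) {
  stopifnot(is.matrix(cellMask), is.matrix(transcriptMask),
            identical(dim(cellMask), dim(transcriptMask)))
  cellA <- sum(cellMask)
  if (cellA == 0) stop("empty cell mask", call. = FALSE)
  cellD <- 100 * sum(transcriptMask & cellMask) / cellA
  nucD <- NA_real_
  if (!is.null(nucleusMask)) {
    stopifnot(is.matrix(nucleusMask),
              identical(dim(nucleusMask), dim(cellMask)))
    nucA <- sum(nucleusMask)
    if (nucA > 0) nucD <- 100 * sum(transcriptMask & nucleusMask) / nucA
  }
  c(density_pct = cellD, nuc_density_pct = nucD)
}

#' Classify phospho-tau inclusion status per cell
#'
#' A cell is inclusion-bearing iff the phospho-tau (AT8) positive area within
#' its cell mask reaches at least \code{minPtauAreaUm2} (inclusive), with
#' positivity defined as intensity strictly above
#' \code{ptauIntensityThreshold}. If the field carries no ptau channel (as in
#' control tissue, where no inclusions occur) every cell is classified
#' FALSE and a warning is emitted.
#'
#' @param seg a \linkS4class{SegmentedField}.
#' @param field the corresponding \linkS4class{FieldImage}.
#' @param ptauIntensityThreshold intensity cut.
#' @param minPtauAreaUm2 minimum AT8-positive area, um^2 (inclusive).
#' @return logical vector, one flag per row of \code{cellData(seg)}.
#' @export
classifyInclusion <- function(seg, field, ptauIntensityThreshold = 0.4,
                              minPtauAreaUm2 = 10) {
  stopifnot(is(seg, "SegmentedField"), is(field, "FieldImage"))
  cells <- seg@cells
  if (!nrow(cells)) return(logical(0))
  if (!hasChannel(field, "ptau")) {
    warning("ptau channel absent; classifying all cells as inclusion-free ",
            "(control-case mode)", call. = FALSE)
    return(rep(FALSE, nrow(cells)))
  }
  ch <- getChannel(field, "ptau")
  n <- max(cells$cell_id)
  posArea <- .areaByLabel(seg@cellLabels, n, ch > ptauIntensityThreshold) *
    field@umPerPx^2
  unname(posArea[cells$cell_id] >= minPtauAreaUm2)
}

#' Quantification parameters
#'
#' Bundles the thresholds and radii used by \code{\link{buildDensityTable}}.
#' Radii are the ROI extension beyond the nucleus per cell type (the paper's
#' "radius length corresponding to the size of cell types"); defaults equal
#' the synthetic generator's cell radius minus its nucleus radius.
#'
#' @param extensionRadiusUm named vector, ROI extension beyond the nucleus
#'   per cell type (um).
#' @param minNucleusAreaUm2,maxNucleusAreaUm2 nucleus area gate (um^2).
#' @param markerIntensityThreshold,minMarkerAreaUm2 cell-typing thresholds.
#' @param transcriptMethod,transcriptFixedThreshold transcript segmentation.
#' @param ptauIntensityThreshold,minPtauAreaUm2 inclusion-calling thresholds.
#' @param keepUntyped,keepBorder retain untyped / border-flagged cells in the
#'   table (both FALSE by default).
#' @return list of class \code{"QuantifyParams"}.
#' @export
quantifyParams <- function(
    extensionRadiusUm = c(neuron = 5, oligodendrocyte = 2, astrocyte = 3.5),
    minNucleusAreaUm2 = 15, maxNucleusAreaUm2 = 150,
    markerIntensityThreshold = 0.4, minMarkerAreaUm2 = 20,
    transcriptMethod = "otsu", transcriptFixedThreshold = NULL,
    ptauIntensityThreshold = 0.4, minPtauAreaUm2 = 10,
    keepUntyped = FALSE, keepBorder = FALSE) {
  p <- list(extensionRadiusUm = extensionRadiusUm,
            minNucleusAreaUm2 = minNucleusAreaUm2,
            maxNucleusAreaUm2 = maxNucleusAreaUm2,
            markerIntensityThreshold = markerIntensityThreshold,
            minMarkerAreaUm2 = minMarkerAreaUm2,
            transcriptMethod = transcriptMethod,
            transcriptFixedThreshold = transcriptFixedThreshold,
            ptauIntensityThreshold = ptauIntensityThreshold,
            minPtauAreaUm2 = minPtauAreaUm2,
            keepUntyped = keepUntyped, keepBorder = keepBorder)
  class(p) <- "QuantifyParams"
  p
}

#' Segment and quantify one field
#'
#' Runs the full per-field chain: nucleus detection, ROI extension by the
#' radius of the field's marker type, marker-based typing, transcript
#' segmentation, inclusion classification, and per-cell whole-cell and
#' nuclear area densities.
#'
#' @param field a \linkS4class{FieldImage}.
#' @param params a \code{\link{quantifyParams}}.
#' @param seg optional pre-built \linkS4class{SegmentedField} (e.g. manually
#'   annotated ROIs); when supplied, nucleus detection, ROI extension and
#'   typing are skipped.
#' @return list: \code{seg} (the \linkS4class{SegmentedField} used) and
#'   \code{records} (data.frame of per-cell rows, all cells, with
#'   \code{border} retained for filtering).
#' @export
quantifyField <- function(field, params = quantifyParams(), seg = NULL) {
  stopifnot(is(field, "FieldImage"))
  if (is.null(seg)) {
    nuc <- detectNuclei(field, params$minNucleusAreaUm2, params$maxNucleusAreaUm2)
    ext <- params$extensionRadiusUm[[field@markerType]]
    if (is.null(ext))
      stop("no extension radius configured for marker type ", field@markerType,
           call. = FALSE)
    seg <- extendRois(nuc, ext, field)
    seg <- callCellType(seg, field,
                        intensityThreshold = params$markerIntensityThreshold,
                        minMarkerAreaUm2 = params$minMarkerAreaUm2)
  }
  cells <- seg@cells
  if (!nrow(cells)) {
    rec <- cbind(data.frame(cell_id = integer(0), field_id = character(0),
                            case_id = character(0), region = character(0),
                            cell_type = character(0), source = character(0),
                            inclusion = logical(0)),
                 data.frame(cell_area_um2 = numeric(0), nuc_area_um2 = numeric(0),
                            mapt_area_um2 = numeric(0),
                            nuc_mapt_area_um2 = numeric(0),
                            density_pct = numeric(0), nuc_density_pct = numeric(0),
                            border = logical(0)))
    return(list(seg = seg, records = rec))
  }
  txMask <- segmentTranscripts(field, params$transcriptMethod,
                               params$transcriptFixedThreshold)
  inclusion <- if (hasChannel(field, "ptau")) {
    classifyInclusion(seg, field, params$ptauIntensityThreshold,
                      params$minPtauAreaUm2)
  } else rep(FALSE, nrow(cells))
  n <- max(cells$cell_id)
  px2 <- field@umPerPx^2
  cellA <- .areaByLabel(seg@cellLabels, n)[cells$cell_id]
  nucA <- .areaByLabel(seg@nucLabels, n)[cells$cell_id]
  cellPos <- .areaByLabel(seg@cellLabels, n, txMask)[cells$cell_id]
  nucPos <- .areaByLabel(seg@nucLabels, n, txMask)[cells$cell_id]
  rec <- data.frame(
    cell_id = cells$cell_id, field_id = field@fieldId, case_id = field@caseId,
    region = field@region, cell_type = cells$cell_type, source = cells$source,
    inclusion = inclusion,
    cell_area_um2 = cellA * px2, nuc_area_um2 = nucA * px2,
    mapt_area_um2 = cellPos * px2, nuc_mapt_area_um2 = nucPos * px2,
    density_pct = 100 * cellPos / cellA,
    nuc_density_pct = ifelse(nucA > 0, 100 * nucPos / nucA, NA_real_),
    border = cells$border,
    stringsAsFactors = FALSE)
  list(seg = seg, records = rec)
}

#' Build a per-cell density table from a set of fields
#'
#' Quantifies every field with \code{\link{quantifyField}}, applies the
#' retention policy (typed, non-border cells by default) and assembles one
#' \linkS4class{DensityTable} with provenance. Deterministic given inputs
#' and parameters.
#'
#' @param fields list of \linkS4class{FieldImage} objects with distinct
#'   \code{fieldId}s.
#' @param params a \code{\link{quantifyParams}}.
#' @param verbose log per-field retention counts.
#' @return a \linkS4class{DensityTable}.
#' @export
buildDensityTable <- function(fields, params = quantifyParams(),
                              verbose = FALSE) {
  if (!length(fields)) stop("empty field list", call. = FALSE)
  ids <- vapply(fields, function(f) paste(f@caseId, f@fieldId, sep = "/"),
                character(1))
  if (anyDuplicated(ids))
    stop("duplicate field ids: ", paste(ids[duplicated(ids)], collapse = ", "),
         call. = FALSE)
  umpp <- vapply(fields, umPerPx, numeric(1))
  if (length(unique(umpp)) > 1L)
    stop("inconsistent um/px across fields", call. = FALSE)
  recs <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    q <- quantifyField(fields[[i]], params)
    rec <- q$records
    nAll <- nrow(rec)
    if (!params$keepBorder) rec <- rec[!rec$border, , drop = FALSE]
    if (!params$keepUntyped) rec <- rec[rec$cell_type != "untyped", , drop = FALSE]
    if (verbose)
      message(sprintf("field %s: %d cells detected, %d retained", ids[i],
                      nAll, nrow(rec)))
    recs[[i]] <- rec
  }
  rec <- do.call(rbind, recs)
  rec$border <- NULL
  rownames(rec) <- NULL
  prov <- list(generator = "buildDensityTable",
               n_fields = length(fields), fields = unname(ids),
               params = unclass(params),
               version = as.character(utils::packageVersion("maptquant")))
  DensityTable(rec, prov)
}
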
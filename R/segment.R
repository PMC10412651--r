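#' Detect nuclei on the DAPI channel
#'
#' Otsu-thresholds the nucleus channel, fills holes, splits touching nuclei
#' by distance-transform watershed, and keeps connected components whose
#' area lies within the given bounds (in square micrometres).
#'
#' A blank channel yields an empty labelling (no error); non-finite pixels
#' are an input error.
#'
#' @param field a \linkS4class{FieldImage}.
#' @param minAreaUm2,maxAreaUm2 retained nucleus area range, um^2.
#' @return integer label matrix (0 = background, 1..n = nuclei, labels
#'   sequential).
#' @export
detectNuclei <- function(field, minAreaUm2 = 15, maxAreaUm2 = 150) {
  stopifnot(is(field, "FieldImage"))
  if (!(minAreaUm2 > 0 && minAreaUm2 < maxAreaUm2))
    stop("need 0 < minAreaUm2 < maxAreaUm2", call. = FALSE)
  ch <- getChannel(field, "nucleus")
  .assertFinite(ch, "nucleus channel")
  H <- nrow(ch); W <- ncol(ch)
  empty <- matrix(0L, H, W)
  rng <- range(ch)
  if (diff(rng) == 0) return(empty)
  th <- EBImage::otsu(EBImage::Image(ch), range = rng)
  bw <- EBImage::fillHull(EBImage::Image(ch > th))
  if (sum(bw) == 0) return(empty)
  labels <- EBImage::watershed(EBImage::distmap(bw), tolerance = 1)
  lab <- matrix(as.integer(EBImage::imageData(labels)), H, W)
  nLab <- max(lab)
  if (nLab == 0L) return(empty)
  areaUm2 <- .areaByLabel(lab, nLab) * field@umPerPx^2
  keep <- which(areaUm2 >= minAreaUm2 & areaUm2 <= maxAreaUm2)
  if (!length(keep)) return(empty)
  remap <- integer(nLab)
  remap[keep] <- seq_along(keep)
  out <- empty
  nz <- lab != 0L
  out[nz] <- remap[lab[nz]]
  out
}

#' Extend nucleus masks into cell regions of interest
#'
#' Dilates every nucleus by a radius corresponding to the size of the cell
#' type under study (converted to pixels, rounded) and resolves overlapping
#' dilations by assigning each contested pixel to the nearest nucleus
#' (region growing from the nucleus seeds; exact ties fall to the lower cell
#' id). Masks are clipped at the field boundary and such cells are flagged
#' \code{border} so they can be excluded from density statistics.
#'
#' @param nucLabels integer nucleus label matrix, e.g. from
#'   \code{\link{detectNuclei}}.
#' @param cellTypeRadiusUm extension radius beyond the nucleus, micrometres
#'   (>= 0; 0 returns the nuclei unchanged as cell masks).
#' @param field the \linkS4class{FieldImage} the labels came from (provides
#'   the pixel size).
#' @return a \linkS4class{SegmentedField} with all cells \code{untyped}.
#' @export
extendRois <- function(nucLabels, cellTypeRadiusUm, field) {
  stopifnot(is(field, "FieldImage"), is.matrix(nucLabels))
  if (!(length(cellTypeRadiusUm) == 1L && is.finite(cellTypeRadiusUm) &&
        cellTypeRadiusUm >= 0))
    stop("cellTypeRadiusUm must be a single number >= 0", call. = FALSE)
  H <- nrow(nucLabels); W <- ncol(nucLabels)
  storage.mode(nucLabels) <- "integer"
  n <- max(nucLabels, 0L)
  rPx <- as.integer(round(cellTypeRadiusUm / field@umPerPx))
  if (n == 0L) {
    cellLab <- nucLabels
  } else if (rPx == 0L) {
    cellLab <- nucLabels
  } else {
    brush <- EBImage::makeBrush(2L * rPx + 1L, shape = "disc")
    mask <- EBImage::dilate(EBImage::Image(nucLabels > 0L), brush)
    # nearest-seed region growing on a flat image = Voronoi partition of the
    # dilated support among nuclei
    prop <- EBImage::propagate(EBImage::Image(matrix(0, H, W)),
                               seeds = EBImage::Image(nucLabels),
                               mask = mask, lambda = 1)
    cellLab <- matrix(as.integer(EBImage::imageData(prop)), H, W)
    nz <- nucLabels != 0L
    cellLab[nz] <- nucLabels[nz]
  }
  .buildSegmentedField(nucLabels, cellLab, field@umPerPx)
}

.buildSegmentedField <- function(nucLabels, cellLab, umPerPx,
                                 cellType = NULL, source = "auto") {
  H <- nrow(nucLabels); W <- ncol(nucLabels)
  n <- max(nucLabels, 0L)
  if (n == 0L) {
    cells <- data.frame(cell_id = integer(0), centroid_row = numeric(0),
                        centroid_col = numeric(0), nucleus_area_px = integer(0),
                        cell_area_px = integer(0), cell_type = character(0),
                        source = character(0), border = logical(0),
                        stringsAsFactors = FALSE)
  } else {
    idx <- which(nucLabels != 0L)
    lab <- nucLabels[idx]
    rows <- ((idx - 1L) %% H) + 1L
    cols <- ((idx - 1L) %/% H) + 1L
    centR <- vapply(split(rows, lab), mean, numeric(1))
    centC <- vapply(split(cols, lab), mean, numeric(1))
    ids <- as.integer(names(centR))
    nucArea <- .areaByLabel(nucLabels, n)
    cellArea <- .areaByLabel(cellLab, n)
    borderLabs <- unique(c(cellLab[1, ], cellLab[H, ], cellLab[, 1], cellLab[, W]))
    cells <- data.frame(
      cell_id = ids,
      centroid_row = unname(centR), centroid_col = unname(centC),
      nucleus_area_px = nucArea[ids], cell_area_px = cellArea[ids],
      cell_type = if (is.null(cellType)) "untyped" else cellType,
      source = source,
      border = ids %in% borderLabs,
      stringsAsFactors = FALSE)
    cells <- cells[order(cells$cell_id), , drop = FALSE]
    rownames(cells) <- NULL
  }
  new("SegmentedField", nucLabels = nucLabels, cellLabels = cellLab,
      cells = cells, umPerPx = umPerPx)
}

#' Call cell types from the marker channel
#'
#' A cell is called the marker's type if and only if the marker-positive area
#' within its cell mask (pixels with intensity strictly above
#' \code{intensityThreshold}) reaches at least \code{minMarkerAreaUm2}
#' (inclusive); otherwise it stays \code{untyped}. Thresholding on both
#' intensity and area suppresses false typing from neighbouring cells'
#' processes. One marker is hybridized per section, so typing is binary per
#' field.
#'
#' @param seg a \linkS4class{SegmentedField}.
#' @param field the corresponding \linkS4class{FieldImage}.
#' @param markerRole channel role holding the marker signal.
#' @param intensityThreshold marker intensity cut (> 0, strict comparison).
#' @param minMarkerAreaUm2 minimum marker-positive area, um^2 (inclusive).
#' @param cellType label to assign (defaults to the field's declared marker
#'   type).
#' @return the \linkS4class{SegmentedField} with \code{cell_type} updated.
#' @export
callCellType <- function(seg, field, markerRole = "marker",
                         intensityThreshold = 0.4, minMarkerAreaUm2 = 20,
                         cellType = field@markerType) {
  stopifnot(is(seg, "SegmentedField"), is(field, "FieldImage"))
  if (!hasChannel(field, markerRole))
    stop(sprintf("configuration error: marker channel '%s' absent", markerRole),
         call. = FALSE)
  if (!(intensityThreshold > 0) || !(minMarkerAreaUm2 > 0))
    stop("thresholds must be > 0", call. = FALSE)
  ch <- getChannel(field, markerRole)
  cells <- seg@cells
  if (!nrow(cells)) return(seg)
  n <- max(cells$cell_id)
  pos <- ch > intensityThreshold
  posArea <- .areaByLabel(seg@cellLabels, n, pos) * field@umPerPx^2
  typed <- posArea[cells$cell_id] >= minMarkerAreaUm2
  cells$cell_type <- ifelse(typed, cellType, "untyped")
  seg@cells <- cells
  seg
}

#' Import manually annotated cell ROIs
#'
#' Reads a polygon-per-cell CSV with columns \code{roi_id}, \code{role}
#' (\code{cell} or \code{nucleus}), \code{vertex_index}, \code{x_px},
#' \code{y_px} (0-based pixel coordinates, x = column, y = row) and
#' rasterizes each polygon into pixel masks. When a nucleus polygon is
#' provided it is used as the nucleus mask (intersected with the cell mask);
#' otherwise the cell polygon doubles as the nucleus mask. Intended for cell
#' populations annotated by hand because of their distinctive morphology
#' (e.g. nigral neurons, Purkinje cells).
#'
#' @param path CSV file path.
#' @param field the \linkS4class{FieldImage} the coordinates refer to.
#' @param cellType type label to assign to the imported cells.
#' @return a \linkS4class{SegmentedField} with \code{source = "manual"}.
#' @export
importManualRois <- function(path, field, cellType = "neuron") {
  stopifnot(is(field, "FieldImage"))
  if (!file.exists(path)) stop("manual ROI file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  H <- nrow(getChannel(field, "nucleus")); W <- ncol(getChannel(field, "nucleus"))
  nucLabels <- matrix(0L, H, W); cellLab <- matrix(0L, H, W)
  if (!nrow(df))
    return(.buildSegmentedField(nucLabels, cellLab, field@umPerPx,
                                source = "manual"))
  need <- c("roi_id", "role", "vertex_index", "x_px", "y_px")
  if (!all(need %in% names(df)))
    stop("manual ROI file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(df$role %in% c("cell", "nucleus")))
    stop("ROI role must be 'cell' or 'nucleus'", call. = FALSE)
  ids <- sort(unique(df$roi_id))
  for (k in seq_along(ids)) {
    sub <- df[df$roi_id == ids[k], , drop = FALSE]
    for (role in unique(sub$role)) {
      poly <- sub[sub$role == role, , drop = FALSE]
      poly <- poly[order(poly$vertex_index), , drop = FALSE]
      if (nrow(poly) < 3)
        stop(sprintf("ROI '%s' (%s): polygon needs >= 3 vertices", ids[k], role),
             call. = FALSE)
      if (any(poly$x_px < 0 | poly$x_px > W - 1 | poly$y_px < 0 | poly$y_px > H - 1))
        stop(sprintf("ROI '%s' (%s): polygon extends outside the image", ids[k], role),
             call. = FALSE)
      if (.polygonSelfIntersects(poly$x_px, poly$y_px))
        stop(sprintf("ROI '%s' (%s): polygon is self-intersecting (rows %s)",
                     ids[k], role,
                     paste(range(which(df$roi_id == ids[k])), collapse = "-")),
             call. = FALSE)
    }
    cellPoly <- sub[sub$role == "cell", , drop = FALSE]
    if (!nrow(cellPoly))
      stop(sprintf("ROI '%s' has no 'cell' polygon", ids[k]), call. = FALSE)
    cellPoly <- cellPoly[order(cellPoly$vertex_index), , drop = FALSE]
    cIdx <- .rasterizePolygon(cellPoly$x_px, cellPoly$y_px, H, W)
    if (!length(cIdx))
      stop(sprintf("ROI '%s' rasterizes to an empty mask", ids[k]), call. = FALSE)
    nucPoly <- sub[sub$role == "nucleus", , drop = FALSE]
    if (nrow(nucPoly)) {
      nucPoly <- nucPoly[order(nucPoly$vertex_index), , drop = FALSE]
      nIdx <- intersect(.rasterizePolygon(nucPoly$x_px, nucPoly$y_px, H, W), cIdx)
      if (!length(nIdx))
        stop(sprintf("ROI '%s': nucleus polygon does not overlap the cell polygon",
                     ids[k]), call. = FALSE)
    } else nIdx <- cIdx
    cellLab[cIdx] <- k
    nucLabels[nIdx] <- k
  }
  # later ROIs win contested pixels; re-sync nuclei onto surviving cell pixels
  nucLabels[nucLabels != cellLab & nucLabels != 0L] <- 0L
  .buildSegmentedField(nucLabels, cellLab, field@umPerPx,
                       cellType = cellType, source = "manual")
}
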
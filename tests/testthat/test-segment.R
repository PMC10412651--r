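# Nucleus detection, ROI extension, cell typing and manual ROI import.

test_that("a blank nucleus channel yields no nuclei", {
  f <- makeField(matrix(0, 64, 64))
  lab <- detectNuclei(f)
  expect_identical(sum(lab), 0L)
  expect_error(detectNuclei(makeField(matrix(NaN, 8, 8))), "non-finite")
})

test_that("a single disk is detected with near-analytic area", {
  # radius 4 um = 8 px at 0.5 um/px; area pi * 16 um^2
  nuc <- stampDisk(matrix(0.05, 128, 128), 64, 64, 8, 0.9)
  f <- makeField(nuc)
  lab <- detectNuclei(f)
  expect_identical(max(lab), 1L)
  areaUm2 <- sum(lab == 1L) * 0.5^2
  expect_lt(abs(areaUm2 - pi * 16) / (pi * 16), 0.10)
})

test_that("well-separated disks are detected individually with true centroids", {
  nuc <- stampDisk(matrix(0.05, 128, 128), 40, 40, 8, 0.9)
  nuc <- stampDisk(nuc, 90, 90, 8, 0.9)
  f <- makeField(nuc)
  seg <- extendRois(detectNuclei(f), 0, f)
  cells <- cellData(seg)
  expect_identical(nrow(cells), 2L)
  got <- cells[order(cells$centroid_row), ]
  expect_lt(max(abs(got$centroid_row - c(40, 90))), 1)
  expect_lt(max(abs(got$centroid_col - c(40, 90))), 1)
})

test_that("zero extension radius returns the nuclei as cell masks", {
  sim <- generateField(tinyFieldConfig(seed = 21L))
  nuc <- detectNuclei(sim$field)
  seg <- extendRois(nuc, 0, sim$field)
  expect_identical(cellLabels(seg), nucleusLabels(seg))
})

test_that("dilation reaches the analytic cell area", {
  # nucleus r = 4 um, extension 5 um -> cell area ~ pi * 9^2 um^2
  nuc <- stampDisk(matrix(0.05, 128, 128), 64, 64, 8, 0.9)
  f <- makeField(nuc)
  seg <- extendRois(detectNuclei(f), 5, f)
  areaUm2 <- cellData(seg)$cell_area_px * 0.5^2
  expect_lt(abs(areaUm2 - pi * 81) / (pi * 81), 0.10)
})

test_that("overlapping dilations partition the union without loss", {
  nuc <- stampDisk(matrix(0.05, 128, 128), 60, 50, 6, 0.9)
  nuc <- stampDisk(nuc, 60, 78, 6, 0.9)
  f <- makeField(nuc)
  lab <- detectNuclei(f)
  seg <- extendRois(lab, 6, f)   # 12 px extension, dilations overlap
  cl <- cellLabels(seg)
  # union equals the unrestricted dilation of all nuclei
  brush <- EBImage::makeBrush(2L * 12L + 1L, "disc")
  want <- EBImage::imageData(EBImage::dilate(EBImage::Image(lab > 0), brush)) > 0
  expect_identical(cl > 0, matrix(want, nrow(lab), ncol(lab)))
  # and the two cells are disjoint by construction of a label matrix,
  # with every contested pixel nearer its own nucleus than the other one
  cells <- cellData(seg)
  for (id in cells$cell_id) {
    own <- which(cl == id, arr.ind = TRUE)
    me <- cells[cells$cell_id == id, ]
    other <- cells[cells$cell_id != id, ]
    dOwn <- sqrt((own[, 1] - me$centroid_row)^2 + (own[, 2] - me$centroid_col)^2)
    dOth <- sqrt((own[, 1] - other$centroid_row)^2 + (own[, 2] - other$centroid_col)^2)
    expect_true(all(dOwn <= dOth + 1.5))  # 1.5 px slack for geodesic rounding
  }
})

test_that("typing requires both marker intensity and area, inclusively", {
  nuc <- stampDisk(matrix(0.05, 100, 100), 50, 50, 6, 0.9)
  f0 <- makeField(nuc, umPerPx = 1)   # 1 um/px: areas in px == um^2
  seg <- extendRois(detectNuclei(f0), 5, f0)

  # all-zero marker -> untyped
  seg0 <- callCellType(seg, f0, minMarkerAreaUm2 = 20)
  expect_identical(cellData(seg0)$cell_type, "untyped")

  # exactly 20 marker-positive px inside the cell at min area 20 -> typed
  marker <- matrix(0, 100, 100)
  inCell <- which(cellLabels(seg) == 1L)
  marker[inCell[1:20]] <- 0.9
  f1 <- makeField(nuc, marker = marker, umPerPx = 1)
  seg1 <- callCellType(seg, f1, minMarkerAreaUm2 = 20)
  expect_identical(cellData(seg1)$cell_type, "neuron")
  # one pixel fewer -> untyped
  marker[inCell[20]] <- 0
  f2 <- makeField(nuc, marker = marker, umPerPx = 1)
  seg2 <- callCellType(seg, f2, minMarkerAreaUm2 = 20)
  expect_identical(cellData(seg2)$cell_type, "untyped")

  expect_error(callCellType(seg, f0, markerRole = "nope"), "configuration error")
})

test_that("raising the intensity threshold never types an untyped cell", {
  sim <- generateField(tinyFieldConfig(seed = 22L))
  nuc <- detectNuclei(sim$field)
  seg <- extendRois(nuc, 5, sim$field)
  prevTyped <- NULL
  for (th in c(0.2, 0.35, 0.5, 0.7, 0.9)) {
    typed <- cellData(callCellType(seg, sim$field,
                                   intensityThreshold = th))$cell_type != "untyped"
    if (!is.null(prevTyped)) expect_true(all(typed <= prevTyped))
    prevTyped <- typed
  }
})

test_that("auto typing recovers ground-truth types on synthetic fields", {
  hits <- 0L; total <- 0L
  for (seed in 23:24) {
    sim <- generateField(tinyFieldConfig(seed = seed))
    q <- quantifyField(sim$field, quantifyParams(keepUntyped = TRUE,
                                                 keepBorder = TRUE))
    rec <- matchToTruth(q$records, q$seg, sim$truth)
    rec <- rec[rec$truth_id > 0, ]
    truthIsMarker <- truthCells(sim$truth)$cell_type[rec$truth_id] == "neuron"
    callIsMarker <- rec$cell_type == "neuron"
    hits <- hits + sum(truthIsMarker == callIsMarker)
    total <- total + nrow(rec)
  }
  expect_gte(hits / total, 0.95)
})

test_that("pixel-level results are covariant under micrometre rescaling", {
  nuc <- stampDisk(matrix(0.05, 120, 120), 60, 60, 10, 0.9)
  fA <- makeField(nuc, umPerPx = 0.5)
  fB <- makeField(nuc, umPerPx = 1.0)
  labA <- detectNuclei(fA, minAreaUm2 = 15, maxAreaUm2 = 150)
  labB <- detectNuclei(fB, minAreaUm2 = 15 * 4, maxAreaUm2 = 150 * 4)
  expect_identical(labA, labB)
  segA <- extendRois(labA, 6, fA)
  segB <- extendRois(labB, 12, fB)
  expect_identical(cellLabels(segA), cellLabels(segB))
})

test_that("manual ROI polygons rasterize, round-trip and fail loudly", {
  f <- makeField(matrix(0, 64, 64))

  empty <- tempfile(fileext = ".csv")
  writeManualRois(data.frame(roi_id = character(0), role = character(0),
                             vertex_index = integer(0), x_px = numeric(0),
                             y_px = numeric(0)), empty)
  expect_identical(nrow(cellData(importManualRois(empty, f))), 0L)

  # a 10 x 10 px square: vertices span columns 5..14, rows 8..17 (0-based)
  sq <- data.frame(roi_id = "r1", role = "cell", vertex_index = 1:4,
                   x_px = c(5, 14, 14, 5), y_px = c(8, 8, 17, 17))
  p <- tempfile(fileext = ".csv")
  writeManualRois(sq, p)
  seg <- importManualRois(p, f)
  expect_identical(sum(cellLabels(seg) == 1L), 100L)
  expect_identical(cellData(seg)$source, "manual")
  # nucleus defaults to the cell polygon
  expect_identical(nucleusLabels(seg), cellLabels(seg))

  # round-trip: write, read, identical mask
  p2 <- tempfile(fileext = ".csv")
  writeManualRois(sq, p2)
  expect_identical(cellLabels(importManualRois(p2, f)), cellLabels(seg))

  # self-intersecting bowtie names the offending ROI
  bow <- data.frame(roi_id = "bad", role = "cell", vertex_index = 1:4,
                    x_px = c(5, 20, 5, 20), y_px = c(5, 20, 20, 5))
  p3 <- tempfile(fileext = ".csv")
  writeManualRois(bow, p3)
  expect_error(importManualRois(p3, f), "self-intersecting")

  # polygon outside the image
  outp <- data.frame(roi_id = "r2", role = "cell", vertex_index = 1:4,
                     x_px = c(50, 80, 80, 50), y_px = c(5, 5, 15, 15))
  p4 <- tempfile(fileext = ".csv")
  writeManualRois(outp, p4)
  expect_error(importManualRois(p4, f), "outside")
})
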
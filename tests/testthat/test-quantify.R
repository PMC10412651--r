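# Transcript segmentation, area densities, inclusion calling and table
# assembly.

test_that("fixed-threshold segmentation handles empty and boundary cases", {
  f <- makeField(matrix(0, 32, 32), transcript = matrix(0, 32, 32))
  expect_identical(sum(segmentTranscripts(f, "fixed", 10)), 0L)

  tx <- matrix(0.3, 32, 32)
  f2 <- makeField(matrix(0, 32, 32), transcript = tx)
  expect_identical(sum(segmentTranscripts(f2, "fixed", 0.5)), 0L)  # above max
  expect_error(segmentTranscripts(f2, "otsu"), "fixed")            # degenerate
  expect_error(segmentTranscripts(f2, "fixed"), "fixedThreshold")
})

test_that("area density follows the mask-ratio definition", {
  cell <- matrix(FALSE, 20, 20); cell[5:14, 5:14] <- TRUE   # 100 px
  nuc <- matrix(FALSE, 20, 20); nuc[8:11, 8:11] <- TRUE     # 16 px

  full <- matrix(TRUE, 20, 20)
  expect_equal(unname(areaDensity(cell, nuc, full)), c(100, 100))

  half <- matrix(FALSE, 20, 20); half[5:14, 5:9] <- TRUE    # half the cell
  expect_equal(unname(areaDensity(cell, nuc, half))[1], 50)

  # empty nucleus: nuclear density is missing, not zero
  expect_true(is.na(areaDensity(cell, matrix(FALSE, 20, 20), half)[2]))
  expect_error(areaDensity(matrix(FALSE, 20, 20), NULL, half), "empty cell")
})

test_that("a Bernoulli transcript mask recovers its rate", {
  H <- 40
  cell <- matrix(FALSE, H, H)
  cell[1:25, 1:40] <- TRUE                                # 1000 px
  stopifnot(sum(cell) == 1000)
  set.seed(42)
  p <- 0.3
  tx <- matrix(runif(H * H) < p, H, H)
  d <- areaDensity(cell, NULL, tx)[1]
  tol <- 3 * 100 * sqrt(p * (1 - p) / 1000)
  expect_lt(abs(d - 100 * p), tol)
})

test_that("whole-cell transcript area splits exactly into nuclear + cytoplasmic", {
  sim <- generateField(tinyFieldConfig(seed = 31L))
  q <- quantifyField(sim$field, quantifyParams(keepUntyped = TRUE,
                                               keepBorder = TRUE))
  tx <- segmentTranscripts(sim$field)
  nl <- nucleusLabels(q$seg); cl <- cellLabels(q$seg)
  for (id in cellData(q$seg)$cell_id) {
    whole <- sum(tx & cl == id)
    nuclear <- sum(tx & nl == id)
    cyto <- sum(tx & cl == id & nl != id)
    expect_identical(whole, nuclear + cyto)
  }
  rec <- q$records
  expect_true(all(rec$density_pct >= 0 & rec$density_pct <= 100))
  expect_true(all(rec$nuc_mapt_area_um2 <= rec$mapt_area_um2 + 1e-9))
})

test_that("inclusion calling is inclusive at the area boundary", {
  nuc <- stampDisk(matrix(0.05, 100, 100), 50, 50, 6, 0.9)
  f0 <- makeField(nuc, ptau = matrix(0, 100, 100), umPerPx = 1)
  seg <- extendRois(detectNuclei(f0), 5, f0)
  expect_false(any(classifyInclusion(seg, f0)))

  ptau <- matrix(0, 100, 100)
  inCell <- which(cellLabels(seg) == 1L)
  ptau[inCell[1:10]] <- 0.9
  f1 <- makeField(nuc, ptau = ptau, umPerPx = 1)
  expect_true(classifyInclusion(seg, f1, minPtauAreaUm2 = 10))
  ptau[inCell[10]] <- 0
  f2 <- makeField(nuc, ptau = ptau, umPerPx = 1)
  expect_false(classifyInclusion(seg, f2, minPtauAreaUm2 = 10))

  # control-case mode: no ptau channel -> all FALSE with a warning
  f3 <- makeField(nuc, umPerPx = 1)
  expect_warning(flags <- classifyInclusion(seg, f3), "control")
  expect_false(any(flags))
})

test_that("inclusion recovery on synthetic fields is accurate", {
  hits <- 0L; total <- 0L
  for (seed in 32:33) {
    sim <- generateField(tinyFieldConfig(seed = seed,
      inclusionFraction = c(neuron = 0.3, oligodendrocyte = 0.3,
                            astrocyte = 0.3)))
    q <- quantifyField(sim$field, quantifyParams(keepUntyped = TRUE,
                                                 keepBorder = TRUE))
    rec <- matchToTruth(q$records, q$seg, sim$truth)
    rec <- rec[rec$truth_id > 0, ]
    truthFlag <- truthCells(sim$truth)$inclusion[rec$truth_id]
    hits <- hits + sum(rec$inclusion == truthFlag)
    total <- total + nrow(rec)
  }
  expect_gte(hits / total, 0.95)
})

test_that("density tables are deterministic, validated and complete", {
  sims <- lapply(41:42, function(s) generateField(tinyFieldConfig(seed = s),
                                                  fieldId = paste0("f", s)))
  fields <- lapply(sims, `[[`, "field")
  dt1 <- buildDensityTable(fields)
  dt2 <- buildDensityTable(fields)
  expect_identical(records(dt1), records(dt2))
  expect_true(all(c("cell_id", "field_id", "case_id", "region", "cell_type",
                    "source", "inclusion", "cell_area_um2", "nuc_area_um2",
                    "mapt_area_um2", "nuc_mapt_area_um2", "density_pct",
                    "nuc_density_pct") %in% names(records(dt1))))

  # row count = typed, non-border cells across fields
  nExpected <- 0L
  for (s in sims) {
    q <- quantifyField(s$field, quantifyParams(keepUntyped = TRUE,
                                               keepBorder = TRUE))
    nExpected <- nExpected + sum(q$records$cell_type != "untyped" &
                                   !q$records$border)
  }
  expect_identical(nrow(records(dt1)), nExpected)

  expect_error(buildDensityTable(list()), "empty")
  expect_error(buildDensityTable(list(fields[[1]], fields[[1]])), "duplicate")
})

test_that("a field with no detectable cells yields an empty table with provenance", {
  blank <- makeField(matrix(0, 64, 64), transcript = matrix(0.1, 64, 64))
  dt <- buildDensityTable(list(blank),
                          quantifyParams(transcriptMethod = "fixed",
                                         transcriptFixedThreshold = 0.5))
  expect_identical(nrow(records(dt)), 0L)
  expect_identical(provenance(dt)$n_fields, 1L)
})

test_that("measured densities track ground truth on full synthetic fields", {
  errs <- c()
  for (seed in 51:52) {
    sim <- generateField(synthFieldConfig(seed = seed))
    q <- quantifyField(sim$field)
    rec <- matchToTruth(q$records, q$seg, sim$truth)
    rec <- rec[rec$truth_id > 0 & !rec$border & rec$cell_type != "untyped", ]
    errs <- c(errs, abs(rec$density_pct -
                          truthCells(sim$truth)$true_density_pct[rec$truth_id]))
  }
  expect_gt(length(errs), 30)
  expect_lte(median(errs), 2)
})
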
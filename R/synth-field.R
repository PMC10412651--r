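#' Lognormal parameters from a target mean
#'
#' Convenience for specifying per-cell density laws by their natural-scale
#' mean: returns \code{c(meanlog, sdlog)} such that a lognormal with these
#' parameters has expectation \code{mean}. With \code{sdlog = 0} the law is
#' degenerate at \code{mean}, which is how a fixed true density is forced.
#'
#' @param mean target mean on the natural (percent) scale; must be > 0.
#' @param sdlog log-scale standard deviation (>= 0).
#' @return named numeric vector \code{c(meanlog, sdlog)}.
#' @examples
#' p <- lognormalFromMean(7.2, 0.8)
#' exp(p["meanlog"] + p["sdlog"]^2 / 2)  # 7.2
#' @export
lognormalFromMean <- function(mean, sdlog) {
  stopifnot(is.finite(mean), mean > 0, is.finite(sdlog), sdlog >= 0)
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Configuration for the synthetic multiplex-FISH field generator
#'
#' Defines the study conditions the generator emulates: how many cells of
#' each type are placed, their nucleus and whole-cell radii, the lognormal
#' law of true per-cell transcript area density stratified by inclusion
#' status, the fraction of inclusion-bearing cells, punctum geometry, and the
#' imaging model (signal amplitude, background, PSF blur, noise) on a [0, 1]
#' intensity scale.
#'
#' Default density laws use the pooled means reported for human tissue
#' (neurons 7.2\%, glia 3.1\%) with a heavy-tailed lognormal spread
#' (sdlog 0.8), and an elevated mean in inclusion-bearing oligodendrocytes
#' (coiled bodies), matching the qualitative structure of the tissue data.
#'
#' @param fieldSize integer c(rows, cols) in pixels.
#' @param umPerPx physical pixel size, micrometres per pixel.
#' @param cellsPerType named integer vector of cells to place per type.
#' @param nucleusRadiusUm,cellRadiusUm named numeric vectors (micrometres);
#'   cell radius is the full radius of the cell disk, nucleus inside it.
#' @param densityLaw nested list: \code{densityLaw[[type]]$noninclusion} and
#'   \code{$inclusion}, each \code{c(meanlog, sdlog)} of the true area-density
#'   lognormal (percent scale, clipped to [0, 100]).
#' @param inclusionFraction named vector in [0, 1]: probability a cell of each
#'   type bears a phospho-tau inclusion.
#' @param punctaSizeUm range (min, max) of punctum diameters, micrometres.
#' @param clusterProb probability a punctum seeds a small confluent cluster
#'   (2--5 overlapping puncta), mimicking transcripts observed singly or in
#'   clusters.
#' @param bgPunctaPerUm2 rate of spurious background puncta outside all cells
#'   (per square micrometre; 0 disables).
#' @param backgroundLevel,signalAmplitude,noiseSd,psfSigmaPx imaging model:
#'   background intensity, added signal amplitude, Gaussian read-noise SD and
#'   Gaussian PSF sigma in pixels.
#' @param markerType cell type labelled by this field's marker channel (the
#'   assay hybridizes one cell-type probe per section, so typing is binary
#'   per field).
#' @param seed integer RNG seed; the generator uses one global stream seeded
#'   from this value, with per-cell draws in deterministic placement order.
#' @return validated config (list with class \code{"SynthFieldConfig"}).
#' @export
synthFieldConfig <- function(
    fieldSize = c(768L, 768L),
    umPerPx = 0.5,
    cellsPerType = c(neuron = 35L, oligodendrocyte = 35L, astrocyte = 35L),
    nucleusRadiusUm = c(neuron = 5, oligodendrocyte = 3, astrocyte = 3.5),
    cellRadiusUm = c(neuron = 10, oligodendrocyte = 5, astrocyte = 7),
    densityLaw = list(
      neuron = list(noninclusion = lognormalFromMean(7.2, 0.8),
                    inclusion = lognormalFromMean(7.2, 0.8)),
      oligodendrocyte = list(noninclusion = lognormalFromMean(3.1, 0.8),
                             inclusion = lognormalFromMean(4.65, 0.8)),
      astrocyte = list(noninclusion = lognormalFromMean(3.1, 0.8),
                       inclusion = lognormalFromMean(3.1, 0.8))),
    inclusionFraction = c(neuron = 0.1, oligodendrocyte = 0.1, astrocyte = 0.1),
    punctaSizeUm = c(0.5, 1.0),
    clusterProb = 0.3,
    bgPunctaPerUm2 = 0,
    backgroundLevel = 0.08,
    signalAmplitude = 0.8,
    noiseSd = 0.03,
    psfSigmaPx = 0.5,
    markerType = "neuron",
    seed = 1L) {
  cfg <- list(fieldSize = as.integer(fieldSize), umPerPx = umPerPx,
              cellsPerType = cellsPerType, nucleusRadiusUm = nucleusRadiusUm,
              cellRadiusUm = cellRadiusUm, densityLaw = densityLaw,
              inclusionFraction = inclusionFraction,
              punctaSizeUm = punctaSizeUm, clusterProb = clusterProb,
              bgPunctaPerUm2 = bgPunctaPerUm2,
              backgroundLevel = backgroundLevel,
              signalAmplitude = signalAmplitude, noiseSd = noiseSd,
              psfSigmaPx = psfSigmaPx, markerType = markerType,
              seed = as.integer(seed))
  class(cfg) <- "SynthFieldConfig"
  .validateSynthFieldConfig(cfg)
  cfg
}

.validateSynthFieldConfig <- function(cfg) {
  fail <- function(msg) stop("invalid SynthFieldConfig: ", msg, call. = FALSE)
  if (length(cfg$fieldSize) != 2L || any(cfg$fieldSize < 16L))
    fail("fieldSize must be two integers >= 16")
  if (!is.finite(cfg$umPerPx) || cfg$umPerPx <= 0)
    fail("umPerPx must be positive")
  types <- names(cfg$cellsPerType)
  if (is.null(types) || any(!nzchar(types))) fail("cellsPerType must be named")
  if (any(cfg$cellsPerType < 0)) fail("cell counts must be >= 0")
  for (field in c("nucleusRadiusUm", "cellRadiusUm", "inclusionFraction")) {
    if (!all(types %in% names(cfg[[field]])))
      fail(sprintf("%s must cover every cell type", field))
  }
  if (any(cfg$nucleusRadiusUm[types] <= 0) || any(cfg$cellRadiusUm[types] <= 0))
    fail("all radii must be > 0")
  if (any(cfg$cellRadiusUm[types] < cfg$nucleusRadiusUm[types]))
    fail("cell radius must be >= nucleus radius for every type")
  if (any(cfg$inclusionFraction[types] < 0 | cfg$inclusionFraction[types] > 1))
    fail("inclusionFraction must lie in [0, 1]")
  for (ty in types) {
    law <- cfg$densityLaw[[ty]]
    if (is.null(law$noninclusion) || is.null(law$inclusion))
      fail(sprintf("densityLaw for '%s' needs noninclusion and inclusion entries", ty))
    for (st in c("noninclusion", "inclusion")) {
      p <- law[[st]]
      # meanlog = -Inf encodes a degenerate 0% law; +Inf/NA are invalid
      if (length(p) != 2L || anyNA(p) || p[["meanlog"]] == Inf ||
          !is.finite(p[["sdlog"]]) || p[["sdlog"]] < 0)
        fail(sprintf("densityLaw$%s$%s must be c(meanlog < Inf, sdlog >= 0)", ty, st))
    }
  }
  if (length(cfg$punctaSizeUm) != 2L || any(cfg$punctaSizeUm <= 0) ||
      cfg$punctaSizeUm[1] > cfg$punctaSizeUm[2])
    fail("punctaSizeUm must be an increasing positive range")
  if (cfg$clusterProb < 0 || cfg$clusterProb > 1)
    fail("clusterProb must lie in [0, 1]")
  if (cfg$bgPunctaPerUm2 < 0) fail("bgPunctaPerUm2 must be >= 0")
  if (cfg$noiseSd < 0) fail("noiseSd must be >= 0")
  if (cfg$psfSigmaPx < 0) fail("psfSigmaPx must be >= 0")
  if (!cfg$markerType %in% types)
    fail("markerType must be one of the configured cell types")
  if (!is.finite(cfg$seed)) fail("seed must be an integer")
  invisible(cfg)
}

# Draw a clipped-lognormal true density (percent) for one (type, status).
.drawDensity <- function(cfg, type, inclusion) {
  p <- cfg$densityLaw[[type]][[if (inclusion) "inclusion" else "noninclusion"]]
  d <- if (p[["sdlog"]] == 0) exp(p[["meanlog"]])
       else stats::rlnorm(1, p[["meanlog"]], p[["sdlog"]])
  min(100, max(0, d))
}

# Stamp puncta inside one cell mask until `target` pixels are positive; the
# final stamp is trimmed so the realized count equals `target` exactly.
.stampTranscripts <- function(mask, cellIdx, target, cfg, H, W) {
  if (target <= 0L) return(mask)
  rPxRange <- cfg$punctaSizeUm / 2 / cfg$umPerPx
  have <- sum(mask[cellIdx])
  guard <- 0L
  maxIter <- 200L + 50L * target
  inCell <- logical(H * W)
  inCell[cellIdx] <- TRUE
  while (have < target) {
    guard <- guard + 1L
    if (guard > maxIter)
      stop("transcript stamping failed to reach target density", call. = FALSE)
    ctr <- cellIdx[sample.int(length(cellIdx), 1L)]
    row <- ((ctr - 1L) %% H) + 1L
    col <- ((ctr - 1L) %/% H) + 1L
    nPuncta <- if (stats::runif(1) < cfg$clusterProb) sample(2:5, 1L) else 1L
    lin <- integer(0)
    for (k in seq_len(nPuncta)) {
      r <- stats::runif(1, rPxRange[1], rPxRange[2])
      jr <- if (k == 1L) 0L else as.integer(round(stats::runif(1, -2 * r, 2 * r)))
      jc <- if (k == 1L) 0L else as.integer(round(stats::runif(1, -2 * r, 2 * r)))
      lin <- c(lin, .diskIndices(row + jr, col + jc, r, H, W))
    }
    lin <- unique(lin)
    lin <- lin[inCell[lin] & !mask[lin]]
    need <- target - have
    if (length(lin) > need) lin <- sample(lin, need)
    mask[lin] <- TRUE
    have <- have + length(lin)
  }
  mask
}

.blurNoiseClip <- function(img, cfg) {
  if (cfg$psfSigmaPx > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = cfg$psfSigmaPx))
  if (cfg$noiseSd > 0)
    img <- img + stats::rnorm(length(img), 0, cfg$noiseSd)
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Generate a synthetic multiplex-FISH field with ground truth
#'
#' Places disk-shaped cells (nucleus disk inside a larger cell disk) without
#' nucleus overlap, draws each cell's true transcript area density from the
#' configured clipped-lognormal law, realizes it by stamping puncta -- singly
#' or in small confluent clusters -- inside the cell mask until the
#' transcript-positive pixel fraction matches the drawn density exactly (to
#' one pixel), and renders four channels (nucleus, marker, transcript,
#' phospho-tau) through a simple imaging model (PSF blur + Gaussian noise).
#' The phospho-tau channel is bright only inside inclusion-flagged cells.
#'
#' Deterministic given the config (which contains the seed); the caller's RNG
#' state is left untouched.
#'
#' @param config a \code{\link{synthFieldConfig}}.
#' @param fieldId,caseId,region identifiers for the resulting field.
#' @return list with elements \code{field} (\linkS4class{FieldImage}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' cfg <- synthFieldConfig(fieldSize = c(128L, 128L),
#'                         cellsPerType = c(neuron = 3L), seed = 7L)
#' out <- generateField(cfg)
#' truthCells(out$truth)
#' @export
generateField <- function(config, fieldId = "field1", caseId = "case1",
                          region = "frontal cortex") {
  .validateSynthFieldConfig(config)
  .withSeed(config$seed, {
    H <- config$fieldSize[1]; W <- config$fieldSize[2]
    types <- names(config$cellsPerType)
    typeOf <- rep(types, times = config$cellsPerType)
    n <- length(typeOf)

    # --- placement: reject-sample nucleus centres, no nucleus overlap ---
    rNucPx <- config$nucleusRadiusUm[typeOf] / config$umPerPx
    rCellPx <- config$cellRadiusUm[typeOf] / config$umPerPx
    ctrRow <- ctrCol <- numeric(n)
    maxRetries <- 2000L
    for (i in seq_len(n)) {
      margin <- ceiling(rNucPx[i]) + 2L
      ok <- FALSE
      for (try in seq_len(maxRetries)) {
        rr <- sample.int(H - 2L * margin, 1L) + margin
        cc <- sample.int(W - 2L * margin, 1L) + margin
        if (i == 1L) { ok <- TRUE }
        else {
          prev <- seq_len(i - 1L)
          minSep <- rNucPx[i] + rNucPx[prev] + 3
          ok <- all((ctrRow[prev] - rr)^2 + (ctrCol[prev] - cc)^2 > minSep^2)
        }
        if (ok) { ctrRow[i] <- rr; ctrCol[i] <- cc; break }
      }
      if (!ok)
        stop("field too crowded: could not place cell ", i, " after ",
             maxRetries, " retries", call. = FALSE)
    }

    # --- truth masks: nuclei are disjoint disks; cell disks compete for ---
    # --- contested pixels by distance to the nucleus centre (lower id wins ties)
    nucLabels <- matrix(0L, H, W)
    cellLabels <- matrix(0L, H, W)
    bestDist <- matrix(Inf, H, W)
    for (i in seq_len(n)) {
      nucLabels[.diskIndices(ctrRow[i], ctrCol[i], rNucPx[i], H, W)] <- i
      idx <- .diskIndices(ctrRow[i], ctrCol[i], rCellPx[i], H, W)
      rowI <- ((idx - 1L) %% H) + 1L
      colI <- ((idx - 1L) %/% H) + 1L
      d <- sqrt((rowI - ctrRow[i])^2 + (colI - ctrCol[i])^2)
      win <- d < bestDist[idx]
      cellLabels[idx[win]] <- i
      bestDist[idx[win]] <- d[win]
    }
    nz <- nucLabels != 0L
    cellLabels[nz] <- nucLabels[nz]   # nucleus always belongs to its own cell

    # --- inclusion flags and true densities, in placement order ---
    inclusion <- stats::runif(n) < config$inclusionFraction[typeOf]
    density <- vapply(seq_len(n), function(i)
      .drawDensity(config, typeOf[i], inclusion[i]), numeric(1))

    # --- transcript truth mask: realized fraction == drawn density ---
    mask <- matrix(FALSE, H, W)
    cellArea <- .areaByLabel(cellLabels, n)
    for (i in seq_len(n)) {
      cellIdx <- which(cellLabels == i)
      target <- as.integer(round(density[i] / 100 * cellArea[i]))
      mask <- .stampTranscripts(mask, cellIdx, target, config, H, W)
    }
    if (config$bgPunctaPerUm2 > 0) {
      outside <- which(cellLabels == 0L)
      areaUm2 <- length(outside) * config$umPerPx^2
      nBg <- stats::rpois(1, config$bgPunctaPerUm2 * areaUm2)
      if (nBg > 0) {
        rPxRange <- config$punctaSizeUm / 2 / config$umPerPx
        for (k in seq_len(nBg)) {
          ctr <- outside[sample.int(length(outside), 1L)]
          row <- ((ctr - 1L) %% H) + 1L; col <- ((ctr - 1L) %/% H) + 1L
          lin <- .diskIndices(row, col, stats::runif(1, rPxRange[1], rPxRange[2]), H, W)
          lin <- lin[cellLabels[lin] == 0L]
          mask[lin] <- TRUE
        }
      }
    }

    nucArea <- .areaByLabel(nucLabels, n)
    nucPos <- .areaByLabel(nucLabels, n, mask)
    nucDensity <- ifelse(nucArea > 0, 100 * nucPos / nucArea, NA_real_)

    # --- render channels ---
    bg <- config$backgroundLevel; A <- config$signalAmplitude
    markerIds <- which(typeOf == config$markerType)
    ptauImg <- matrix(0, H, W)
    for (i in which(inclusion)) {
      blob <- .diskIndices(ctrRow[i], ctrCol[i], 1.2 * rNucPx[i], H, W)
      blob <- blob[cellLabels[blob] == i]
      ptauImg[blob] <- 1
    }
    channels <- list(
      nucleus = .blurNoiseClip(bg + A * (nucLabels > 0L), config),
      marker = .blurNoiseClip(bg + A * matrix(cellLabels %in% markerIds, H, W),
                              config),
      transcript = .blurNoiseClip(bg + A * mask, config),
      ptau = .blurNoiseClip(bg + A * ptauImg, config)
    )
    for (role in names(channels)) {
      if (mean(channels[[role]] >= 1) > 0.5)
        stop(sprintf("configuration error: '%s' channel saturates on > 50%% of pixels",
                     role), call. = FALSE)
    }

    truth <- new("GroundTruth",
      cells = data.frame(
        cell_id = seq_len(n), cell_type = typeOf,
        centroid_row = ctrRow, centroid_col = ctrCol,
        inclusion = inclusion,
        true_density_pct = density,
        true_nuc_density_pct = nucDensity,
        stringsAsFactors = FALSE),
      nucLabels = nucLabels, cellLabels = cellLabels, transcriptMask = mask)
    field <- FieldImage(channels, config$umPerPx, fieldId = fieldId,
                        caseId = caseId, region = region,
                        markerType = config$markerType)
    list(field = field, truth = truth)
  })
}

#' Draw a per-cell density table directly from the configured laws
#'
#' Bypasses image synthesis: rows are drawn straight from the density law,
#' with the schema of the quantification output, so the statistical stage can
#' be exercised on tables with known distributional structure.
#'
#' @param config a \code{\link{synthFieldConfig}} (only the cell-type mix,
#'   radii, density laws, inclusion fractions and seed are used).
#' @param nCells total number of rows to draw (allocated across types in
#'   proportion to \code{cellsPerType}).
#' @param caseId,region identifiers stamped on every row.
#' @return list with \code{table} (\linkS4class{DensityTable}) and
#'   \code{truth} (data.frame mirroring the drawn values).
#' @export
generateDensityTable <- function(config, nCells, caseId = "synthetic",
                                 region = "synthetic") {
  .validateSynthFieldConfig(config)
  if (length(nCells) != 1L || !is.finite(nCells) || nCells < 1)
    stop("nCells must be a single integer >= 1", call. = FALSE)
  nCells <- as.integer(nCells)
  .withSeed(config$seed, {
    types <- names(config$cellsPerType)
    w <- config$cellsPerType / sum(config$cellsPerType)
    alloc <- diff(c(0L, as.integer(round(cumsum(w * nCells)))))
    typeOf <- rep(types, times = alloc)
    n <- length(typeOf)
    inclusion <- stats::runif(n) < config$inclusionFraction[typeOf]
    density <- vapply(seq_len(n), function(i)
      .drawDensity(config, typeOf[i], inclusion[i]), numeric(1))
    nucDensity <- vapply(seq_len(n), function(i)
      .drawDensity(config, typeOf[i], inclusion[i]), numeric(1))
    cellArea <- pi * config$cellRadiusUm[typeOf]^2
    nucArea <- pi * config$nucleusRadiusUm[typeOf]^2
    rec <- data.frame(
      cell_id = seq_len(n), field_id = "synthetic", case_id = caseId,
      region = region, cell_type = typeOf, source = "synthetic",
      inclusion = inclusion,
      cell_area_um2 = unname(cellArea), nuc_area_um2 = unname(nucArea),
      mapt_area_um2 = unname(density / 100 * cellArea),
      nuc_mapt_area_um2 = unname(nucDensity / 100 * nucArea),
      density_pct = density, nuc_density_pct = nucDensity,
      stringsAsFactors = FALSE)
    prov <- list(generator = "generateDensityTable", seed = config$seed,
                 n_cells = n,
                 version = as.character(utils::packageVersion("maptquant")))
    list(table = DensityTable(rec, prov), truth = rec)
  })
}
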
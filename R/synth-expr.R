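#' Configuration for the synthetic single-nucleus count-matrix generator
#'
#' Emulates the statistical structure of a cells x genes UMI matrix from
#' single-nucleus RNA-seq of cortex: per-cell library sizes follow a
#' lognormal law (median around 8000 UMIs, as observed in human frontal
#' cortex nuclei), MAPT abundance is graded across cell types (highest in
#' inhibitory neurons, then astrocytes and OPCs; low in excitatory neurons
#' and mature oligodendrocytes; nearly absent in endothelial cells), counts
#' are negative-binomial with a common overdispersion, and designated cell
#' types carry a multiplicative group shift of MAPT in the disease group.
#'
#' @param nCellsPerGroup cells per (group, cell type).
#' @param groups two group labels; the shift applies to the second.
#' @param cellTypes character vector of cell-type labels.
#' @param maptBaseCp10k named vector: baseline MAPT abundance per type on the
#'   counts-per-10,000 scale.
#' @param shiftTypes cell types whose MAPT mean is multiplied by
#'   \code{shiftFactor} in the second group (default: the three types with
#'   reduced expression in disease).
#' @param shiftFactor multiplicative MAPT shift (0.6 = a 40\% reduction).
#' @param nFillerGenes number of background genes sharing the remaining
#'   library mass equally.
#' @param libSizeMeanlog,libSizeSdlog lognormal law of target library sizes.
#' @param dispersion negative-binomial size parameter (smaller = noisier).
#' @param seed integer RNG seed.
#' @return validated config (list with class \code{"ExprSynthConfig"}).
#' @export
exprSynthConfig <- function(
    nCellsPerGroup = 2000L,
    groups = c("control", "PSP"),
    cellTypes = c("excitatory_neuron", "inhibitory_neuron", "astrocyte",
                  "oligodendrocyte", "OPC", "endothelial"),
    maptBaseCp10k = c(excitatory_neuron = 8, inhibitory_neuron = 30,
                      astrocyte = 20, oligodendrocyte = 6, OPC = 15,
                      endothelial = 0.2),
    shiftTypes = c("inhibitory_neuron", "astrocyte", "OPC"),
    shiftFactor = 0.6,
    nFillerGenes = 24L,
    libSizeMeanlog = log(8000),
    libSizeSdlog = 0.4,
    dispersion = 2,
    seed = 1L) {
  cfg <- list(nCellsPerGroup = as.integer(nCellsPerGroup), groups = groups,
              cellTypes = cellTypes, maptBaseCp10k = maptBaseCp10k,
              shiftTypes = shiftTypes, shiftFactor = shiftFactor,
              nFillerGenes = as.integer(nFillerGenes),
              libSizeMeanlog = libSizeMeanlog, libSizeSdlog = libSizeSdlog,
              dispersion = dispersion, seed = as.integer(seed))
  class(cfg) <- "ExprSynthConfig"
  .validateExprSynthConfig(cfg)
  cfg
}

.validateExprSynthConfig <- function(cfg) {
  fail <- function(msg) stop("invalid ExprSynthConfig: ", msg, call. = FALSE)
  if (cfg$nCellsPerGroup < 1L) fail("nCellsPerGroup must be >= 1")
  if (length(cfg$groups) != 2L || anyDuplicated(cfg$groups))
    fail("groups must be two distinct labels")
  if (!length(cfg$cellTypes)) fail("cellTypes must be non-empty")
  if (!all(cfg$cellTypes %in% names(cfg$maptBaseCp10k)))
    fail("maptBaseCp10k must cover every cell type")
  if (any(cfg$maptBaseCp10k < 0)) fail("maptBaseCp10k must be >= 0")
  if (!all(cfg$shiftTypes %in% cfg$cellTypes))
    fail("shiftTypes must be a subset of cellTypes")
  if (!is.finite(cfg$shiftFactor) || cfg$shiftFactor < 0)
    fail("shiftFactor must be >= 0")
  if (cfg$nFillerGenes < 1L) fail("nFillerGenes must be >= 1")
  if (cfg$libSizeSdlog < 0) fail("libSizeSdlog must be >= 0")
  if (!is.finite(cfg$dispersion) || cfg$dispersion <= 0)
    fail("dispersion must be > 0")
  invisible(cfg)
}

#' Generate a synthetic genes x cells count matrix with metadata
#'
#' Integer UMI counts for MAPT plus filler genes across cells of each
#' (group, cell type) stratum, per \code{\link{exprSynthConfig}}. Counts are
#' negative-binomial around per-gene expected fractions of each cell's drawn
#' library size, so realized library sizes concentrate around the configured
#' lognormal law.
#'
#' @param config an \code{\link{exprSynthConfig}}.
#' @return list with \code{counts} (integer matrix, genes in rows with
#'   \code{"MAPT"} first, cells in columns) and \code{meta} (data.frame:
#'   \code{cell_id}, \code{group}, \code{cell_type}).
#' @examples
#' cfg <- exprSynthConfig(nCellsPerGroup = 5L, seed = 3L)
#' m <- generateExprMatrix(cfg)
#' dim(m$counts); head(m$meta)
#' @export
generateExprMatrix <- function(config) {
  .validateExprSynthConfig(config)
  .withSeed(config$seed, {
    strata <- expand.grid(group = config$groups, cell_type = config$cellTypes,
                          stringsAsFactors = FALSE)
    meta <- strata[rep(seq_len(nrow(strata)), each = config$nCellsPerGroup), ]
    nCells <- nrow(meta)
    meta$cell_id <- sprintf("cell%06d", seq_len(nCells))
    rownames(meta) <- NULL
    meta <- meta[, c("cell_id", "group", "cell_type")]

    genes <- c("MAPT", sprintf("GENE%03d", seq_len(config$nFillerGenes)))
    lib <- stats::rlnorm(nCells, config$libSizeMeanlog, config$libSizeSdlog)

    maptFrac <- config$maptBaseCp10k[meta$cell_type] / 1e4
    shifted <- meta$group == config$groups[2] &
      meta$cell_type %in% config$shiftTypes
    maptFrac[shifted] <- maptFrac[shifted] * config$shiftFactor

    counts <- matrix(0L, nrow = length(genes), ncol = nCells,
                     dimnames = list(genes, meta$cell_id))
    counts["MAPT", ] <- stats::rnbinom(nCells, mu = lib * maptFrac,
                                       size = config$dispersion)
    fillerMu <- lib * (1 - maptFrac) / config$nFillerGenes
    for (g in seq_len(config$nFillerGenes)) {
      counts[g + 1L, ] <- stats::rnbinom(nCells, mu = fillerMu,
                                         size = config$dispersion)
    }
    list(counts = counts, meta = meta)
  })
}
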
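# Shared fixtures: small synthetic configurations and truth-matching helpers.

# A small, fast field: ~200 um square, a handful of cells per type.
tinyFieldConfig <- function(seed = 1L, ...) {
  args <- list(
    fieldSize = c(400L, 400L),
    cellsPerType = c(neuron = 8L, oligodendrocyte = 8L, astrocyte = 8L),
    seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthFieldConfig, args)
}

# A bare FieldImage from plain matrices (defaults: blank marker/transcript).
makeField <- function(nucleus, marker = NULL, transcript = NULL, ptau = NULL,
                      umPerPx = 0.5, markerType = "neuron") {
  blank <- matrix(0, nrow(nucleus), ncol(nucleus))
  ch <- list(nucleus = nucleus,
             marker = if (is.null(marker)) blank else marker,
             transcript = if (is.null(transcript)) blank else transcript)
  if (!is.null(ptau)) ch$ptau <- ptau
  FieldImage(ch, umPerPx = umPerPx, markerType = markerType)
}

# Stamp a filled disk of radius r (px) into a matrix.
stampDisk <- function(mat, row, col, r, value = 1) {
  H <- nrow(mat); W <- ncol(mat)
  d <- seq(-ceiling(r), ceiling(r))
  g <- expand.grid(dr = d, dc = d)
  g <- g[g$dr^2 + g$dc^2 <= r^2, ]
  rr <- row + g$dr; cc <- col + g$dc
  keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  mat[cbind(rr[keep], cc[keep])] <- value
  mat
}

# Map each measured cell to the ground-truth cell whose truth mask contains
# its nucleus centroid (0 rows where unmatched).
matchToTruth <- function(records, seg, truth) {
  cells <- cellData(seg)
  lab <- truthCellLabels(truth)
  idx <- cbind(pmax(1, round(cells$centroid_row)),
               pmax(1, round(cells$centroid_col)))
  tid <- lab[idx]
  m <- match(records$cell_id, cells$cell_id)
  data.frame(records, truth_id = tid[m])
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating all assignments
# of the pooled values to the two groups (independent oracle; no ties).
mwExactOracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  uOf <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  uObs <- uOf(seq_len(n1))
  us <- apply(utils::combn(length(pooled), n1), 2, uOf)
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(us - mu) >= abs(uObs - mu))
}
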
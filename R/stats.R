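# Nonparametric group comparisons, percentile-exceedance criterion and
# summary statistics for per-cell area-density tables.

.testResult <- function(test, statistic, p, nGroups, labels, alpha) {
  data.frame(test = test, statistic = unname(statistic), p_value = unname(p),
             n = paste(nGroups, collapse = ","),
             groups = paste(labels, collapse = " vs "),
             alpha = alpha, significant = unname(p) < alpha,
             stringsAsFactors = FALSE)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of the values against a normal with the sample mean
#' and SD. This screen uses the conventional 0.05 level (p < 0.05 is read as
#' non-normal) and only gates the choice of nonparametric tests downstream;
#' estimating the parameters from the data makes the screen anticonservative
#' (the Lilliefors effect), which is accepted here because commercial
#' statistics packages screen the same way.
#'
#' @param values numeric vector, n >= 5, finite.
#' @param alpha screening level (default 0.05).
#' @return one-row data.frame: test, statistic, p_value, n, groups, alpha,
#'   significant (TRUE = non-normal).
#' @export
ksNormality <- function(values, alpha = 0.05) {
  if (length(values) < 5) stop("ksNormality requires n >= 5", call. = FALSE)
  .assertFinite(values, "values")
  s <- stats::sd(values)
  if (s == 0)
    stop("degenerate distribution: zero variance", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(values, "pnorm", mean(values), s))
  .testResult("KS-normality", kt$statistic, kt$p.value, length(values),
              "sample vs normal", alpha)
}

#' Mann-Whitney U test
#'
#' Two-sided comparison of two groups. The p-value is exact (by complete
#' enumeration) when both groups have at most 8 observations and there are
#' no ties; otherwise the normal approximation with tie correction is used,
#' without continuity correction so that for two groups the Kruskal-Wallis
#' statistic satisfies H = z^2 and both tests return the same p-value.
#'
#' @param a,b numeric vectors, each non-empty and finite.
#' @param alpha significance level (default 0.01).
#' @param labels group labels for reporting.
#' @return one-row data.frame (see \code{\link{ksNormality}}); statistic is
#'   the U of the first group.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # exact two-sided p = 0.1
#' @export
mannWhitney <- function(a, b, alpha = 0.01, labels = c("a", "b")) {
  if (!length(a) || !length(b)) stop("empty group", call. = FALSE)
  .assertFinite(c(a, b), "values")
  exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = FALSE))
  p <- wt$p.value
  if (is.na(p)) p <- 1  # zero rank variance: every observation tied
  .testResult("Mann-Whitney U", wt$statistic, min(1, p),
              c(length(a), length(b)), labels, alpha)
}

#' Kruskal-Wallis test
#'
#' Rank-based comparison of two or more groups, with tie correction and a
#' chi-square reference distribution on k - 1 degrees of freedom.
#'
#' @param groups list of >= 2 non-empty finite numeric vectors.
#' @param alpha significance level (default 0.01).
#' @return one-row data.frame (see \code{\link{ksNormality}}).
#' @export
kruskalWallis <- function(groups, alpha = 0.01) {
  if (!is.list(groups) || length(groups) < 2)
    stop("kruskalWallis requires >= 2 groups", call. = FALSE)
  if (any(lengths(groups) == 0)) stop("empty group", call. = FALSE)
  .assertFinite(unlist(groups), "values")
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("g", seq_along(groups))
  kt <- stats::kruskal.test(groups)
  H <- kt$statistic; p <- kt$p.value
  if (is.na(H)) { H <- 0; p <- 1 }  # all observations tied
  .testResult("Kruskal-Wallis", H, p, lengths(groups), labs, alpha)
}

#' Percentile cutoff of a reference group
#'
#' The q-th percentile of the reference distribution, used as the cutoff in
#' the exceedance criterion. The default operationalization is the empirical
#' percentile with linear interpolation between the closest order statistics
#' (the convention matters on small samples and is therefore fixed and
#' documented); a parametric standard-score variant, mean + z_q * SD, is
#' available for sensitivity analysis on near-normal data.
#'
#' @param reference numeric vector of reference-group densities; a warning
#'   is issued below n = 20.
#' @param q percentile in (0, 100), default 95.
#' @param method \code{"empirical"} (default) or \code{"parametric"}.
#' @return the cutoff value.
#' @examples
#' percentileCutoff(0:100)  # 95
#' @export
percentileCutoff <- function(reference, q = 95, method = c("empirical", "parametric")) {
  method <- match.arg(method)
  if (!length(reference)) stop("empty reference group", call. = FALSE)
  .assertFinite(reference, "reference")
  if (!(q > 0 && q < 100)) stop("q must lie in (0, 100)", call. = FALSE)
  if (length(reference) < 20)
    warning("reference group has n < 20; the percentile cutoff is unstable",
            call. = FALSE)
  if (method == "empirical")
    unname(stats::quantile(reference, q / 100, type = 7))
  else
    mean(reference) + stats::qnorm(q / 100) * stats::sd(reference)
}

#' Percentile-exceedance criterion
#'
#' Computes the proportion of test-group cells (cells with tau-immunopositive
#' inclusions) whose area density lies strictly above (or strictly below)
#' the q-th percentile cutoff of the reference group (cells without
#' inclusions). A proportion reaching 50\% is flagged as a strong indicator
#' of an increase (or decrease) of transcript density in inclusion-bearing
#' cells.
#'
#' @param reference,test non-empty numeric vectors.
#' @param direction \code{"above"} or \code{"below"} (strict comparisons, so
#'   a test value exactly at the cutoff never exceeds).
#' @param q percentile in (0, 100), default 95.
#' @param method cutoff operationalization, see \code{\link{percentileCutoff}}.
#' @return one-row data.frame: direction, q, cutoff, n_ref, n_test,
#'   n_exceeding, proportion_pct, strong_indicator.
#' @export
exceedance <- function(reference, test, direction = c("above", "below"),
                       q = 95, method = "empirical") {
  direction <- match.arg(direction)
  if (!length(test)) stop("empty test group", call. = FALSE)
  .assertFinite(test, "test")
  cutoff <- suppressWarnings(percentileCutoff(reference, q, method))
  nEx <- if (direction == "above") sum(test > cutoff) else sum(test < cutoff)
  prop <- 100 * nEx / length(test)
  data.frame(direction = direction, q = q, cutoff = cutoff,
             n_ref = length(reference), n_test = length(test),
             n_exceeding = nEx, proportion_pct = prop,
             strong_indicator = prop >= 50,
             stringsAsFactors = FALSE)
}

#' Pool density tables
#'
#' Concatenates compatible per-case density tables into one, preserving every
#' record (pooled n is the exact sum of the input ns) and taking the union
#' of provenance. Records that collide on (case, field, cell) are an error.
#'
#' @param tables list of \linkS4class{DensityTable} objects.
#' @return a \linkS4class{DensityTable}.
#' @export
poolTables <- function(tables) {
  if (!length(tables)) stop("no tables to pool", call. = FALSE)
  stopifnot(all(vapply(tables, is, logical(1), "DensityTable")))
  recs <- lapply(tables, records)
  cols <- lapply(recs, names)
  if (!all(vapply(cols, identical, logical(1), cols[[1]])))
    stop("incompatible table schemas", call. = FALSE)
  rec <- do.call(rbind, recs)
  key <- paste(rec$case_id, rec$field_id, rec$cell_id, sep = "\r")
  if (anyDuplicated(key))
    stop("key collision across pooled tables: same (case, field, cell) in ",
         "more than one input", call. = FALSE)
  rownames(rec) <- NULL
  DensityTable(rec, list(pooled_from = lapply(tables, provenance)))
}

#' Mean and standard error of the mean
#'
#' Area density is conventionally reported as mean +/- SEM, where
#' SEM = SD / sqrt(n). SEM is undefined (NA) for a single value.
#'
#' @param values numeric vector, n >= 1.
#' @return one-row data.frame: n, mean, sem.
#' @examples
#' densitySummary(c(1, 2, 3))  # mean 2, sem 1/sqrt(3)
#' @export
densitySummary <- function(values) {
  if (!length(values)) stop("empty value vector", call. = FALSE)
  .assertFinite(values, "values")
  n <- length(values)
  data.frame(n = n, mean = mean(values),
             sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_)
}

#' Integer percentage from a count pair
#'
#' \code{round(100 * x / n)} to the nearest integer, rounding halves away
#' from zero, matching the "17/85, 20\%"-style reporting of cell counts.
#'
#' @param x count of events, 0 <= x <= n (vectorized).
#' @param n total count, >= 1.
#' @return integer percentage(s).
#' @examples
#' pctFromCounts(17, 85)  # 20
#' @export
pctFromCounts <- function(x, n) {
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  if (any(x < 0 | x > n)) stop("need 0 <= x <= n", call. = FALSE)
  if (any(x != floor(x) | n != floor(n)))
    stop("x and n must be integers", call. = FALSE)
  as.integer(.roundHalfUp(100 * x / n))
}

#' Inclusion-stratified statistical report for a density table
#'
#' Reproduces the full statistics stage on a per-cell density table: per
#' (cell type, region) stratum and per cell type pooled across regions it
#' reports group sizes and mean +/- SEM for cells with and without
#' inclusions, the KS normality screen, the Mann-Whitney comparison of
#' inclusion vs non-inclusion cells at \code{alpha}, and the
#' percentile-exceedance criterion in both directions; across cell types it
#' runs Kruskal-Wallis on the inclusion-free cells. P-values are unadjusted
#' (no multiple-testing correction is applied, by design).
#'
#' @param table a \linkS4class{DensityTable}.
#' @param alpha significance level (default 0.01).
#' @param q exceedance percentile (default 95).
#' @param method cutoff operationalization, see \code{\link{percentileCutoff}}.
#' @param value which density to analyse: \code{"density_pct"} (whole-cell)
#'   or \code{"nuc_density_pct"} (nuclear).
#' @return list of data.frames: \code{summaries}, \code{normality},
#'   \code{comparisons}, \code{exceedance}, \code{between_types}.
#' @export
runDensityStats <- function(table, alpha = 0.01, q = 95, method = "empirical",
                            value = c("density_pct", "nuc_density_pct")) {
  stopifnot(is(table, "DensityTable"))
  value <- match.arg(value)
  rec <- records(table)
  rec <- rec[!is.na(rec[[value]]), , drop = FALSE]
  if (!nrow(rec)) stop("no usable records", call. = FALSE)

  strata <- unique(rbind(
    data.frame(cell_type = rec$cell_type, region = rec$region,
               stringsAsFactors = FALSE),
    data.frame(cell_type = unique(rec$cell_type), region = "pooled",
               stringsAsFactors = FALSE)))
  summaries <- normality <- comparisons <- exceed <- list()
  for (i in seq_len(nrow(strata))) {
    ty <- strata$cell_type[i]; rg <- strata$region[i]
    sub <- rec[rec$cell_type == ty &
                 (rg == "pooled" | rec$region == rg), , drop = FALSE]
    for (st in c(FALSE, TRUE)) {
      v <- sub[[value]][sub$inclusion == st]
      if (length(v)) {
        s <- densitySummary(v)
        s <- cbind(data.frame(cell_type = ty, region = rg, inclusion = st,
                              stringsAsFactors = FALSE), s)
        summaries[[length(summaries) + 1L]] <- s
        if (length(v) >= 5 && stats::sd(v) > 0) {
          nr <- cbind(data.frame(cell_type = ty, region = rg, inclusion = st,
                                 stringsAsFactors = FALSE), ksNormality(v))
          normality[[length(normality) + 1L]] <- nr
        }
      }
    }
    vNo <- sub[[value]][!sub$inclusion]
    vYes <- sub[[value]][sub$inclusion]
    if (length(vNo) && length(vYes)) {
      cmp <- cbind(data.frame(cell_type = ty, region = rg,
                              stringsAsFactors = FALSE),
                   mannWhitney(vNo, vYes, alpha = alpha,
                               labels = c("no inclusion", "inclusion")))
      comparisons[[length(comparisons) + 1L]] <- cmp
      for (dir in c("above", "below")) {
        ex <- cbind(data.frame(cell_type = ty, region = rg,
                               stringsAsFactors = FALSE),
                    exceedance(vNo, vYes, direction = dir, q = q,
                               method = method))
        exceed[[length(exceed) + 1L]] <- ex
      }
    }
  }
  types <- unique(rec$cell_type)
  between <- NULL
  if (length(types) >= 2) {
    gl <- split(rec[[value]][!rec$inclusion], rec$cell_type[!rec$inclusion])
    gl <- gl[lengths(gl) > 0]
    if (length(gl) >= 2) between <- kruskalWallis(gl, alpha = alpha)
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  list(summaries = bind(summaries), normality = bind(normality),
       comparisons = bind(comparisons), exceedance = bind(exceed),
       between_types = between)
}
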
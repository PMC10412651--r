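# Reproducible end-to-end runs: simulate -> quantify -> stats -> exprstats,
# driven by a declarative YAML config, with a manifest recording config hash,
# seed and package version.

#' Read and validate a run configuration
#'
#' The configuration is a YAML file of flat keys plus nested stage sections
#' (see the bundled demo at
#' \code{system.file("extdata", "demo_config.yaml", package = "maptquant")}).
#' Overrides supplied programmatically (or from CLI flags) replace file
#' values before validation. Validation failures name the offending field.
#'
#' @param path YAML file path, or NULL to start from defaults.
#' @param overrides named list merged over the file values (nested lists are
#'   merged recursively).
#' @return validated config list (class \code{"RunConfig"}).
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- list(
    seed = 1L, output_dir = "maptquant_out", alpha = 0.01, percentile_q = 95,
    um_per_px = 0.5,
    simulate = list(n_fields = 3L,
                    marker_types = c("neuron", "oligodendrocyte", "astrocyte"),
                    cells_per_type = NULL, field_size = NULL,
                    expr = list(n_cells_per_group = 300L)),
    quantify = list(input_dir = NULL, transcript_method = "otsu",
                    transcript_fixed_threshold = NULL),
    stats = list(table = NULL),
    exprstats = list(input_dir = NULL))
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- .mergeConfig(cfg, yaml::read_yaml(path))
  }
  cfg <- .mergeConfig(cfg, overrides)
  .validateRunConfig(cfg)
  class(cfg) <- "RunConfig"
  cfg
}

.mergeConfig <- function(base, new) {
  for (k in names(new)) {
    base[[k]] <- if (is.list(new[[k]]) && is.list(base[[k]]))
      .mergeConfig(base[[k]], new[[k]]) else new[[k]]
  }
  base
}

.validateRunConfig <- function(cfg) {
  fail <- function(field, msg)
    stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || !is.finite(cfg$seed))
    fail("seed", "must be a single integer")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    fail("alpha", "must lie strictly between 0 and 1")
  if (!is.numeric(cfg$percentile_q) || cfg$percentile_q <= 0 ||
      cfg$percentile_q >= 100)
    fail("percentile_q", "must lie strictly between 0 and 100")
  if (!is.numeric(cfg$um_per_px) || cfg$um_per_px <= 0)
    fail("um_per_px", "must be positive")
  if (cfg$simulate$n_fields < 1) fail("simulate.n_fields", "must be >= 1")
  for (f in c("quantify$input_dir", "stats$table", "exprstats$input_dir")) {
    parts <- strsplit(f, "$", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (!is.null(v) && !file.exists(v))
      fail(gsub("$", ".", f, fixed = TRUE), sprintf("path '%s' does not exist", v))
  }
  invisible(cfg)
}

.configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.simFieldConfig <- function(cfg, i) {
  mk <- cfg$simulate$marker_types
  args <- list(markerType = mk[((i - 1L) %% length(mk)) + 1L],
               umPerPx = cfg$um_per_px,
               seed = as.integer(cfg$seed) + i)
  if (!is.null(cfg$simulate$cells_per_type))
    args$cellsPerType <- unlist(cfg$simulate$cells_per_type)
  if (!is.null(cfg$simulate$field_size))
    args$fieldSize <- as.integer(unlist(cfg$simulate$field_size))
  do.call(synthFieldConfig, args)
}

#' Run the pipeline
#'
#' Executes one or all stages against a validated configuration, writing
#' images as multi-page TIFF, tables as CSV, the statistical report as JSON
#' plus a human-readable text rendering, and a manifest with the config
#' hash, seed and package version. Identical configurations produce
#' identical artifacts.
#'
#' @param config a \code{\link{readRunConfig}} result, or a path to a YAML
#'   config.
#' @param stage one of \code{"simulate"}, \code{"quantify"}, \code{"stats"},
#'   \code{"exprstats"}, \code{"all"}.
#' @param verbose log stage progress and per-field retention counts.
#' @return invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(config, stage = c("all", "simulate", "quantify",
                                          "stats", "exprstats"),
                        verbose = FALSE) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- readRunConfig(config)
  .validateRunConfig(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  say <- function(...) if (verbose) message(sprintf(...))

  if (stage %in% c("all", "simulate")) {
    say("simulate: %d field(s)", config$simulate$n_fields)
    fdir <- file.path(out, "fields")
    dir.create(fdir, showWarnings = FALSE)
    for (i in seq_len(config$simulate$n_fields)) {
      fc <- .simFieldConfig(config, i)
      sim <- generateField(fc, fieldId = sprintf("field%02d", i))
      writeFieldTiff(sim$field, file.path(fdir, sprintf("field%02d.tif", i)),
                     channelOrder = c("nucleus", "marker", "transcript", "ptau"))
      writeGroundTruth(sim$truth, file.path(fdir, sprintf("truth%02d.csv", i)))
      cfgPath <- file.path(fdir, sprintf("field%02d.yaml", i))
      yaml::write_yaml(list(marker_type = fc$markerType, um_per_px = fc$umPerPx,
                            seed = fc$seed), cfgPath)
    }
    artifacts$fields_dir <- fdir
    ec <- exprSynthConfig(
      nCellsPerGroup = as.integer(config$simulate$expr$n_cells_per_group),
      seed = as.integer(config$seed))
    em <- generateExprMatrix(ec)
    artifacts$expr_dir <- writeExprMatrix(em$counts, em$meta,
                                          file.path(out, "expr"))
  }

  if (stage %in% c("all", "quantify")) {
    fdir <- if (!is.null(config$quantify$input_dir)) config$quantify$input_dir
            else file.path(out, "fields")
    tifs <- sort(list.files(fdir, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(tifs)) stop("no TIFF fields found in ", fdir, call. = FALSE)
    fields <- lapply(tifs, function(p) {
      side <- sub("\\.tiff?$", ".yaml", p)
      meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
      readFieldTiff(p, umPerPx = meta$um_per_px %||% config$um_per_px,
                    fieldId = sub("\\.tiff?$", "", basename(p)),
                    markerType = meta$marker_type %||% "neuron")
    })
    say("quantify: %d field(s)", length(fields))
    params <- quantifyParams(
      transcriptMethod = config$quantify$transcript_method,
      transcriptFixedThreshold = config$quantify$transcript_fixed_threshold)
    dt <- buildDensityTable(fields, params, verbose = verbose)
    artifacts$density_table <- file.path(out, "density_table.csv")
    writeDensityTable(dt, artifacts$density_table)
  }

  if (stage %in% c("all", "stats")) {
    tpath <- config$stats$table %||% file.path(out, "density_table.csv")
    if (!file.exists(tpath)) stop("density table not found: ", tpath, call. = FALSE)
    dt <- readDensityTable(tpath)
    say("stats: %d cells", nrow(records(dt)))
    rep <- runDensityStats(dt, alpha = config$alpha, q = config$percentile_q)
    artifacts$report_json <- file.path(out, "report.json")
    jsonlite::write_json(rep, artifacts$report_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    artifacts$report_txt <- file.path(out, "report.txt")
    writeLines(.renderReport(rep, config), artifacts$report_txt)
  }

  if (stage %in% c("all", "exprstats")) {
    edir <- config$exprstats$input_dir %||% file.path(out, "expr")
    if (dir.exists(edir)) {
      em <- readExprMatrix(edir)
      say("exprstats: %d cells", ncol(em$counts))
      norm <- normalizeCp10k(em$counts)
      res <- compareMaptByCelltype(norm, em$meta, alpha = config$alpha)
      artifacts$expr_tests <- file.path(out, "expr_tests.csv")
      utils::write.csv(res, artifacts$expr_tests, row.names = FALSE)
    } else if (stage == "exprstats") {
      stop("expression directory not found: ", edir, call. = FALSE)
    }
  }

  manifest <- list(config = unclass(config), config_hash = .configHash(config),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("maptquant")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts$manifest <- file.path(out, "manifest.json")
  invisible(artifacts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.renderReport <- function(rep, cfg) {
  lines <- c("Per-cell MAPT transcript area-density report",
             sprintf("alpha = %g, exceedance percentile q = %g", cfg$alpha,
                     cfg$percentile_q), "")
  s <- rep$summaries
  if (!is.null(s)) {
    lines <- c(lines, "Mean +/- SEM by cell type, region and inclusion status:")
    for (i in seq_len(nrow(s))) {
      lines <- c(lines, sprintf(
        "  %-16s %-14s %-12s n=%4d  %.2f +/- %s %%", s$cell_type[i],
        s$region[i], if (s$inclusion[i]) "inclusion" else "no-inclusion",
        s$n[i], s$mean[i],
        if (is.na(s$sem[i])) "NA" else sprintf("%.2f", s$sem[i])))
    }
    lines <- c(lines, "")
  }
  cm <- rep$comparisons
  if (!is.null(cm)) {
    lines <- c(lines, "Mann-Whitney, inclusion vs no-inclusion (unadjusted p):")
    for (i in seq_len(nrow(cm))) {
      lines <- c(lines, sprintf("  %-16s %-14s U=%.1f p=%.4g%s", cm$cell_type[i],
                                cm$region[i], cm$statistic[i], cm$p_value[i],
                                if (cm$significant[i]) " *" else ""))
    }
    lines <- c(lines, "")
  }
  ex <- rep$exceedance
  if (!is.null(ex)) {
    lines <- c(lines, "Exceedance vs reference percentile cutoff:")
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf(
        "  %-16s %-14s %-6s cutoff=%.2f%%  %d/%d (%.1f%%)%s",
        ex$cell_type[i], ex$region[i], ex$direction[i], ex$cutoff[i],
        ex$n_exceeding[i], ex$n_test[i], ex$proportion_pct[i],
        if (ex$strong_indicator[i]) "  STRONG" else ""))
    }
    lines <- c(lines, "")
  }
  if (!is.null(rep$between_types)) {
    bt <- rep$between_types
    lines <- c(lines, sprintf(
      "Kruskal-Wallis across cell types (no-inclusion cells): H=%.2f p=%.4g%s",
      bt$statistic, bt$p_value, if (bt$significant) " *" else ""))
  }
  lines
}
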
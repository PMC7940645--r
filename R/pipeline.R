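# Run-level workflow: simulate -> analyze -> compare, each fully determined
# by a serialisable config + seed, with a checksum manifest of every output.

#' Assemble a run configuration
#'
#' A run is fully determined by its config: re-executing from a saved config
#' reproduces every output byte (the structured log, which carries wall
#' times, is excluded from the manifest for that reason).
#'
#' @param outDir output directory.
#' @param inputTables named character vector (group label -> table path), or
#'   NULL to use the cohort previously simulated into \code{outDir}.
#' @param synthetic list of overrides for \code{\link{syntheticSpec}} fields
#'   (groupNames, groupSizes, layout, within, between, noiseSd), or NULL for
#'   \code{\link{defaultSyntheticSpec}}.
#' @param pathwayConfig path to a pathway config, or NULL for the shipped
#'   default; \code{pathwayNames} optionally restricts to a subset.
#' @param pathwayNames subset of pathway names to analyse (NULL = all).
#' @param distanceMode \code{"absolute"} or \code{"signed"}.
#' @param edgeThreshold edge-filter distance threshold in (0, 1].
#' @param retainRule \code{"threshold"} or \code{"density"}.
#' @param snapshotLambdas filtration values for snapshot exports.
#' @param statistics statistics for group comparison.
#' @param nPermutations permutations per comparison.
#' @param alpha significance flag threshold.
#' @param seed master seed for the whole run.
#' @param verbose emit one structured log line per stage to stderr.
#' @return A list of class \code{phnRunConfig}.
#' @export
runConfig <- function(outDir,
                      inputTables = NULL,
                      synthetic = NULL,
                      pathwayConfig = NULL,
                      pathwayNames = NULL,
                      distanceMode = "absolute",
                      edgeThreshold = 0.5,
                      retainRule = "threshold",
                      snapshotLambdas = c(0.05, 0.10, 0.15, 0.20, 0.25),
                      statistics = c("sipAUC", "cpl"),
                      nPermutations = 10000L,
                      alpha = 0.001,
                      seed = 1L,
                      verbose = FALSE) {
  cfg <- list(outDir = outDir, inputTables = inputTables,
              synthetic = synthetic, pathwayConfig = pathwayConfig,
              pathwayNames = pathwayNames, distanceMode = distanceMode,
              edgeThreshold = edgeThreshold, retainRule = retainRule,
              snapshotLambdas = snapshotLambdas, statistics = statistics,
              nPermutations = as.integer(nPermutations), alpha = alpha,
              seed = as.integer(seed), verbose = isTRUE(verbose))
  class(cfg) <- "phnRunConfig"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' @param path config file.
#' @return A \code{phnRunConfig}.
#' @export
readRunConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    stop(sprintf("unsupported config extension '.%s'", ext)))
  if (!is.null(raw$inputTables)) raw$inputTables <- unlist(raw$inputTables)
  known <- names(formals(runConfig))
  do.call(runConfig, raw[intersect(names(raw), known)])
}

#' Save a run configuration as JSON
#'
#' @param config a \code{phnRunConfig}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

.log <- function(config, stage, detail, t0) {
  line <- sprintf("[phnet] stage=%s %s elapsed=%.2fs", stage, detail,
                  as.numeric(Sys.time()) - t0)
  if (isTRUE(config$verbose)) message(line)
  logfile <- file.path(config$outDir, "run.log")
  cat(line, "\n", file = logfile, append = TRUE, sep = "")
}

# Checksum manifest over every file under outDir except the manifest itself
# and the (wall-time-stamped) log.
.writeManifest <- function(outDir) {
  files <- sort(list.files(outDir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, c("manifest.csv", "run.log"))
  md5 <- unname(tools::md5sum(file.path(outDir, files)))
  con <- file(file.path(outDir, "manifest.csv"), open = "wb")
  on.exit(close(con))
  writeLines("file,md5", con)
  for (k in seq_along(files))
    writeLines(paste(files[k], md5[k], sep = ","), con)
  invisible(file.path(outDir, "manifest.csv"))
}

.syntheticFromConfig <- function(config) {
  if (is.null(config$synthetic)) return(defaultSyntheticSpec(config$seed))
  base <- defaultSyntheticSpec(config$seed)
  ov <- config$synthetic
  syntheticSpec(
    groupNames = if (is.null(ov$groupNames)) base@groupNames else ov$groupNames,
    groupSizes = if (is.null(ov$groupSizes)) base@groupSizes else ov$groupSizes,
    layout = if (is.null(ov$layout)) base@layout else ov$layout,
    within = if (is.null(ov$within)) base@within else ov$within,
    between = if (is.null(ov$between)) base@between else ov$between,
    noiseSd = if (is.null(ov$noiseSd)) base@noiseSd else ov$noiseSd,
    seed = config$seed)
}

.loadGroups <- function(config) {
  if (!is.null(config$inputTables)) {
    tabs <- config$inputTables
    if (is.null(names(tabs)) || any(!nzchar(names(tabs))))
      stop("inputTables must be named by group label")
    out <- lapply(names(tabs), function(g) readSubjectTable(tabs[[g]], g))
    names(out) <- names(tabs)
    return(out)
  }
  sidecar <- file.path(config$outDir, "cohort", "cohort_spec.json")
  if (!file.exists(sidecar))
    stop("no inputTables given and no simulated cohort found; run runSimulate() first")
  meta <- jsonlite::fromJSON(sidecar)
  out <- lapply(meta$groupNames, function(g)
    readSubjectTable(file.path(config$outDir, "cohort",
                               paste0("cohort_", g, ".csv")), g))
  names(out) <- meta$groupNames
  out
}

.loadPathways <- function(config) {
  paths <- if (is.null(config$pathwayConfig)) defaultPathways()
           else loadPathwayConfig(config$pathwayConfig)
  if (!is.null(config$pathwayNames)) {
    missing <- setdiff(config$pathwayNames, names(paths))
    if (length(missing))
      stop(sprintf("unknown pathway name(s): %s",
                   paste(missing, collapse = ", ")))
    paths <- paths[config$pathwayNames]
  }
  paths
}

#' Simulate a synthetic cohort to disk
#'
#' Writes one delimited table per group plus the JSON spec sidecar into
#' \code{outDir/cohort/} and refreshes the run manifest.
#'
#' @param config a \code{phnRunConfig}.
#' @return Invisibly, the written file paths.
#' @export
runSimulate <- function(config) {
  t0 <- as.numeric(Sys.time())
  if (!dir.exists(config$outDir)) dir.create(config$outDir, recursive = TRUE)
  spec <- .syntheticFromConfig(config)
  cohort <- generateCohort(spec)
  files <- writeCohort(cohort, spec, file.path(config$outDir, "cohort"))
  .log(config, "simulate",
       sprintf("groups=%d rois=%d", length(cohort), length(roiNames(spec))), t0)
  .writeManifest(config$outDir)
  invisible(files)
}

#' Analyse every group x pathway network
#'
#' For each diagnostic group and pathway: extracts the pathway columns,
#' computes the Pearson correlation and distance matrix, runs the full
#' persistence analysis and the graph metrics, and writes a tidy metrics
#' table, barcode and Betti-0 CSVs, a Newick dendrogram and snapshot edge
#' lists at the configured filtration values. A manifest with checksums
#' covers every artifact.
#'
#' @param config a \code{phnRunConfig}.
#' @return Invisibly, a named list of \linkS4class{PersistenceResult}
#'   objects keyed \code{<group>.<pathway>}.
#' @export
runAnalyze <- function(config) {
  t0 <- as.numeric(Sys.time())
  groups <- .loadGroups(config)
  paths <- .loadPathways(config)
  adir <- file.path(config$outDir, "analysis")
  if (!dir.exists(adir)) dir.create(adir, recursive = TRUE)
  metrics <- list()
  results <- list()
  for (g in names(groups)) {
    for (pw in names(paths)) {
      ctx <- sprintf("group=%s pathway=%s", g, pw)
      res <- tryCatch({
        sub <- extractPathway(groups[[g]], paths[[pw]])
        corr <- pearsonMatrix(sub)
        dist <- toDistance(corr, mode = config$distanceMode)
        ph <- persistentHomology(dist)
        wg <- filterEdges(dist, threshold = config$edgeThreshold,
                          rule = config$retainRule)
        list(sub = sub, dist = dist, ph = ph, wg = wg)
      }, error = function(e)
        stop(sprintf("analysis failed (%s): %s", ctx, conditionMessage(e)),
             call. = FALSE))
      cplv <- characteristicPathLength(res$wg)
      ndv <- networkDiameter(res$wg)
      ecv <- suppressWarnings(eigenvectorCentrality(res$wg))
      metrics[[paste(g, pw)]] <- data.frame(
        group = g, pathway = pw,
        metric = c("cpl", "nd", "ecMean", "sipAUC"),
        value = c(cplv$value, ndv$value, mean(ecv, na.rm = TRUE),
                  sipAUC(res$ph)),
        threshold = config$edgeThreshold,
        retain_rule = res$wg@retainRule,
        n_disconnected_pairs = c(cplv$nUnreachablePairs,
                                 ndv$nUnreachablePairs, NA, NA))
      stem <- file.path(adir, paste0(g, "_", pw))
      writeBarcodeCSV(res$ph, paste0(stem, "_barcode.csv"))
      writeBettiCSV(res$ph, paste0(stem, "_betti.csv"))
      writeNewick(res$ph, paste0(stem, "_dendrogram.nwk"))
      for (lam in config$snapshotLambdas)
        writeSnapshotCSV(res$dist, lam,
                         sprintf("%s_snapshot_lambda%.2f.csv", stem, lam))
      results[[paste(g, pw, sep = ".")]] <- res$ph
      .log(config, "analyze", ctx, t0)
    }
  }
  mt <- do.call(rbind, metrics)
  rownames(mt) <- NULL
  mt$value <- .fmtNum(mt$value)
  utils::write.csv(mt, file.path(adir, "metrics.csv"), row.names = FALSE,
                   quote = FALSE, na = "")
  .writeManifest(config$outDir)
  invisible(results)
}

#' Compare all group pairs with permutation tests
#'
#' Writes the tidy pairwise comparison table and a run-metadata JSON
#' (seed, permutations, thresholds, config hash) into
#' \code{outDir/compare/}.
#'
#' @param config a \code{phnRunConfig}.
#' @return Invisibly, the comparison data.frame.
#' @export
runCompare <- function(config) {
  t0 <- as.numeric(Sys.time())
  groups <- .loadGroups(config)
  paths <- .loadPathways(config)
  cdir <- file.path(config$outDir, "compare")
  if (!dir.exists(cdir)) dir.create(cdir, recursive = TRUE)
  tab <- pairwiseComparisonTable(
    groups, paths, statistics = config$statistics,
    nPermutations = config$nPermutations, seed = config$seed,
    alpha = config$alpha,
    options = list(threshold = config$edgeThreshold,
                   mode = config$distanceMode))
  out <- tab
  for (col in c("value1", "value2", "difference", "pValue"))
    out[[col]] <- .fmtNum(out[[col]])
  utils::write.csv(out, file.path(cdir, "comparisons.csv"),
                   row.names = FALSE, quote = FALSE)
  cfgTmp <- tempfile(fileext = ".json")
  hashable <- config
  hashable$outDir <- NULL  # hash the scientific parameters, not locations
  hashable$verbose <- NULL
  if (!is.null(hashable$pathwayConfig))  # content identifies the atlas
    hashable$pathwayConfig <- unname(tools::md5sum(hashable$pathwayConfig))
  if (!is.null(hashable$inputTables)) {
    tabs <- unlist(hashable$inputTables)
    hashable$inputTables <- as.list(stats::setNames(
      unname(tools::md5sum(tabs)), names(tabs)))
  }
  writeRunConfig(hashable, cfgTmp)
  jsonlite::write_json(
    list(seed = config$seed, nPermutations = config$nPermutations,
         edgeThreshold = config$edgeThreshold, alpha = config$alpha,
         statistics = config$statistics,
         nullConstruction = "subject-label permutation, group sizes preserved, network statistic recomputed from correlation onward per shuffle",
         configMD5 = unname(tools::md5sum(cfgTmp))),
    file.path(cdir, "run_metadata.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  unlink(cfgTmp)
  .log(config, "compare", sprintf("rows=%d", nrow(tab)), t0)
  .writeManifest(config$outDir)
  invisible(tab)
}

#' Export filtration snapshots only
#'
#' @param config a \code{phnRunConfig}.
#' @return Invisibly, the written file paths.
#' @export
runSnapshots <- function(config) {
  t0 <- as.numeric(Sys.time())
  groups <- .loadGroups(config)
  paths <- .loadPathways(config)
  sdir <- file.path(config$outDir, "snapshots")
  if (!dir.exists(sdir)) dir.create(sdir, recursive = TRUE)
  files <- character(0)
  for (g in names(groups)) {
    for (pw in names(paths)) {
      sub <- extractPathway(groups[[g]], paths[[pw]])
      dist <- toDistance(pearsonMatrix(sub), mode = config$distanceMode)
      for (lam in config$snapshotLambdas) {
        f <- file.path(sdir, sprintf("%s_%s_snapshot_lambda%.2f.csv",
                                     g, pw, lam))
        writeSnapshotCSV(dist, lam, f)
        files <- c(files, f)
      }
      .log(config, "snapshots", sprintf("group=%s pathway=%s", g, pw), t0)
    }
  }
  .writeManifest(config$outDir)
  invisible(files)
}
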
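## io_cli: batch processing, deterministic CSV export, and table round-trips.
## The shell entry point (inst/cli/pollenquant) is a thin wrapper over these
## functions.

.IMAGE_PATTERN <- "\\.(png|tif|tiff|jpg|jpeg)$"

# deterministic image discovery: matching extensions, lexicographic order
.discoverImages <- function(inputPath) {
  if (dir.exists(inputPath)) {
    files <- list.files(inputPath, full.names = TRUE)
    files <- files[grepl(.IMAGE_PATTERN, files, ignore.case = TRUE)]
    sort(files)
  } else if (file.exists(inputPath)) {
    inputPath
  } else {
    stop("input path does not exist: ", inputPath)
  }
}

# fixed CSV dialect: comma-separated, '.' decimal point, header row, PV to
# two decimals, undefined PV as an empty field — byte-reproducible output.
.formatResults <- function(results) {
  data.frame(
    image_id = results$image_id,
    total_count = results$total_count,
    viable_count = results$viable_count,
    viability_pct = ifelse(is.na(results$viability_pct), "",
                           sprintf("%.2f", results$viability_pct)),
    scenario_name = results$scenario_name,
    error = if ("error" %in% names(results))
      ifelse(is.na(results$error), "", results$error) else "",
    stringsAsFactors = FALSE)
}

.checkOverwrite <- function(path, overwrite) {
  if (file.exists(path) && !overwrite)
    stop("output file exists (use overwrite = TRUE): ", path)
}

#' Write per-image results as CSV
#'
#' Fixed dialect: UTF-8, comma separator, header row, \code{.} decimal
#' separator, PV formatted to 2 decimals, undefined PV as an empty field.
#' Identical results always produce byte-identical files.
#'
#' @param results a result data.frame (from \code{\link{processImage}},
#'   \code{\link{runScenarios}} or \code{\link{batchProcess}}).
#' @param path output CSV path.
#' @param overwrite overwrite an existing file? Default FALSE.
#' @return \code{path}, invisibly.
#' @export
writeResultsCsv <- function(results, path, overwrite = FALSE) {
  .checkOverwrite(path, overwrite)
  utils::write.csv(.formatResults(results), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a results CSV back into result records
#'
#' Inverse of \code{\link{writeResultsCsv}}: empty PV fields become
#' \code{NA}, and the derived \code{pv_over_100} flag is recomputed.
#'
#' @param path CSV path.
#' @return A result data.frame.
#' @export
readResultsCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(image_id = "character",
                                      scenario_name = "character"))
  d$viability_pct <- suppressWarnings(as.numeric(d$viability_pct))
  d$pv_over_100 <- !is.na(d$viability_pct) & d$viability_pct > 100
  if (!"error" %in% names(d)) d$error <- NA_character_
  d$error[!is.na(d$error) & d$error == ""] <- NA_character_
  d[, c("image_id", "scenario_name", "total_count", "viable_count",
        "viability_pct", "pv_over_100", "error")]
}

#' Read an image-to-group mapping
#'
#' CSV with header \code{image_id, group} (e.g. genotype labels).
#'
#' @param path CSV path.
#' @return A data.frame with columns \code{image_id} and \code{group}.
#' @export
readGroupMap <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "group") %in% names(g)))
    stop("group CSV must have columns: image_id, group")
  g
}

#' Batch-process a directory (or single file) of micrographs
#'
#' Discovers readable images (*.png, *.tif, *.tiff, *.jpg, *.jpeg;
#' case-insensitive, lexicographic order), runs each through the counting
#' pipeline under the given scenario(s), and writes one result row per image
#' and scenario to \code{outputCsv}. A failure on an individual image is
#' recorded in its \code{error} field and does not abort the run. When a
#' manual-count CSV is supplied the scenario evaluation
#' (\code{\link{evaluateScenarios}}) is run as well and written next to the
#' results; when a group CSV is supplied, per-group summaries
#' (\code{\link{summarizeByGroup}}) are written likewise.
#'
#' @param inputPath image file or directory.
#' @param scenario a scenario name, a \linkS4class{ScenarioSpec}, or a list
#'   of them (default "S1", the optimized parameterization).
#' @param config a \linkS4class{PipelineConfig}.
#' @param outputCsv results CSV path.
#' @param manualCsv optional manual-count CSV
#'   (\code{image_id, manual_total, manual_viable}); triggers scenario
#'   evaluation, written to \code{<outputCsv stem>_evaluation.csv}.
#' @param groupCsv optional group-map CSV (\code{image_id, group}); triggers
#'   per-group summaries, written to \code{<outputCsv stem>_groups.csv}
#'   (first scenario only).
#' @param overwrite overwrite existing output files? Default FALSE.
#' @return Invisibly, a list with \code{results} and (when computed)
#'   \code{evaluation} and \code{groups}.
#' @export
batchProcess <- function(inputPath, scenario = "S1",
                         config = pipelineConfig(), outputCsv,
                         manualCsv = NULL, groupCsv = NULL,
                         overwrite = FALSE) {
  scenarios <- if (is.character(scenario))
    lapply(scenario, function(s) resolveScenario(s))
  else if (is(scenario, "ScenarioSpec")) list(scenario)
  else scenario
  stopifnot(all(vapply(scenarios, is, logical(1), "ScenarioSpec")))
  .checkOverwrite(outputCsv, overwrite)

  files <- .discoverImages(inputPath)
  if (!length(files)) stop("no readable images under: ", inputPath)
  images <- lapply(files, function(f) {
    tryCatch(readPollenImage(f), error = function(e) {
      structure(list(id = sub("\\.[^.]+$", "", basename(f)),
                     message = conditionMessage(e)),
                class = "pollenReadError")
    })
  })
  ok <- !vapply(images, inherits, logical(1), "pollenReadError")
  if (!any(ok)) stop("no readable images under: ", inputPath)

  results <- runScenarios(images[ok], scenarios, config)
  for (bad in images[!ok]) {
    for (sc in scenarios)
      results <- rbind(results, data.frame(
        image_id = bad$id, scenario_name = sc@name,
        total_count = NA_integer_, viable_count = NA_integer_,
        viability_pct = NA_real_, pv_over_100 = NA, error = bad$message,
        stringsAsFactors = FALSE))
  }
  results <- results[order(results$image_id, results$scenario_name), ,
                     drop = FALSE]
  rownames(results) <- NULL
  writeResultsCsv(results, outputCsv, overwrite = overwrite)
  out <- list(results = results)

  stem <- sub("\\.csv$", "", outputCsv)
  if (!is.null(manualCsv)) {
    evals <- evaluateScenarios(results, readManualCounts(manualCsv))
    evalPath <- paste0(stem, "_evaluation.csv")
    .checkOverwrite(evalPath, overwrite)
    utils::write.csv(evals, evalPath, row.names = FALSE,
                     fileEncoding = "UTF-8")
    out$evaluation <- evals
  }
  if (!is.null(groupCsv)) {
    first <- results[results$scenario_name == scenarios[[1L]]@name &
                       is.na(results$error), , drop = FALSE]
    groups <- summarizeByGroup(first, readGroupMap(groupCsv))
    groupPath <- paste0(stem, "_groups.csv")
    .checkOverwrite(groupPath, overwrite)
    utils::write.csv(groups, groupPath, row.names = FALSE,
                     fileEncoding = "UTF-8")
    out$groups <- groups
  }
  invisible(out)
}
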
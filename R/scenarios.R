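## scenario_eval: the parameter-optimization procedure — sweep the scenario
## catalog over an image set, correlate automatic with manual counts, rank
## scenarios, and summarize counts by group (e.g. genotype).

#' The scenario catalog
#'
#' The seven filter parameterizations evaluated when optimizing the counter:
#' S0, the original tool's asymmetric setting (red/total size window 60-800
#' px^2, green/viable 100-800 px^2, circularity 0.4-1 on both), and S1-S6,
#' the 2 x 3 grid of size windows {100-900, 200-900} px^2 by circularity
#' windows {0.4-1, 0.5-1, 0.6-1}, applied identically to both channels.
#'
#' @return A named list of 7 \linkS4class{ScenarioSpec}s, "S0" to "S6".
#' @examples
#' names(scenarioCatalog())
#' scenarioCatalog()[["S1"]]
#' @export
scenarioCatalog <- function() {
  cat <- list(scenarioSpec("S0",
                           redFilter = particleFilter(60, 800, 0.4, 1),
                           greenFilter = particleFilter(100, 800, 0.4, 1)))
  sizes <- list(c(100, 900), c(200, 900))
  circs <- list(c(0.4, 1), c(0.5, 1), c(0.6, 1))
  k <- 1L
  for (circ in circs) {
    for (size in sizes) {
      cat[[length(cat) + 1L]] <- scenarioSpec(
        paste0("S", k), particleFilter(size[1], size[2], circ[1], circ[2]))
      k <- k + 1L
    }
  }
  names(cat) <- vapply(cat, scenarioName, character(1))
  cat
}

#' Resolve a scenario by name or explicit bounds
#'
#' Either looks a name up in \code{\link{scenarioCatalog}} or builds a
#' symmetric scenario from explicit size/circularity bounds (all four
#' required together).
#'
#' @param name catalog scenario name ("S0".."S6"), or NULL when giving
#'   explicit bounds.
#' @param sizeMin,sizeMax,circMin,circMax explicit window bounds.
#' @return A \linkS4class{ScenarioSpec}.
#' @examples
#' resolveScenario("S1")
#' resolveScenario(sizeMin = 120, sizeMax = 700, circMin = 0.5, circMax = 1)
#' @export
resolveScenario <- function(name = NULL, sizeMin = NULL, sizeMax = NULL,
                            circMin = NULL, circMax = NULL) {
  if (!is.null(name)) {
    cat <- scenarioCatalog()
    if (!name %in% names(cat))
      stop("unknown scenario '", name, "'; available: ",
           paste(names(cat), collapse = ", "))
    return(cat[[name]])
  }
  bounds <- list(sizeMin = sizeMin, sizeMax = sizeMax,
                 circMin = circMin, circMax = circMax)
  missing <- names(bounds)[vapply(bounds, is.null, logical(1))]
  if (length(missing))
    stop("explicit scenario needs all bounds; missing: ",
         paste(missing, collapse = ", "))
  if (sizeMin > sizeMax)
    stop(sprintf("inverted size interval [%s, %s]", sizeMin, sizeMax))
  if (circMin > circMax)
    stop(sprintf("inverted circularity interval [%s, %s]", circMin, circMax))
  scenarioSpec(sprintf("custom(%g-%g;%g-%g)", sizeMin, sizeMax, circMin,
                       circMax),
               particleFilter(sizeMin, sizeMax, circMin, circMax))
}

#' Run a scenario sweep over an image set
#'
#' Produces one \code{ImageCountResult} row per image x scenario. The
#' segmentation (background subtraction through particle measurement) is
#' scenario-independent, so each image is segmented once and only the
#' size/circularity filters differ between scenarios; the results are
#' identical to calling \code{\link{processImage}} per pair. Failures on
#' individual images are recorded in the \code{error} column and do not abort
#' the sweep.
#'
#' @param images list of \linkS4class{RgbImage}s.
#' @param scenarios list of \linkS4class{ScenarioSpec}s (default: the full
#'   catalog).
#' @param config a \linkS4class{PipelineConfig}.
#' @return A data.frame with one row per (image, scenario): columns
#'   \code{image_id}, \code{scenario_name}, \code{total_count},
#'   \code{viable_count}, \code{viability_pct}, \code{pv_over_100},
#'   \code{error} (NA when the image processed cleanly).
#' @export
runScenarios <- function(images, scenarios = scenarioCatalog(),
                         config = pipelineConfig()) {
  if (!length(images)) stop("no images supplied")
  if (!length(scenarios)) {
    return(data.frame(image_id = character(), scenario_name = character(),
                      total_count = integer(), viable_count = integer(),
                      viability_pct = numeric(), pv_over_100 = logical(),
                      error = character(), stringsAsFactors = FALSE))
  }
  rows <- vector("list", length(images) * length(scenarios))
  k <- 1L
  nFailed <- 0L
  for (img in images) {
    parts <- tryCatch(.channelParticles(img, config), error = function(e) e)
    for (sc in scenarios) {
      if (inherits(parts, "error")) {
        rows[[k]] <- data.frame(
          image_id = if (is(img, "RgbImage")) img@id else NA_character_,
          scenario_name = sc@name, total_count = NA_integer_,
          viable_count = NA_integer_, viability_pct = NA_real_,
          pv_over_100 = NA, error = conditionMessage(parts),
          stringsAsFactors = FALSE)
      } else {
        r <- .countResult(img@id, sc, parts)
        r$error <- NA_character_
        rows[[k]] <- r
      }
      k <- k + 1L
    }
    if (inherits(parts, "error")) nFailed <- nFailed + 1L
  }
  if (nFailed == length(images))
    stop("all ", nFailed, " images failed to process")
  do.call(rbind, rows)
}

#' Pearson correlation with a two-sided p-value
#'
#' The product-moment correlation computed by direct summation,
#' r = sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2)
#' sum((y - mean(y))^2)), with the two-sided p-value from the t transform
#' t = r sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return A list with elements \code{r}, \code{p} and \code{n}.
#' @examples
#' pearsonCorrelation(1:4, c(2, 4, 5, 9))
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx * dx); syy <- sum(dy * dy)
  if (sxx == 0 || syy == 0)
    stop("undefined correlation: a vector has zero variance")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  n <- length(x)
  p <- if (abs(r) == 1) 0
  else 2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Read a manual-count table
#'
#' CSV with header \code{image_id, manual_total, manual_viable} (UTF-8,
#' comma-separated): the per-image human tally of all grains and of darkly
#' stained (viable) grains.
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
readManualCounts <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "manual_total", "manual_viable")
  if (!all(need %in% names(m)))
    stop("manual-count CSV must have columns: ", paste(need, collapse = ", "))
  if (any(m$manual_viable > m$manual_total))
    stop("manual_viable exceeds manual_total for image(s): ",
         paste(m$image_id[m$manual_viable > m$manual_total], collapse = ", "))
  if (any(m$manual_total < 0) || any(m$manual_viable < 0))
    stop("manual counts must be non-negative")
  m
}

#' Correlate scenario results with manual counts
#'
#' For each scenario, Pearson-correlates automatic total counts with manual
#' total counts (\code{r_count}) and automatic PV with manual PV
#' (\code{r_viability}), with two-sided p-values. Images whose automatic PV
#' is undefined (zero total) or whose manual total is zero are excluded
#' pairwise from the viability correlation and counted in
#' \code{n_pv_excluded}; optionally, images with automatic PV above 100 can
#' be excluded too. Scenarios with fewer than 3 usable pairs, or with
#' zero-variance pairs, are flagged undefined rather than dropped.
#'
#' @param results a sweep table from \code{\link{runScenarios}}.
#' @param manual a manual-count data.frame
#'   (\code{\link{readManualCounts}}).
#' @param includeOver100 keep images whose automatic PV exceeds 100 percent
#'   in the viability correlation? Default TRUE.
#' @return A data.frame with one row per scenario: \code{scenario_name},
#'   \code{r_count}, \code{p_count}, \code{r_viability}, \code{p_viability},
#'   \code{n_images}, \code{n_pv_excluded}, \code{defined}.
#' @export
evaluateScenarios <- function(results, manual, includeOver100 = TRUE) {
  ok <- is.na(results$error)
  results <- results[ok, , drop = FALSE]
  missing <- setdiff(unique(results$image_id), manual$image_id)
  if (length(missing))
    stop("no manual counts for image(s): ", paste(missing, collapse = ", "))
  manual$manual_pv <- ifelse(manual$manual_total > 0,
                             100 * manual$manual_viable / manual$manual_total,
                             NA_real_)
  scenarios <- unique(results$scenario_name)
  rows <- lapply(scenarios, function(sn) {
    sub <- results[results$scenario_name == sn, , drop = FALSE]
    i <- match(sub$image_id, manual$image_id)
    mt <- manual$manual_total[i]
    mpv <- manual$manual_pv[i]
    cc <- tryCatch(pearsonCorrelation(sub$total_count, mt),
                   error = function(e) NULL)
    usable <- !is.na(sub$viability_pct) & !is.na(mpv)
    if (!includeOver100) usable <- usable & sub$viability_pct <= 100
    cv <- if (sum(usable) >= 3L)
      tryCatch(pearsonCorrelation(sub$viability_pct[usable], mpv[usable]),
               error = function(e) NULL)
    else NULL
    data.frame(scenario_name = sn,
               r_count = if (is.null(cc)) NA_real_ else cc$r,
               p_count = if (is.null(cc)) NA_real_ else cc$p,
               r_viability = if (is.null(cv)) NA_real_ else cv$r,
               p_viability = if (is.null(cv)) NA_real_ else cv$p,
               n_images = nrow(sub),
               n_pv_excluded = sum(!usable),
               defined = !is.null(cc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the best-performing scenario
#'
#' The scenario maximizing the count correlation \code{r_count}; ties are
#' broken by the viability correlation \code{r_viability} (undefined treated
#' as lowest), then by scenario name. The count correlation leads because
#' every downstream quantity (including PV) derives from the counts.
#'
#' @param evals an evaluation table from \code{\link{evaluateScenarios}}.
#' @return The winning scenario name (character).
#' @export
selectBestScenario <- function(evals) {
  ok <- evals[evals$defined & !is.na(evals$r_count), , drop = FALSE]
  if (!nrow(ok)) stop("no defined scenario evaluations to select from")
  rv <- ifelse(is.na(ok$r_viability), -Inf, ok$r_viability)
  ord <- order(-ok$r_count, -rv, ok$scenario_name)
  ok$scenario_name[ord[1L]]
}

#' Summarize counts and viability by group
#'
#' Per-group (e.g. per-genotype) summaries of total pollen count and PV:
#' n, mean, sample SD (n - 1 denominator), min and max. Rows with undefined
#' PV are excluded from the PV statistics and counted.
#'
#' @param results per-image result rows (a data.frame with \code{image_id},
#'   \code{total_count}, \code{viability_pct}), typically from
#'   \code{\link{runScenarios}} under one scenario.
#' @param groups mapping of image ids to group labels: a named character
#'   vector, or a data.frame with columns \code{image_id} and \code{group}.
#' @return A data.frame with one row per group: \code{group}, \code{n},
#'   \code{count_mean}, \code{count_sd}, \code{count_min}, \code{count_max},
#'   \code{pv_mean}, \code{pv_sd}, \code{pv_min}, \code{pv_max},
#'   \code{n_pv_excluded}.
#' @export
summarizeByGroup <- function(results, groups) {
  if (is.data.frame(groups)) {
    if (!all(c("image_id", "group") %in% names(groups)))
      stop("groups data.frame must have columns image_id and group")
    map <- stats::setNames(as.character(groups$group),
                           as.character(groups$image_id))
  } else {
    map <- groups
  }
  unmapped <- setdiff(unique(results$image_id), names(map))
  if (length(unmapped))
    stop("image(s) not mapped to a group: ", paste(unmapped, collapse = ", "))
  results$group <- unname(map[results$image_id])
  stat <- function(v, f) if (length(v)) f(v) else NA_real_
  rows <- lapply(split(results, results$group), function(sub) {
    pv <- sub$viability_pct[!is.na(sub$viability_pct)]
    data.frame(group = sub$group[1L], n = nrow(sub),
               count_mean = stat(sub$total_count, mean),
               count_sd = if (nrow(sub) > 1L) stats::sd(sub$total_count)
                          else NA_real_,
               count_min = stat(sub$total_count, min),
               count_max = stat(sub$total_count, max),
               pv_mean = stat(pv, mean),
               pv_sd = if (length(pv) > 1L) stats::sd(pv) else NA_real_,
               pv_min = stat(pv, min), pv_max = stat(pv, max),
               n_pv_excluded = sum(is.na(sub$viability_pct)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # keep rows (n = 0) for mapped groups that produced no results
  absent <- setdiff(unique(unname(map)), out$group)
  for (g in absent)
    out <- rbind(out, data.frame(group = g, n = 0L, count_mean = NA_real_,
                                 count_sd = NA_real_, count_min = NA_real_,
                                 count_max = NA_real_, pv_mean = NA_real_,
                                 pv_sd = NA_real_, pv_min = NA_real_,
                                 pv_max = NA_real_, n_pv_excluded = 0L,
                                 stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}
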
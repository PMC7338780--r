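## pipeline: the image-processing chain from raw micrograph to per-image
## counts: (contrast) -> background subtraction -> channel split -> binarize
## -> dilate/fill/erode -> watershed -> measure -> filter -> counts -> PV.

# matrix <-> EBImage adapters. EBImage indexes (x, y); all operations used
# here (morphology with symmetric brushes, distance transform, watershed,
# hole filling) are orientation-symmetric, so matrices are passed through
# without transposition.
.eb <- function(m) EBImage::Image(m)
.ebMat <- function(img) {
  m <- EBImage::imageData(img)
  dim(m) <- dim(m)[1:2]
  m
}

#' Read a micrograph from file
#'
#' Reads an 8-bit RGB raster (TIFF, PNG or JPEG) into an
#' \linkS4class{RgbImage}. Grayscale input is replicated across channels; an
#' alpha channel is dropped.
#'
#' @param path path to the image file.
#' @param id image identifier; defaults to the file name without extension.
#' @return An \linkS4class{RgbImage} with intensities in \[0, 255\].
#' @export
readPollenImage <- function(path,
                            id = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image '", path, "': ",
                                           conditionMessage(e)))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] < 3L) stop("expected an RGB image: ", path)
  px <- aperm(a, c(2L, 1L, 3L)) * 255      # EBImage is (x, y); we use (row, col)
  px[px < 0] <- 0; px[px > 255] <- 255
  rgbImage(px, id = id)
}

#' Rolling-ball background subtraction
#'
#' Estimates the smoothly varying illumination field of each channel as the
#' grayscale morphological closing with a disc structuring element of the
#' given radius (the surface traced over dark objects by a ball too large to
#' enter them), subtracts it, and restores the channel's median background
#' level, so an already-flat image passes through (almost) unchanged while
#' illumination gradients are removed. The radius must exceed the grain
#' radius, otherwise grains are absorbed into the background estimate.
#'
#' @param image an \linkS4class{RgbImage}.
#' @param radius ball radius in pixels; must be positive and smaller than the
#'   shorter image side.
#' @return An \linkS4class{RgbImage} of identical size, intensities in
#'   \[0, 255\].
#' @export
subtractBackground <- function(image, radius = 50) {
  stopifnot(is(image, "RgbImage"))
  d <- dim(image@pixels)
  if (radius <= 0) stop("background radius must be positive")
  if (radius >= min(d[1:2]))
    stop(sprintf("background radius %g px must be smaller than the image (%d x %d)",
                 radius, d[1], d[2]))
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- image@pixels
  for (ch in 1:3) {
    plane <- .eb(image@pixels[, , ch])
    bg <- .ebMat(EBImage::erode(EBImage::dilate(plane, brush), brush))
    v <- image@pixels[, , ch] - bg + stats::median(bg)
    v[v < 0] <- 0; v[v > 255] <- 255
    out[, , ch] <- v
  }
  rgbImage(out, id = image@id)
}

#' Linear contrast enhancement with tail saturation
#'
#' Per-channel linear rescaling such that the requested percentage of pixels
#' saturates, half at each intensity tail, with output clipped to \[0, 255\].
#' With 0 percent, the channel range is stretched to the full scale. Constant
#' channels are returned unchanged. This is an optional rescue step for
#' weakly stained slides; over-applying it can make lightly stained
#' (non-viable) grains register in the green channel and inflate the viable
#' count, so it is off by default in \code{\link{pipelineConfig}}.
#'
#' @param image an \linkS4class{RgbImage}.
#' @param saturatedPct percentage of pixels to saturate, in \[0, 100).
#' @return The rescaled \linkS4class{RgbImage}.
#' @export
enhanceContrast <- function(image, saturatedPct = 0.35) {
  stopifnot(is(image, "RgbImage"))
  if (saturatedPct < 0 || saturatedPct >= 100)
    stop("saturatedPct must be in [0, 100)")
  out <- image@pixels
  for (ch in 1:3) {
    v <- image@pixels[, , ch]
    s <- sort(as.vector(v))
    n <- length(s)
    k <- min(floor(n * saturatedPct / 200), floor((n - 1) / 2))
    lo <- s[k + 1L]
    hi <- s[n - k]
    if (hi <= lo) next                      # zero dynamic range: leave as is
    w <- (v - lo) * 255 / (hi - lo)
    w[w < 0] <- 0; w[w > 255] <- 255
    out[, , ch] <- w
  }
  rgbImage(out, id = image@id)
}

#' Split an RGB image into channel planes
#'
#' The red plane carries all stained grains (both stain classes are dark in
#' red) and is used for the total pollen count; the green plane is dark only
#' for darkly stained (viable) grains and is used for the viable count; the
#' blue plane is returned for completeness but unused downstream.
#'
#' @param image an \linkS4class{RgbImage}.
#' @return A named list of three \linkS4class{GrayImage}s: \code{red},
#'   \code{green}, \code{blue}.
#' @export
splitChannels <- function(image) {
  stopifnot(is(image, "RgbImage"))
  list(red = grayImage(image@pixels[, , 1], "red"),
       green = grayImage(image@pixels[, , 2], "green"),
       blue = grayImage(image@pixels[, , 3], "blue"))
}

# IsoData (iterative intermeans) threshold on an 8-bit intensity vector:
# t <- (mean below t + mean above t)/2 iterated to a fixed point from the
# global mean. Degenerate (constant) input returns the minimum so that
# strictly-below-threshold foreground is empty.
.isodataThreshold <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi - lo < 1) return(lo)
  h <- tabulate(as.integer(round(v)) + 1L, 256L)
  g <- 0:255
  t <- sum(g * h) / sum(h)
  for (i in 1:100) {
    below <- g <= t
    wb <- sum(h[below]); wa <- sum(h[!below])
    if (wb == 0 || wa == 0) break
    t2 <- (sum(g[below] * h[below]) / wb + sum(g[!below] * h[!below]) / wa) / 2
    if (abs(t2 - t) < 0.25) { t <- t2; break }
    t <- t2
  }
  t
}

.autoThreshold <- function(px, method) {
  v <- as.vector(px)
  switch(method,
    isodata = .isodataThreshold(v),
    otsu = {
      if (max(v) - min(v) < 1) min(v)
      else EBImage::otsu(.eb(px / 255), range = c(0, 1), levels = 256L) * 255
    },
    stop("unknown threshold method '", method,
         "'; available: isodata, otsu"))
}

#' Binarize a channel plane by auto-thresholding
#'
#' Computes a global threshold from the intensity histogram by the named
#' method and marks as foreground the pixels strictly below it: stained
#' pollen is dark in its diagnostic channel. A constant (zero-contrast)
#' channel yields an empty foreground.
#'
#' Histogram auto-thresholds always split off the darkest mode, even when no
#' stained object is present (a blank channel thresholds inside its sensor
#' noise; a channel containing only lightly stained grains splits them from
#' the background although their stain contrast is far below that of a
#' genuinely dark stain). Since stain classes are distinguished by strong
#' contrast, the split is therefore accepted only when the background mean
#' exceeds the foreground mean by at least \code{minContrast} intensity
#' levels; otherwise the channel is declared signal-free and the mask is
#' empty. Set \code{minContrast = 0} to disable the guard.
#'
#' @param channel a \linkS4class{GrayImage}.
#' @param method "isodata" (iterative intermeans; default) or "otsu".
#' @param minContrast minimum background-to-foreground contrast in intensity
#'   levels (default 50).
#' @return A \linkS4class{BinaryMask} of the same size.
#' @export
binarize <- function(channel, method = "isodata", minContrast = 50) {
  stopifnot(is(channel, "GrayImage"))
  px <- channel@pixels
  thr <- .autoThreshold(px, method)
  fg <- px < thr
  if (any(fg) && !all(fg) && minContrast > 0 &&
      mean(px[!fg]) - mean(px[fg]) < minContrast)
    fg[] <- FALSE
  binaryMask(fg)
}

#' Morphological mask refinement: dilate, fill holes, erode
#'
#' Applies the given number of dilation passes with a 3x3 square structuring
#' element, fills interior holes, then applies the same number of erosion
#' passes — the standard clean-up that closes thin gaps and removes
#' stain-centre holes while approximately preserving object outlines.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param iterations number of dilate and of erode passes.
#' @return The refined \linkS4class{BinaryMask}.
#' @export
refineMask <- function(mask, iterations = 1L) {
  stopifnot(is(mask, "BinaryMask"), iterations >= 1L)
  brush <- EBImage::makeBrush(3L, shape = "box")
  m <- .eb(mask@pixels * 1)
  for (i in seq_len(iterations)) m <- EBImage::dilate(m, brush)
  m <- EBImage::fillHull(m)
  for (i in seq_len(iterations)) m <- EBImage::erode(m, brush)
  binaryMask(.ebMat(m) > 0.5)
}

#' Separate touching objects by distance-transform watershed
#'
#' Computes the Euclidean distance transform of the foreground and applies
#' the watershed transform to its inverse, seeded at distance-map local
#' maxima (detected in a 5x5 neighbourhood, i.e. a minimum peak separation of
#' about 5 px, with sub-unit maxima plateaus merged), so clusters of touching
#' convex grains are split along the ridges between their distance peaks.
#' Non-touching objects are labelled unchanged.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param connectivity 4 or 8: foreground connectivity for labelling. The
#'   watershed transform itself joins diagonal neighbours (8-connectivity,
#'   the default); with 4, labels are additionally split into 4-connected
#'   components.
#' @return A \linkS4class{LabelImage}; one label per putative grain.
#' @export
watershedSplit <- function(mask, connectivity = 8L) {
  stopifnot(is(mask, "BinaryMask"), connectivity %in% c(4L, 8L))
  if (!any(mask@pixels))
    return(labelImage(matrix(0L, nrow(mask@pixels), ncol(mask@pixels))))
  dm <- EBImage::distmap(.eb(mask@pixels * 1))
  w <- .ebMat(EBImage::watershed(dm, tolerance = 1, ext = 2))
  if (connectivity == 4L) {
    comp4 <- .ebMat(EBImage::bwlabel(.eb(mask@pixels * 1)))  # 4-connected
    w <- w * (max(comp4) + 1) + comp4
    w[!mask@pixels] <- 0
  }
  labelImage(w)
}

#' Count filtered particles in one channel plane
#'
#' The per-channel composition \code{\link{binarize}} ->
#' \code{\link{refineMask}} -> \code{\link{watershedSplit}} ->
#' \code{\link{measureParticles}} -> \code{\link{filterParticles}}.
#'
#' @param channel a \linkS4class{GrayImage}.
#' @param filter the \linkS4class{ParticleFilter} for this channel.
#' @param config a \linkS4class{PipelineConfig}.
#' @return A list with \code{count} (number of surviving particles) and
#'   \code{particles} (their measurement data.frame).
#' @export
countChannel <- function(channel, filter, config = pipelineConfig()) {
  stopifnot(is(channel, "GrayImage"), is(filter, "ParticleFilter"),
            is(config, "PipelineConfig"))
  parts <- .measureChannel(channel, config)
  kept <- filterParticles(parts, filter)
  list(count = nrow(kept), particles = kept)
}

# binarize -> refine -> watershed -> measure (+ optional edge exclusion);
# the scenario-independent part of the per-channel chain.
.measureChannel <- function(channel, config) {
  mask <- binarize(channel, config@thresholdMethod, config@minContrast)
  mask <- refineMask(mask, config@morphIterations)
  labels <- watershedSplit(mask, config@connectivity)
  parts <- measureParticles(labels)
  if (config@excludeEdges) parts <- parts[!parts$touchesEdge, , drop = FALSE]
  parts
}

# contrast (optional) -> background subtraction -> split -> measure red and
# green. Scenario-independent, so scenario sweeps can reuse it.
.channelParticles <- function(image, config) {
  if (!is.na(config@contrastSaturation))
    image <- enhanceContrast(image, config@contrastSaturation)
  image <- subtractBackground(image, config@backgroundRadius)
  ch <- splitChannels(image)
  list(red = .measureChannel(ch$red, config),
       green = .measureChannel(ch$green, config))
}

#' Percent pollen viability
#'
#' PV = 100 * viable / total. With a zero total the result is the undefined
#' marker \code{NA} (distinguishing "no pollen seen" from "0 percent
#' viable"), not an error. Values above 100 — a real failure mode when the
#' viable (green-channel) count overshoots the total (red-channel) count —
#' are returned as-is with a warning so they surface in downstream checks.
#'
#' @param viableCount,totalCount non-negative integer counts.
#' @return PV in percent, or \code{NA} when \code{totalCount} is 0.
#' @examples
#' percentViability(50, 100)   # 50
#' percentViability(0, 0)      # NA
#' @export
percentViability <- function(viableCount, totalCount) {
  if (length(viableCount) != 1L || length(totalCount) != 1L ||
      is.na(viableCount) || is.na(totalCount) ||
      viableCount < 0 || totalCount < 0)
    stop("counts must be single non-negative numbers")
  if (totalCount == 0) return(NA_real_)
  pv <- 100 * viableCount / totalCount
  if (pv > 100)
    warning(sprintf("viability %.1f%% exceeds 100%%: viable count %d > total count %d",
                    pv, as.integer(viableCount), as.integer(totalCount)))
  pv
}

#' Process one micrograph under a scenario
#'
#' Runs the full chain — optional contrast enhancement, background
#' subtraction, channel split, then per-channel binarize / refine / watershed
#' / measure / filter — and assembles the per-image result: the red-channel
#' particle count is the total pollen number, the green-channel count the
#' viable pollen number, and PV their ratio in percent.
#'
#' @param image an \linkS4class{RgbImage}.
#' @param scenario a \linkS4class{ScenarioSpec} (see
#'   \code{\link{scenarioCatalog}}).
#' @param config a \linkS4class{PipelineConfig}.
#' @return A one-row data.frame with columns \code{image_id},
#'   \code{scenario_name}, \code{total_count}, \code{viable_count},
#'   \code{viability_pct} (\code{NA} when no pollen is detected) and
#'   \code{pv_over_100} (logical flag).
#' @export
processImage <- function(image, scenario, config = pipelineConfig()) {
  stopifnot(is(image, "RgbImage"), is(scenario, "ScenarioSpec"),
            is(config, "PipelineConfig"))
  parts <- .channelParticles(image, config)
  .countResult(image@id, scenario, parts)
}

# assemble an ImageCountResult row from measured red/green particle tables
.countResult <- function(imageId, scenario, parts) {
  total <- nrow(filterParticles(parts$red, scenario@redFilter))
  viable <- nrow(filterParticles(parts$green, scenario@greenFilter))
  pv <- suppressWarnings(percentViability(viable, total))
  data.frame(image_id = imageId, scenario_name = scenario@name,
             total_count = total, viable_count = viable,
             viability_pct = pv,
             pv_over_100 = !is.na(pv) && pv > 100,
             stringsAsFactors = FALSE)
}
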
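#' @import methods
NULL

## ---------------------------------------------------------------------------
## Raster containers
##
## Pixels are stored as base matrices/arrays in (row, col) orientation with
## 8-bit intensities on [0, 255]. Reported coordinates are (row, col), 0-based.
## ---------------------------------------------------------------------------

#' RgbImage: a 3-channel 8-bit micrograph
#'
#' The pipeline's input container: a height x width x 3 numeric array of
#' intensities in \[0, 255\] (channel order red, green, blue) plus an image
#' identifier used to key results.
#'
#' @slot pixels numeric array, height x width x 3, values in \[0, 255\].
#' @slot id character(1) image identifier.
#' @exportClass RgbImage
setClass("RgbImage",
  representation(pixels = "array", id = "character"),
  validity = function(object) {
    p <- object@pixels
    if (length(dim(p)) != 3L || dim(p)[3] != 3L)
      return("pixels must be a height x width x 3 array")
    if (dim(p)[1] < 1L || dim(p)[2] < 1L)
      return("image must be at least 1 x 1")
    if (anyNA(p) || min(p) < 0 || max(p) > 255)
      return("intensities must lie in [0, 255]")
    if (length(object@id) != 1L) return("id must be a single string")
    TRUE
  })

#' GrayImage: a single-channel 8-bit plane
#'
#' @slot pixels numeric matrix, height x width, values in \[0, 255\].
#' @slot channelTag one of "red", "green", "blue", "none": which channel of an
#'   RGB source this plane was split from.
#' @exportClass GrayImage
setClass("GrayImage",
  representation(pixels = "matrix", channelTag = "character"),
  validity = function(object) {
    p <- object@pixels
    if (anyNA(p) || min(p) < 0 || max(p) > 255)
      return("intensities must lie in [0, 255]")
    if (!object@channelTag %in% c("red", "green", "blue", "none"))
      return("channelTag must be one of red/green/blue/none")
    TRUE
  })

#' BinaryMask: foreground/background raster
#'
#' @slot pixels logical matrix; TRUE marks foreground.
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(pixels = "matrix"),
  validity = function(object) {
    if (!is.logical(object@pixels)) return("pixels must be logical")
    if (anyNA(object@pixels)) return("pixels must not contain NA")
    TRUE
  })

#' LabelImage: labelled connected objects
#'
#' Non-negative integer raster; 0 is background and positive labels form the
#' contiguous set 1..nLabels.
#'
#' @slot pixels integer matrix of labels.
#' @slot nLabels integer(1), number of distinct positive labels.
#' @exportClass LabelImage
setClass("LabelImage",
  representation(pixels = "matrix", nLabels = "integer"),
  validity = function(object) {
    p <- object@pixels
    if (anyNA(p) || min(p) < 0) return("labels must be non-negative")
    u <- sort(unique(as.integer(p[p > 0])))
    if (length(u) != object@nLabels)
      return("nLabels must equal the number of distinct positive labels")
    if (length(u) && !identical(u, seq_len(object@nLabels)))
      return("positive labels must form the contiguous set 1..nLabels")
    TRUE
  })

## ---------------------------------------------------------------------------
## Filter / scenario / configuration parameter bundles
## ---------------------------------------------------------------------------

#' ParticleFilter: a size and circularity window
#'
#' Particles are retained when sizeMin <= area <= sizeMax and
#' circMin <= circularity <= circMax; all bounds are inclusive (the windows
#' are printed as closed intervals, e.g. 100-900 and 0.4-1).
#'
#' @slot sizeMin,sizeMax numeric(1) area bounds in pixel^2.
#' @slot circMin,circMax numeric(1) circularity bounds in \[0, 1\].
#' @exportClass ParticleFilter
setClass("ParticleFilter",
  representation(sizeMin = "numeric", sizeMax = "numeric",
                 circMin = "numeric", circMax = "numeric"),
  validity = function(object) {
    if (object@sizeMin < 0 || object@sizeMin > object@sizeMax)
      return(sprintf("invalid size interval [%s, %s]: need 0 <= sizeMin <= sizeMax",
                     object@sizeMin, object@sizeMax))
    if (object@circMin < 0 || object@circMin > object@circMax ||
        object@circMax > 1)
      return(sprintf("invalid circularity interval [%s, %s]: need 0 <= circMin <= circMax <= 1",
                     object@circMin, object@circMax))
    TRUE
  })

#' ScenarioSpec: a named pair of per-channel particle filters
#'
#' The red-channel filter selects particles counted as total pollen; the
#' green-channel filter selects particles counted as viable pollen.
#'
#' @slot name character(1) scenario name (e.g. "S1").
#' @slot redFilter,greenFilter \linkS4class{ParticleFilter} objects.
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  representation(name = "character",
                 redFilter = "ParticleFilter", greenFilter = "ParticleFilter"),
  validity = function(object) {
    if (length(object@name) != 1L || !nzchar(object@name))
      return("name must be a non-empty string")
    TRUE
  })

#' PipelineConfig: tunable parameters of the image-processing chain
#'
#' @slot backgroundRadius numeric(1) rolling-ball radius (pixels) for
#'   background subtraction; must exceed the grain radius.
#' @slot thresholdMethod character(1), "isodata" (iterative intermeans,
#'   default) or "otsu".
#' @slot morphIterations integer(1) dilate/erode iterations (3x3 element).
#' @slot connectivity integer(1), 4 or 8, foreground connectivity.
#' @slot excludeEdges logical(1); drop border-touching particles when TRUE.
#' @slot contrastSaturation numeric(1) percent of pixels saturated by the
#'   optional contrast-enhancement step, or NA to skip it (the default: the
#'   step is a documented rescue for weakly stained images and can inflate
#'   viable counts when overused).
#' @slot minContrast numeric(1) minimum stain contrast (intensity levels)
#'   between background and below-threshold foreground for the foreground to
#'   be accepted during binarization; shallower splits are treated as
#'   no-signal (see \code{\link{binarize}}).
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(backgroundRadius = "numeric", thresholdMethod = "character",
                 morphIterations = "integer", connectivity = "integer",
                 excludeEdges = "logical", contrastSaturation = "numeric",
                 minContrast = "numeric"),
  validity = function(object) {
    if (object@backgroundRadius <= 0)
      return("backgroundRadius must be positive")
    if (!object@thresholdMethod %in% c("isodata", "otsu"))
      return("thresholdMethod must be 'isodata' or 'otsu'")
    if (object@morphIterations < 1L)
      return("morphIterations must be a positive integer")
    if (!object@connectivity %in% c(4L, 8L))
      return("connectivity must be 4 or 8")
    if (!is.na(object@contrastSaturation) &&
        (object@contrastSaturation < 0 || object@contrastSaturation > 100))
      return("contrastSaturation must be in [0, 100] or NA")
    if (object@minContrast < 0 || object@minContrast > 255)
      return("minContrast must be in [0, 255]")
    TRUE
  })

#' SceneParams: parameters of the synthetic micrograph generator
#'
#' @slot width,height integer(1) scene size in pixels.
#' @slot nViable,nNonviable integer(1) grain counts by stain class.
#' @slot grainAreaRange numeric(2) target grain areas (pixel^2).
#' @slot eccentricityRange numeric(2) grain ellipse eccentricities in \[0, 1).
#' @slot clusterFraction numeric(1) proportion of grains placed in touching
#'   clusters of 2-3.
#' @slot nDebrisSmall,nDebrisLarge integer(1) counts of sub-range specks and
#'   super-range blobs.
#' @slot noiseSd numeric(1) Gaussian sensor-noise SD (intensity levels).
#' @slot illuminationGradient logical(1) add a linear illumination ramp.
#' @slot seed integer(1) RNG seed; the full scene is deterministic given it.
#' @exportClass SceneParams
setClass("SceneParams",
  representation(width = "integer", height = "integer",
                 nViable = "integer", nNonviable = "integer",
                 grainAreaRange = "numeric", eccentricityRange = "numeric",
                 clusterFraction = "numeric",
                 nDebrisSmall = "integer", nDebrisLarge = "integer",
                 noiseSd = "numeric", illuminationGradient = "logical",
                 seed = "integer"),
  validity = function(object) {
    if (object@width < 64L || object@height < 64L)
      return("scene must be at least 64 x 64 pixels")
    if (object@nViable < 0L || object@nNonviable < 0L ||
        object@nDebrisSmall < 0L || object@nDebrisLarge < 0L)
      return("counts must be non-negative")
    r <- object@grainAreaRange
    if (length(r) != 2L || r[1] <= 0 || r[1] > r[2])
      return("grainAreaRange must be an increasing positive interval")
    if (r[2] > object@width * object@height)
      return("grainAreaRange exceeds the image area")
    e <- object@eccentricityRange
    if (length(e) != 2L || e[1] < 0 || e[1] > e[2] || e[2] >= 1)
      return("eccentricityRange must lie within [0, 1)")
    if (object@clusterFraction < 0 || object@clusterFraction > 1)
      return("clusterFraction must be in [0, 1]")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
  })

## ---------------------------------------------------------------------------
## Constructors
## ---------------------------------------------------------------------------

#' Create an RgbImage from a pixel array
#'
#' @param pixels height x width x 3 numeric array of 8-bit intensities.
#' @param id image identifier string.
#' @return An \linkS4class{RgbImage}.
#' @examples
#' img <- rgbImage(array(200, dim = c(32, 48, 3)), id = "blank")
#' dim(imagePixels(img))
#' @export
rgbImage <- function(pixels, id = "image") {
  new("RgbImage", pixels = pixels, id = as.character(id))
}

#' Create a GrayImage
#'
#' @param pixels height x width numeric matrix of 8-bit intensities.
#' @param channelTag which RGB channel the plane came from ("red", "green",
#'   "blue") or "none".
#' @return A \linkS4class{GrayImage}.
#' @export
grayImage <- function(pixels, channelTag = "none") {
  new("GrayImage", pixels = pixels, channelTag = channelTag)
}

#' Create a BinaryMask
#'
#' @param pixels logical matrix; TRUE marks foreground.
#' @return A \linkS4class{BinaryMask}.
#' @export
binaryMask <- function(pixels) {
  mode(pixels) <- "logical"
  new("BinaryMask", pixels = pixels)
}

#' Create a LabelImage
#'
#' @param pixels integer matrix of non-negative labels (0 = background);
#'   positive labels are relabelled, in order of first appearance by label
#'   value, to the contiguous set 1..n.
#' @return A \linkS4class{LabelImage}.
#' @export
labelImage <- function(pixels) {
  p <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  u <- sort(unique(p[p > 0L]))
  if (length(u) && !identical(u, seq_along(u))) {
    remap <- integer(max(u))
    remap[u] <- seq_along(u)
    pos <- p > 0L
    p[pos] <- remap[p[pos]]
  }
  new("LabelImage", pixels = p, nLabels = length(u))
}

#' Create a ParticleFilter
#'
#' @param sizeMin,sizeMax inclusive area window in pixel^2.
#' @param circMin,circMax inclusive circularity window in \[0, 1\].
#' @return A \linkS4class{ParticleFilter}.
#' @examples
#' particleFilter(100, 900, 0.4, 1)
#' @export
particleFilter <- function(sizeMin, sizeMax, circMin = 0, circMax = 1) {
  new("ParticleFilter", sizeMin = as.numeric(sizeMin),
      sizeMax = as.numeric(sizeMax), circMin = as.numeric(circMin),
      circMax = as.numeric(circMax))
}

#' Create a ScenarioSpec
#'
#' @param name scenario name.
#' @param redFilter filter applied to red-channel particles (total pollen).
#' @param greenFilter filter applied to green-channel particles (viable
#'   pollen); defaults to the red filter, the symmetric case of the S1-S6
#'   grid.
#' @return A \linkS4class{ScenarioSpec}.
#' @export
scenarioSpec <- function(name, redFilter, greenFilter = redFilter) {
  new("ScenarioSpec", name = as.character(name), redFilter = redFilter,
      greenFilter = greenFilter)
}

#' Create a PipelineConfig
#'
#' Defaults follow the conventions of interactive particle-analysis tools:
#' rolling-ball radius 50 px (well above the 10-17 px radius of grains in the
#' 100-900 px^2 window), IsoData auto-thresholding, one dilate/erode
#' iteration, 8-connected foreground, border particles retained, contrast
#' enhancement off.
#'
#' @param backgroundRadius rolling-ball radius in pixels.
#' @param thresholdMethod "isodata" or "otsu".
#' @param morphIterations dilate/erode iterations.
#' @param connectivity 4 or 8.
#' @param excludeEdges drop particles touching the image border?
#' @param contrastSaturation percent of saturated pixels for the optional
#'   contrast-enhancement step, or NA (default) to skip it.
#' @param minContrast minimum background-to-foreground intensity contrast for
#'   binarization to accept a foreground (levels of 255); see
#'   \code{\link{binarize}}.
#' @return A \linkS4class{PipelineConfig}.
#' @examples
#' pipelineConfig()
#' pipelineConfig(thresholdMethod = "otsu", excludeEdges = TRUE)
#' @export
pipelineConfig <- function(backgroundRadius = 50, thresholdMethod = "isodata",
                           morphIterations = 1L, connectivity = 8L,
                           excludeEdges = FALSE, contrastSaturation = NA_real_,
                           minContrast = 50) {
  new("PipelineConfig", backgroundRadius = as.numeric(backgroundRadius),
      thresholdMethod = thresholdMethod,
      morphIterations = as.integer(morphIterations),
      connectivity = as.integer(connectivity),
      excludeEdges = isTRUE(excludeEdges),
      contrastSaturation = as.numeric(contrastSaturation),
      minContrast = as.numeric(minContrast))
}

#' Create SceneParams for the synthetic micrograph generator
#'
#' Defaults emulate a typical well-prepared slide at half the linear
#' resolution of a 2048 x 1536 camera frame: 40 viable and 10 non-viable
#' grains (80 percent viability), grain areas 150-850 px^2, mild ellipticity,
#' 15 percent of grains in touching clusters, a few sub-threshold specks and
#' oversized debris blobs, and sensor noise of 3 intensity levels.
#'
#' @param width,height scene size in pixels.
#' @param nViable,nNonviable grain counts by stain class.
#' @param grainAreaRange target grain areas in pixel^2.
#' @param eccentricityRange grain ellipse eccentricities; the default cap of
#'   0.6 keeps grain circularity well inside the 0.4-1 filter windows.
#' @param clusterFraction proportion of grains placed in touching clusters.
#' @param nDebrisSmall,nDebrisLarge counts of sub-range and super-range
#'   distractors.
#' @param noiseSd Gaussian sensor-noise SD in intensity levels.
#' @param illuminationGradient add a linear illumination ramp?
#' @param seed RNG seed.
#' @return A \linkS4class{SceneParams}.
#' @examples
#' sceneParams(nViable = 20, nNonviable = 5, seed = 7)
#' @export
sceneParams <- function(width = 1024L, height = 768L,
                        nViable = 40L, nNonviable = 10L,
                        grainAreaRange = c(150, 850),
                        eccentricityRange = c(0, 0.6),
                        clusterFraction = 0.15,
                        nDebrisSmall = 6L, nDebrisLarge = 2L,
                        noiseSd = 3, illuminationGradient = FALSE,
                        seed = 1L) {
  new("SceneParams", width = as.integer(width), height = as.integer(height),
      nViable = as.integer(nViable), nNonviable = as.integer(nNonviable),
      grainAreaRange = as.numeric(grainAreaRange),
      eccentricityRange = as.numeric(eccentricityRange),
      clusterFraction = as.numeric(clusterFraction),
      nDebrisSmall = as.integer(nDebrisSmall),
      nDebrisLarge = as.integer(nDebrisLarge),
      noiseSd = as.numeric(noiseSd),
      illuminationGradient = isTRUE(illuminationGradient),
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Accessors and show methods
## ---------------------------------------------------------------------------

#' @rdname rgbImage
#' @param object an RgbImage, GrayImage, BinaryMask or LabelImage.
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))

#' @rdname rgbImage
#' @export
setMethod("imagePixels", "RgbImage", function(object) object@pixels)
#' @rdname rgbImage
#' @export
setMethod("imagePixels", "GrayImage", function(object) object@pixels)
#' @rdname rgbImage
#' @export
setMethod("imagePixels", "BinaryMask", function(object) object@pixels)
#' @rdname rgbImage
#' @export
setMethod("imagePixels", "LabelImage", function(object) object@pixels)

#' @rdname rgbImage
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))
#' @rdname rgbImage
#' @export
setMethod("imageId", "RgbImage", function(object) object@id)

#' @rdname labelImage
#' @param object a LabelImage.
#' @export
setGeneric("nLabels", function(object) standardGeneric("nLabels"))
#' @rdname labelImage
#' @export
setMethod("nLabels", "LabelImage", function(object) object@nLabels)

#' @rdname scenarioSpec
#' @param object a ScenarioSpec.
#' @export
setGeneric("scenarioName", function(object) standardGeneric("scenarioName"))
#' @rdname scenarioSpec
#' @export
setMethod("scenarioName", "ScenarioSpec", function(object) object@name)

#' @rdname scenarioSpec
#' @export
setGeneric("redFilter", function(object) standardGeneric("redFilter"))
#' @rdname scenarioSpec
#' @export
setMethod("redFilter", "ScenarioSpec", function(object) object@redFilter)

#' @rdname scenarioSpec
#' @export
setGeneric("greenFilter", function(object) standardGeneric("greenFilter"))
#' @rdname scenarioSpec
#' @export
setMethod("greenFilter", "ScenarioSpec", function(object) object@greenFilter)

#' @rdname particleFilter
#' @param object a ParticleFilter.
#' @export
setGeneric("filterBounds", function(object) standardGeneric("filterBounds"))

#' @rdname particleFilter
#' @export
setMethod("filterBounds", "ParticleFilter", function(object) {
  c(sizeMin = object@sizeMin, sizeMax = object@sizeMax,
    circMin = object@circMin, circMax = object@circMax)
})

setMethod("show", "RgbImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RgbImage '%s': %d x %d px, 3 channels, range [%g, %g]\n",
              object@id, d[1], d[2], min(object@pixels), max(object@pixels)))
})

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImage (%s): %d x %d px, range [%g, %g]\n",
              object@channelTag, d[1], d[2],
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d px, %d foreground px\n",
              nrow(object@pixels), ncol(object@pixels), sum(object@pixels)))
})

setMethod("show", "LabelImage", function(object) {
  cat(sprintf("LabelImage: %d x %d px, %d objects\n",
              nrow(object@pixels), ncol(object@pixels), object@nLabels))
})

setMethod("show", "ParticleFilter", function(object) {
  cat(sprintf("ParticleFilter: size [%g, %g] px^2, circularity [%g, %g]\n",
              object@sizeMin, object@sizeMax, object@circMin, object@circMax))
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec %s\n  red   (total):  size [%g, %g], circ [%g, %g]\n  green (viable): size [%g, %g], circ [%g, %g]\n",
              object@name,
              object@redFilter@sizeMin, object@redFilter@sizeMax,
              object@redFilter@circMin, object@redFilter@circMax,
              object@greenFilter@sizeMin, object@greenFilter@sizeMax,
              object@greenFilter@circMin, object@greenFilter@circMax))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(
    "PipelineConfig: bg radius %g px, threshold '%s', morph x%d, %d-connected, edges %s, contrast %s\n",
    object@backgroundRadius, object@thresholdMethod, object@morphIterations,
    object@connectivity,
    if (object@excludeEdges) "excluded" else "kept",
    if (is.na(object@contrastSaturation)) "off"
    else sprintf("saturate %g%%", object@contrastSaturation)))
})

setMethod("show", "SceneParams", function(object) {
  cat(sprintf(
    "SceneParams: %d x %d px, %d viable + %d non-viable grains, areas [%g, %g] px^2,\n  cluster fraction %g, debris %d small / %d large, noise sd %g, gradient %s, seed %d\n",
    object@width, object@height, object@nViable, object@nNonviable,
    object@grainAreaRange[1], object@grainAreaRange[2],
    object@clusterFraction, object@nDebrisSmall, object@nDebrisLarge,
    object@noiseSd, if (object@illuminationGradient) "on" else "off",
    object@seed))
})
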
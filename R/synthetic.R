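## synthetic_data: seeded generator of Alexander-stain-like micrographs with
## exact per-grain ground truth.

# Stain colour model (RGB). Viable grains are dark blue: dark in both red
# and green, so they register in both counting channels. Non-viable grains
# are light blue: dark enough in red to be counted as pollen, but close to
# the pale background in green, so they drop out of the viable count. This
# is the colour mechanism the counting pipeline exploits.
.COL_BACKGROUND <- c(235, 225, 230)
.COL_VIABLE     <- c(70, 50, 120)
.COL_NONVIABLE  <- c(140, 190, 220)
.COL_DEBRIS     <- c(90, 80, 110)

# run expr with a private RNG stream seeded by `seed`; the caller's RNG
# state is untouched.
.withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hasSeed) get(".Random.seed", envir = globalenv())
  on.exit(if (hasSeed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# semi-axes of an ellipse with the given area and eccentricity
.ellipseAxes <- function(area, ecc) {
  q <- sqrt(1 - ecc^2)                 # b/a
  a <- sqrt(area / (pi * q))
  c(a = a, b = a * q)
}

# logical mask of a rotated ellipse over integer pixel grid rows r0:r1,
# cols c0:c1 (pixel centres)
.ellipseMask <- function(rows, cols, cy, cx, a, b, theta) {
  dr <- outer(rows - cy, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cx)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one synthetic stained-pollen micrograph with ground truth
#'
#' Renders dark-blue (viable) and light-blue (non-viable) elliptical grains
#' on a pale background, with optional touching clusters, sub-threshold
#' debris specks, oversized debris blobs, Gaussian sensor noise and a linear
#' illumination gradient. Every stochastic choice is drawn from a private
#' RNG stream seeded by \code{params@seed} in a fixed order (grain classes,
#' geometry, cluster assignment, placement, colour jitter, pixel noise), so
#' the scene is bit-reproducible.
#'
#' Grain placement keeps non-clustered objects separated by at least 6 px of
#' background so that morphological refinement cannot merge them; clustered
#' grains are placed overlapping, with centre separation of 1.2-1.7 times
#' their mean effective radius. A packing guard rejects parameter sets whose
#' total grain area exceeds 30 percent of the image area. Debris distractors
#' that cannot be placed in a crowded scene are dropped (grains never are:
#' the requested grain counts are the scene's ground truth).
#'
#' @param params a \linkS4class{SceneParams}.
#' @param id image identifier (default derived from the seed).
#' @param grainAreas optional explicit vector of target grain areas
#'   (pixel^2), length \code{nViable + nNonviable}, overriding uniform
#'   sampling from \code{grainAreaRange} (used by
#'   \code{\link{generateBenchmark}} to impose area mixtures).
#' @return A list with \code{image} (an \linkS4class{RgbImage}) and
#'   \code{truth}: a list with \code{grains} (data.frame: class, centre,
#'   semi-axes, orientation, target and rasterized area, cluster id),
#'   \code{trueTotal}, \code{trueViable}, \code{truePv} (debris is excluded
#'   from all true counts).
#' @examples
#' sc <- generateScene(sceneParams(width = 256, height = 256, nViable = 6,
#'                                 nNonviable = 2, nDebrisSmall = 2,
#'                                 nDebrisLarge = 0, clusterFraction = 0,
#'                                 seed = 42))
#' sc$truth$trueTotal; sc$truth$truePv
#' @export
generateScene <- function(params, id = sprintf("scene_seed%d", params@seed),
                          grainAreas = NULL) {
  stopifnot(is(params, "SceneParams"))
  .withSeed(params@seed, .renderScene(params, id, grainAreas))
}

.renderScene <- function(params, id, grainAreas) {
  W <- params@width; H <- params@height
  nG <- params@nViable + params@nNonviable

  ## 1. classes and geometry ------------------------------------------------
  classes <- c(rep("viable", params@nViable),
               rep("nonviable", params@nNonviable))
  if (nG > 1L) classes <- sample(classes)
  areas <- if (is.null(grainAreas))
    stats::runif(nG, params@grainAreaRange[1], params@grainAreaRange[2])
  else {
    stopifnot(length(grainAreas) == nG)
    as.numeric(grainAreas)
  }
  eccs <- stats::runif(nG, params@eccentricityRange[1],
                       params@eccentricityRange[2])
  thetas <- stats::runif(nG, 0, pi)
  ax <- t(vapply(seq_len(nG), function(i) .ellipseAxes(areas[i], eccs[i]),
                 numeric(2)))

  ## debris geometry
  nS <- params@nDebrisSmall; nL <- params@nDebrisLarge
  smallR <- stats::runif(nS, 1.8, 3.2)              # areas ~ 10-32 px^2
  largeA <- stats::runif(nL, 2200, 3200)            # well above 900 px^2
  largeE <- stats::runif(nL, 0.80, 0.90)
  # keep large debris placeable in small scenes while staying > 900 px^2
  if (nL > 0L) {
    sizeCap <- pi * sqrt(1 - max(largeE)^2) * (min(W, H) / 6)^2
    largeA <- pmax(pmin(largeA, max(1000, sizeCap)), 1000)
  }
  largeTh <- stats::runif(nL, 0, pi)
  largeAx <- if (nL) t(vapply(seq_len(nL),
                              function(i) .ellipseAxes(largeA[i], largeE[i]),
                              numeric(2))) else matrix(0, 0, 2)

  ## packing guard
  if (sum(areas) + sum(pi * smallR^2) + sum(largeA) > 0.30 * W * H)
    stop("packing guard: requested grain area exceeds 30% of the image area")

  ## 2. cluster assignment --------------------------------------------------
  nClustered <- round(params@clusterFraction * nG)
  clusterId <- integer(nG)                          # 0 = unclustered
  if (nClustered >= 2L) {
    pool <- seq_len(nClustered)                     # classes already shuffled
    cid <- 1L
    while (length(pool) >= 2L) {
      k <- if (length(pool) >= 3L && stats::runif(1) < 0.5) 3L else 2L
      take <- pool[seq_len(k)]
      clusterId[take] <- cid
      pool <- pool[-seq_len(k)]
      cid <- cid + 1L
    }
  }

  ## 3. placement -----------------------------------------------------------
  # entities: grains (by cluster unit), then small debris, then large debris
  boundR <- ax[, 1]
  effR <- sqrt(areas / pi)
  cy <- numeric(nG); cx <- numeric(nG)
  placedY <- numeric(0); placedX <- numeric(0); placedR <- numeric(0)
  gap <- 6

  placeFree <- function(rad, required = TRUE) {
    if (rad + 8 < H - rad && rad + 8 < W - rad) {
      for (try in 1:400) {
        y <- stats::runif(1, rad + 4, H - rad - 3)
        x <- stats::runif(1, rad + 4, W - rad - 3)
        if (!length(placedR) ||
            all(sqrt((placedY - y)^2 + (placedX - x)^2) >=
                placedR + rad + gap))
          return(c(y, x))
      }
    }
    if (required)
      stop("could not place all grains; reduce counts or grain areas")
    NULL                                  # crowded scene: drop this distractor
  }

  for (cid in setdiff(unique(clusterId), 0L)) {
    members <- which(clusterId == cid)
    # relative layout: chain of overlapping members
    relY <- numeric(length(members)); relX <- numeric(length(members))
    for (j in seq_along(members)[-1]) {
      i1 <- members[j - 1L]; i2 <- members[j]
      sep <- stats::runif(1, 1.25, 1.7) * (effR[i1] + effR[i2]) / 2
      ang <- stats::runif(1, 0, 2 * pi)
      relY[j] <- relY[j - 1L] + sep * sin(ang)
      relX[j] <- relX[j - 1L] + sep * cos(ang)
    }
    cR <- max(sqrt(relY^2 + relX^2) + boundR[members])
    at <- placeFree(cR)
    cy[members] <- at[1] + relY; cx[members] <- at[2] + relX
    placedY <- c(placedY, at[1]); placedX <- c(placedX, at[2])
    placedR <- c(placedR, cR)
  }
  for (i in which(clusterId == 0L)) {
    at <- placeFree(boundR[i])
    cy[i] <- at[1]; cx[i] <- at[2]
    placedY <- c(placedY, at[1]); placedX <- c(placedX, at[2])
    placedR <- c(placedR, boundR[i])
  }
  # debris are distractors, not counted objects: in scenes too crowded to
  # fit one, it is dropped rather than failing the scene
  smallY <- numeric(0); smallX <- numeric(0); smallKeep <- integer(0)
  for (i in seq_len(nS)) {
    at <- placeFree(smallR[i], required = FALSE)
    if (is.null(at)) next
    smallY <- c(smallY, at[1]); smallX <- c(smallX, at[2])
    smallKeep <- c(smallKeep, i)
    placedY <- c(placedY, at[1]); placedX <- c(placedX, at[2])
    placedR <- c(placedR, smallR[i])
  }
  smallR <- smallR[smallKeep]; nS <- length(smallKeep)
  largeY <- numeric(0); largeX <- numeric(0); largeKeep <- integer(0)
  for (i in seq_len(nL)) {
    at <- placeFree(largeAx[i, 1], required = FALSE)
    if (is.null(at)) next
    largeY <- c(largeY, at[1]); largeX <- c(largeX, at[2])
    largeKeep <- c(largeKeep, i)
    placedY <- c(placedY, at[1]); placedX <- c(placedX, at[2])
    placedR <- c(placedR, largeAx[i, 1])
  }
  largeA <- largeA[largeKeep]; largeTh <- largeTh[largeKeep]
  largeAx <- largeAx[largeKeep, , drop = FALSE]; nL <- length(largeKeep)

  ## 4. rendering -----------------------------------------------------------
  px <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) px[, , ch] <- .COL_BACKGROUND[ch]
  if (params@illuminationGradient) {
    ramp <- matrix(seq(-15, 15, length.out = W), H, W, byrow = TRUE)
    for (ch in 1:3) px[, , ch] <- px[, , ch] + ramp
  }

  rasterArea <- integer(nG)
  paint <- function(px, cy, cx, a, b, theta, col, jitterSd = 4) {
    r0 <- max(1L, floor(cy - a - 1)); r1 <- min(H, ceiling(cy + a + 1))
    c0 <- max(1L, floor(cx - a - 1)); c1 <- min(W, ceiling(cx + a + 1))
    m <- .ellipseMask(r0:r1, c0:c1, cy, cx, a, b, theta)
    col <- col + stats::rnorm(3, 0, jitterSd)
    for (ch in 1:3) {
      plane <- px[r0:r1, c0:c1, ch]
      plane[m] <- col[ch]
      px[r0:r1, c0:c1, ch] <- plane
    }
    attr(px, "npix") <- sum(m)
    px
  }
  for (i in seq_len(nG)) {
    col <- if (classes[i] == "viable") .COL_VIABLE else .COL_NONVIABLE
    px <- paint(px, cy[i], cx[i], ax[i, 1], ax[i, 2], thetas[i], col)
    rasterArea[i] <- attr(px, "npix")
  }
  for (i in seq_len(nS))
    px <- paint(px, smallY[i], smallX[i], smallR[i], smallR[i], 0,
                .COL_DEBRIS)
  for (i in seq_len(nL))
    px <- paint(px, largeY[i], largeX[i], largeAx[i, 1], largeAx[i, 2],
                largeTh[i], .COL_DEBRIS)
  attr(px, "npix") <- NULL

  if (params@noiseSd > 0)
    px <- px + array(stats::rnorm(length(px), 0, params@noiseSd), dim(px))
  px <- round(px)
  px[px < 0] <- 0; px[px > 255] <- 255

  ## 5. ground truth --------------------------------------------------------
  grains <- data.frame(
    class = c(classes, rep("debris", nS + nL)),
    centerRow = c(cy, smallY, largeY) - 1,          # 0-based coordinates
    centerCol = c(cx, smallX, largeX) - 1,
    semiMajor = c(ax[, 1], smallR, largeAx[, 1]),
    semiMinor = c(ax[, 2], smallR, largeAx[, 2]),
    orientation = c(thetas, rep(0, nS), largeTh),
    targetArea = c(areas, pi * smallR^2, largeA),
    rasterArea = c(rasterArea, rep(NA_integer_, nS + nL)),
    clusterId = c(clusterId, rep(0L, nS + nL)),
    stringsAsFactors = FALSE)
  trueTotal <- nG
  trueViable <- params@nViable
  list(image = rgbImage(px, id = id),
       truth = list(grains = grains, trueTotal = trueTotal,
                    trueViable = trueViable,
                    truePv = if (trueTotal > 0) 100 * trueViable / trueTotal
                             else NA_real_))
}

#' Generate a synthetic optimization benchmark
#'
#' A seeded set of synthetic micrographs whose true totals and viabilities
#' span the given ranges, together with the manual-count table derived from
#' ground truth — a synthetic stand-in for an optimization image set with
#' human counts. Per-grain areas are drawn from a two-component mixture:
#' with probability \code{smallAreaFraction} from the sub-window
#' \code{smallAreaWindow}, otherwise uniformly from the remainder of
#' \code{areaRange}, so that filter windows with a raised lower size bound
#' lose a variable fraction of grains per image. Every other image carries a
#' linear illumination gradient.
#'
#' @param nImages number of images (>= 3; default 31).
#' @param totalRange range of true total grain counts per image.
#' @param viabilityRange range of true viability percentages.
#' @param areaRange overall grain-area range (pixel^2).
#' @param smallAreaFraction probability that a grain's area is drawn from
#'   \code{smallAreaWindow}.
#' @param smallAreaWindow the small-grain area sub-window (pixel^2).
#' @param width,height image size in pixels.
#' @param clusterFraction,noiseSd passed to \code{\link{sceneParams}}.
#' @param seed RNG seed governing the whole benchmark.
#' @param dir optional output directory; when given, images are written as
#'   8-bit PNGs under \code{dir/images/} and the manual-count table as
#'   \code{dir/truth.csv}.
#' @return A list with \code{scenes} (list of \code{\link{generateScene}}
#'   results) and \code{manual} (data.frame: \code{image_id},
#'   \code{manual_total}, \code{manual_viable}).
#' @export
generateBenchmark <- function(nImages = 31L, totalRange = c(20, 120),
                              viabilityRange = c(10, 95),
                              areaRange = c(100, 900),
                              smallAreaFraction = 0.1,
                              smallAreaWindow = c(100, 200),
                              width = 1024L, height = 768L,
                              clusterFraction = 0.1, noiseSd = 3,
                              seed = 1L, dir = NULL) {
  if (nImages < 3L) stop("need at least 3 images for a benchmark")
  plan <- .withSeed(seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, nImages),
         totals = round(stats::runif(nImages, totalRange[1], totalRange[2])),
         pvs = stats::runif(nImages, viabilityRange[1], viabilityRange[2]))
  })
  scenes <- vector("list", nImages)
  manual <- data.frame(image_id = character(nImages),
                       manual_total = integer(nImages),
                       manual_viable = integer(nImages),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nImages)) {
    total <- as.integer(plan$totals[i])
    nViable <- max(1L, min(total, as.integer(round(total * plan$pvs[i] / 100))))
    params <- sceneParams(width = width, height = height,
                          nViable = nViable, nNonviable = total - nViable,
                          grainAreaRange = areaRange,
                          clusterFraction = clusterFraction,
                          noiseSd = noiseSd,
                          illuminationGradient = i %% 2L == 0L,
                          seed = plan$seeds[i])
    areas <- .withSeed(plan$seeds[i] + 1L, {
      small <- stats::runif(total) < smallAreaFraction
      ifelse(small,
             stats::runif(total, smallAreaWindow[1], smallAreaWindow[2]),
             stats::runif(total, max(smallAreaWindow[2], areaRange[1]),
                          areaRange[2]))
    })
    id <- sprintf("synthetic_%02d", i)
    scenes[[i]] <- generateScene(params, id = id, grainAreas = areas)
    manual$image_id[i] <- id
    manual$manual_total[i] <- scenes[[i]]$truth$trueTotal
    manual$manual_viable[i] <- scenes[[i]]$truth$trueViable
  }
  if (!is.null(dir)) {
    imgDir <- file.path(dir, "images")
    dir.create(imgDir, recursive = TRUE, showWarnings = FALSE)
    for (sc in scenes) {
      arr <- aperm(sc$image@pixels, c(2L, 1L, 3L)) / 255
      EBImage::writeImage(EBImage::Image(arr, colormode = "Color"),
                          file.path(imgDir, paste0(sc$image@id, ".png")))
    }
    utils::write.csv(manual, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(scenes = scenes, manual = manual)
}
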
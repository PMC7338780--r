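# Fixture builders: rasterized shapes and touching-grain clusters, built in
# code so every expected value can be recomputed from first principles.

discMask <- function(r, pad = 5L) {
  n <- 2L * ceiling(r) + 2L * pad
  cx <- (n + 1) / 2
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2)
  m
}

ellipseMaskAt <- function(nrow, ncol, cy, cx, a, b, theta = 0) {
  ix <- matrix(seq_len(nrow), nrow, ncol)
  iy <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  u <- (ix - cy) * cos(theta) + (iy - cx) * sin(theta)
  v <- -(ix - cy) * sin(theta) + (iy - cx) * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# a chain of k touching discs with centre separation sepFactor x mean radius
clusterMask <- function(k, radii, sepFactor, nrow = 140L, ncol = 180L,
                        angles = rep(0, k - 1L)) {
  m <- matrix(FALSE, nrow, ncol)
  ys <- nrow / 2; xs <- 45
  for (j in seq_len(k - 1L)) {
    sep <- sepFactor * (radii[j] + radii[j + 1L]) / 2
    ys <- c(ys, ys[j] + sep * sin(angles[j]))
    xs <- c(xs, xs[j] + sep * cos(angles[j]))
  }
  ix <- row(m); iy <- col(m)
  for (j in seq_len(k))
    m[(ix - ys[j])^2 + (iy - xs[j])^2 <= radii[j]^2] <- TRUE
  m
}

# small, fast scene for pipeline tests
quickScene <- function(seed, nViable = 12L, nNonviable = 4L, ...) {
  generateScene(sceneParams(width = 448L, height = 336L, nViable = nViable,
                            nNonviable = nNonviable, clusterFraction = 0,
                            nDebrisSmall = 3L, nDebrisLarge = 1L,
                            grainAreaRange = c(150, 850), seed = seed, ...))
}

fastConfig <- function(...) pipelineConfig(...)
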
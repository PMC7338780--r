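# imaging_core: circularity, particle measurement, window filtering

test_that("circularity follows 4*pi*A/P^2 with clipping at 1", {
  expect_equal(circularity(100, 40), 4 * pi * 100 / 1600)
  # ideal continuous circle: A = pi r^2, P = 2 pi r
  r <- 7.3
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  # perimeter underestimation can push the ratio above 1: clipped
  expect_equal(circularity(400, 60), 1)
  expect_error(circularity(0.5, 10), "invalid measurement")
  expect_error(circularity(10, 0), "invalid measurement")
  expect_error(circularity(10, -3), "invalid measurement")
})

test_that("measureParticles returns exact pixel areas and label order", {
  m <- matrix(0L, 26, 26)
  m[4:23, 4:23] <- 1L
  p <- measureParticles(labelImage(m))
  expect_equal(nrow(p), 1L)
  expect_equal(p$area, 400L)
  expect_false(p$touchesEdge)
  # centroid of a square spanning rows/cols 4..23 (1-based) in 0-based coords
  expect_equal(p$centroidRow, mean(3:22))
  expect_equal(p$centroidCol, mean(3:22))

  empty <- measureParticles(labelImage(matrix(0L, 10, 10)))
  expect_equal(nrow(empty), 0L)
})

test_that("disjoint discs are measured with their rasterized pixel counts", {
  m <- matrix(0L, 80, 80)
  d10 <- discMask(10); d5 <- discMask(5)
  m[3 + seq_len(nrow(d10)), 3 + seq_len(ncol(d10))][d10] <- 1L
  m[48 + seq_len(nrow(d5)), 48 + seq_len(ncol(d5))][d5] <- 2L
  p <- measureParticles(labelImage(m))
  expect_equal(nrow(p), 2L)
  # exact pixel counts of the rasterized discs, computed independently
  expect_equal(p$area, c(sum(d10), sum(d5)))
  # and each within 5% of the continuous disc area
  expect_lt(abs(p$area[1] - pi * 100) / (pi * 100), 0.05)
  expect_lt(abs(p$area[2] - pi * 25) / (pi * 25), 0.05)
})

test_that("area measurement conserves total foreground pixel count", {
  set.seed(41)
  for (i in 1:5) {
    m <- matrix(0L, 80, 80)
    for (lab in 1:4) {
      d <- discMask(runif(1, 3, 7))
      r0 <- sample(40, 1); c0 <- sample(40, 1)
      block <- m[r0 + seq_len(nrow(d)), c0 + seq_len(ncol(d))]
      block[d] <- lab
      m[r0 + seq_len(nrow(d)), c0 + seq_len(ncol(d))] <- block
    }
    li <- labelImage(m)
    p <- measureParticles(li)
    expect_equal(sum(p$area), sum(imagePixels(li) > 0))
  }
})

test_that("rasterized discs measure as near-perfect circles", {
  for (r in c(8, 10, 12, 15, 17, 20, 25)) {
    d <- discMask(r)
    p <- measureParticles(labelImage(d * 1L))
    expect_gte(p$circularity, 0.9)
  }
})

test_that("border-touching particles are flagged and excludable", {
  m <- matrix(0L, 30, 30)
  m[1:6, 10:15] <- 1L     # touches top border
  m[15:20, 10:15] <- 2L
  p <- measureParticles(labelImage(m))
  expect_equal(p$touchesEdge, c(TRUE, FALSE))
})

test_that("filterParticles applies inclusive bounds on both windows", {
  pf <- particleFilter(100, 900, 0.4, 1)
  parts <- data.frame(area = c(95, 100, 900, 901, 500, 500),
                      circularity = c(0.9, 0.4, 1, 0.7, 0.39, 0.401))
  kept <- filterParticles(parts, pf)
  expect_equal(rownames(kept), c("2", "3", "6"))
})

test_that("filterParticles matches an exhaustive interval scan and is monotone", {
  set.seed(17)
  for (i in 1:25) {
    parts <- data.frame(area = round(runif(200, 0, 1200)),
                        circularity = round(runif(200), 3))
    b <- sort(runif(2, 0, 1200)); cb <- sort(runif(2))
    pf <- particleFilter(b[1], b[2], cb[1], cb[2])
    kept <- filterParticles(parts, pf)
    # independent exhaustive scan, row by row
    oracle <- parts[vapply(seq_len(nrow(parts)), function(j) {
      parts$area[j] >= b[1] && parts$area[j] <= b[2] &&
        parts$circularity[j] >= cb[1] && parts$circularity[j] <= cb[2]
    }, logical(1)), , drop = FALSE]
    expect_identical(kept, oracle)
    # subset of input, order preserved
    expect_true(all(rownames(kept) %in% rownames(parts)))
    expect_false(is.unsorted(as.integer(rownames(kept))))
    # shrinking any window never increases the yield
    shrunk <- particleFilter(b[1] + (b[2] - b[1]) / 4, b[2],
                             cb[1] + (cb[2] - cb[1]) / 4, cb[2])
    expect_lte(nrow(filterParticles(parts, shrunk)), nrow(kept))
  }
})

test_that("invalid filter windows are rejected at construction", {
  expect_error(particleFilter(900, 100), "size")
  expect_error(particleFilter(100, 900, 0.8, 0.4), "circularity")
  expect_error(particleFilter(100, 900, 0.4, 1.2), "circularity")
})
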
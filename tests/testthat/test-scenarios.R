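# scenario_eval: catalog, correlation, evaluation, selection, group summary

test_that("the scenario catalog holds the seven canonical parameterizations", {
  cat <- scenarioCatalog()
  expect_length(cat, 7L)
  expect_identical(names(cat), paste0("S", 0:6))
  # S0: asymmetric original setting
  expect_equal(filterBounds(redFilter(cat$S0)),
               c(sizeMin = 60, sizeMax = 800, circMin = 0.4, circMax = 1))
  expect_equal(filterBounds(greenFilter(cat$S0)),
               c(sizeMin = 100, sizeMax = 800, circMin = 0.4, circMax = 1))
  # S1..S6: the 2x3 grid, symmetric across channels
  grid <- list(S1 = c(100, 900, 0.4, 1), S2 = c(200, 900, 0.4, 1),
               S3 = c(100, 900, 0.5, 1), S4 = c(200, 900, 0.5, 1),
               S5 = c(100, 900, 0.6, 1), S6 = c(200, 900, 0.6, 1))
  for (nm in names(grid)) {
    expect_equal(unname(filterBounds(redFilter(cat[[nm]]))), grid[[nm]])
    expect_equal(filterBounds(redFilter(cat[[nm]])),
                 filterBounds(greenFilter(cat[[nm]])))
  }
})

test_that("resolveScenario looks up names and validates explicit bounds", {
  s1 <- resolveScenario("S1")
  expect_equal(unname(filterBounds(redFilter(s1))), c(100, 900, 0.4, 1))
  s0 <- resolveScenario("S0")
  expect_equal(unname(filterBounds(redFilter(s0))[1:2]), c(60, 800))
  expect_equal(unname(filterBounds(greenFilter(s0))[1:2]), c(100, 800))
  expect_error(resolveScenario("S9"), "unknown scenario")
  expect_error(resolveScenario(sizeMin = 900, sizeMax = 100,
                               circMin = 0.4, circMax = 1),
               "inverted size interval")
  expect_error(resolveScenario(sizeMin = 100, sizeMax = 900, circMin = 0.4),
               "missing: circMax")
})

test_that("pearsonCorrelation matches the direct-summation definition", {
  expect_equal(pearsonCorrelation(c(1, 2, 3, 4), c(1, 2, 3, 4))$r, 1)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(2, 2, 4))$r, sqrt(3) / 2,
               tolerance = 1e-12)
  set.seed(23)
  for (i in 1:20) {
    x <- rnorm(sample(3:40, 1)); y <- rnorm(length(x))
    got <- pearsonCorrelation(x, y)
    ct <- cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-10)
  }
  expect_error(pearsonCorrelation(1:3, rep(2, 3)), "zero variance")
  expect_error(pearsonCorrelation(1:3, 1:4), "equal length")
  expect_error(pearsonCorrelation(1:2, 2:3), "at least 3")
})

test_that("runScenarios produces the image x scenario cartesian product", {
  imgs <- lapply(c(501, 502, 503), function(s) quickScene(s)$image)
  res <- runScenarios(imgs, scenarioCatalog())
  expect_equal(nrow(res), 3L * 7L)
  expect_equal(sort(unique(res$scenario_name)), paste0("S", 0:6))
  expect_true(all(is.na(res$error)))
  # nested windows: S1 dominates S5 per image
  for (id in unique(res$image_id)) {
    sub <- res[res$image_id == id, ]
    expect_gte(sub$total_count[sub$scenario_name == "S1"],
               sub$total_count[sub$scenario_name == "S5"])
  }
  # empty scenario list: empty table
  expect_equal(nrow(runScenarios(imgs, list())), 0L)
  # consistency with processImage
  one <- processImage(imgs[[1]], scenarioCatalog()$S1)
  row <- res[res$image_id == one$image_id & res$scenario_name == "S1", ]
  expect_equal(row$total_count, one$total_count)
  expect_equal(row$viable_count, one$viable_count)
})

test_that("evaluateScenarios correlates automatic with manual counts", {
  # synthetic evaluation with hand-built numbers
  mkres <- function(tot, pv, sn) data.frame(
    image_id = sprintf("i%02d", seq_along(tot)), scenario_name = sn,
    total_count = tot, viable_count = round(tot * pv / 100),
    viability_pct = pv, pv_over_100 = pv > 100, error = NA_character_,
    stringsAsFactors = FALSE)
  manual <- data.frame(image_id = sprintf("i%02d", 1:6),
                       manual_total = c(20, 45, 60, 80, 100, 120),
                       manual_viable = c(5, 40, 20, 60, 90, 30))
  # automatic identical to manual: perfect count correlation
  res <- mkres(manual$manual_total,
               100 * manual$manual_viable / manual$manual_total, "SX")
  ev <- evaluateScenarios(res, manual)
  expect_equal(ev$r_count, 1)
  expect_equal(ev$r_viability, 1)
  expect_lt(ev$p_count, 0.001)
  # constant automatic viability: undefined viability correlation, flagged
  res2 <- mkres(manual$manual_total, rep(50, 6), "SY")
  ev2 <- evaluateScenarios(res2, manual)
  expect_true(is.na(ev2$r_viability))
  expect_false(is.na(ev2$r_count))
  # permutation invariance in image order
  perm <- res[sample(nrow(res)), ]
  expect_equal(evaluateScenarios(perm, manual)$r_count, ev$r_count)
  # unmatched images are an error
  expect_error(evaluateScenarios(mkres(1:5 * 10, rep(50, 5), "SZ")[1:5, ],
                                 manual[1:2, ]), "no manual counts")
})

test_that("undefined automatic PV is excluded pairwise from the viability correlation", {
  manual <- data.frame(image_id = sprintf("i%d", 1:5),
                       manual_total = c(10, 20, 30, 40, 50),
                       manual_viable = c(1, 10, 12, 30, 45))
  res <- data.frame(image_id = sprintf("i%d", 1:5), scenario_name = "S1",
                    total_count = c(0L, 20L, 30L, 40L, 50L),
                    viable_count = c(0L, 10L, 12L, 30L, 45L),
                    viability_pct = c(NA, 50, 40, 75, 90),
                    pv_over_100 = FALSE, error = NA_character_,
                    stringsAsFactors = FALSE)
  ev <- evaluateScenarios(res, manual)
  expect_equal(ev$n_pv_excluded, 1L)
  manualPv <- 100 * manual$manual_viable[2:5] / manual$manual_total[2:5]
  expect_equal(ev$r_viability,
               pearsonCorrelation(res$viability_pct[2:5], manualPv)$r)
})

test_that("selectBestScenario ranks by r_count then r_viability then name", {
  ev <- data.frame(scenario_name = c("S2", "S1", "S3"),
                   r_count = c(0.9, 0.99, 0.99),
                   r_viability = c(0.95, 0.8, 0.7),
                   defined = TRUE)
  expect_equal(selectBestScenario(ev), "S1")          # viability tie-break
  ev$r_viability <- c(0.95, 0.8, 0.8)
  expect_equal(selectBestScenario(ev), "S1")          # name tie-break
  expect_equal(selectBestScenario(ev[1, ]), "S2")     # single scenario
  ev$defined <- FALSE
  expect_error(selectBestScenario(ev), "no defined scenario")
  # deterministic under the documented ordering
  ev$defined <- TRUE
  expect_identical(selectBestScenario(ev), selectBestScenario(ev[3:1, ]))
})

test_that("summarizeByGroup computes per-group sample statistics", {
  res <- data.frame(image_id = c("a", "b"), total_count = c(100L, 120L),
                    viability_pct = c(40, 60))
  s <- summarizeByGroup(res, c(a = "G1", b = "G1"))
  expect_equal(s$n, 2L)
  expect_equal(s$pv_mean, 50)
  expect_equal(s$pv_sd, sqrt(200))    # sample sd, n - 1 denominator
  expect_equal(s$count_mean, 110)
  # empty results for a mapped group: n = 0 row
  s2 <- summarizeByGroup(res, c(a = "G1", b = "G1", zz = "G2"))
  expect_equal(s2$n[s2$group == "G2"], 0L)
  expect_true(is.na(s2$pv_mean[s2$group == "G2"]))
  # unmapped image is an error
  expect_error(summarizeByGroup(res, c(a = "G1")), "not mapped")
  # undefined PV rows are excluded and counted
  res$viability_pct[2] <- NA
  s3 <- summarizeByGroup(res, c(a = "G1", b = "G1"))
  expect_equal(s3$n_pv_excluded, 1L)
  expect_equal(s3$pv_mean, 40)
})

test_that("groups with distinct true viability separate by more than 3 pooled SD", {
  hi <- lapply(601:603, function(s) quickScene(s, nViable = 14L, nNonviable = 2L))
  lo <- lapply(604:606, function(s) quickScene(s, nViable = 3L, nNonviable = 13L))
  imgs <- c(lapply(hi, `[[`, "image"), lapply(lo, `[[`, "image"))
  res <- runScenarios(imgs, scenarioCatalog()["S1"])
  groups <- stats::setNames(rep(c("high", "low"), each = 3),
                            vapply(imgs, imageId, character(1)))
  s <- summarizeByGroup(res, groups)
  pooled <- sqrt(mean(s$pv_sd^2))
  expect_gt(abs(diff(s$pv_mean)), 3 * pooled)
})
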
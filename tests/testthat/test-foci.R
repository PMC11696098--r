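test_that("equalization flattens constants and is scale invariant", {
  eq <- equalizeLocal(matrix(3.7, 48, 48), 5)
  expect_lt(max(abs(eq - 1)), 1e-6)

  plane <- matrix(runif(64 * 64, 10, 50), 64, 64)
  e1 <- equalizeLocal(plane, 4)
  e2 <- equalizeLocal(7.3 * plane, 4)
  expect_lt(max(abs(e1 - e2) / abs(e1)), 1e-9)

  ## all-zero plane returns all ones by convention
  expect_equal(equalizeLocal(matrix(0, 32, 32), 4), matrix(1, 32, 32))
  expect_error(equalizeLocal(plane, 0), "positive")
})

test_that("equalization matches a direct-kernel oracle and peaks on spots", {
  sigma <- 4
  plane <- matrix(20, 64, 64)
  d2 <- outer((seq_len(64) - 32)^2, (seq_len(64) - 32)^2, "+")
  plane <- plane + 300 * exp(-d2 / (2 * 2^2))
  pos <- plane[plane > 0]
  delta <- 1e-6 * mean(pos)
  ref <- (plane + delta) / (refGaussBlur(plane, sigma) + delta)
  got <- equalizeLocal(plane, sigma)
  expect_lt(max(abs(got - ref)), 1e-6)
  expect_gt(got[32, 32], 1)
  far <- sqrt(d2) > 3 * sigma
  expect_true(all(got[32, 32] > got[far]))
})

test_that("detection keeps disks above the area gate and drops specks", {
  plane <- matrix(1, 96, 96)
  for (ct in list(c(20, 20), c(50, 60), c(75, 30)))
    plane[mkDisk(96, ct[1], ct[2], 2.6)] <- 200   # area 21 px each
  plane[40, 80] <- 200; plane[41, 80] <- 200      # 2-px speck
  ft <- detectFoci(plane, fociParams(eqSigmaPx = 8, rawThreshold = 100,
                                     minFocusAreaPx = 5L))
  expect_equal(nrow(fociInfo(ft)), 3L)
  expect_true(all(fociInfo(ft)$area_px == 21L))
  ## post-hoc re-check: every row satisfies every active filter
  expect_true(all(fociInfo(ft)$area_px >= 5L & fociInfo(ft)$area_px <= 400L))

  ## empty input gives a valid empty table
  ft0 <- detectFoci(matrix(0, 64, 64), fociParams())
  expect_equal(nrow(fociInfo(ft0)), 0L)
  expect_true(validObject(ft0))
})

test_that("circularity filter separates disks from lines", {
  ## frozen reference perimeters from an independent implementation
  disk8 <- mkDisk(29, 15, 15, 8)
  expect_equal(maskPerimeter(disk8), 52.250114, tolerance = 1e-6)
  line <- matrix(FALSE, 10, 40); line[5, 5:34] <- TRUE
  expect_equal(maskPerimeter(line), 57.668965, tolerance = 1e-6)
  expect_gt(maskCircularity(disk8), 0.9)
  expect_lt(maskCircularity(line), 0.3)

  plane <- matrix(1, 80, 80)
  plane[mkDisk(80, 25, 25, 8)] <- 300
  plane[60, 20:49] <- 300
  prmOff <- fociParams(eqSigmaPx = 10, rawThreshold = 100,
                       minFocusAreaPx = 5L, circularityMin = "off")
  prmOn <- fociParams(eqSigmaPx = 10, rawThreshold = 100,
                      minFocusAreaPx = 5L, circularityMin = 0.6)
  expect_equal(nrow(fociInfo(detectFoci(plane, prmOff))), 2L)
  info <- fociInfo(detectFoci(plane, prmOn))
  expect_equal(nrow(info), 1L)
  expect_gt(info$circularity, 0.6)
})

test_that("the foci mask is contained in the raw-threshold mask", {
  sc <- simulateScene(smallScene(71L, nCells = 3L,
                                 fractionFociPositiveCells = 1))
  bg <- subtractBackground(getChannel(sc$image, "lc3b"), 100)
  ft <- detectFoci(bg, fociParams())
  thr <- ft@provenance$rawThresholdUsed
  expect_true(all(bg[fociMask(ft)] >= thr))
  ## detected foci labels live inside the mask and are disjoint by value
  expect_true(all(fociMask(ft)[fociLabels(ft) > 0L]))
})

test_that("rescaling the plane leaves the detected foci unchanged (Otsu)", {
  sc <- simulateScene(smallScene(72L, nCells = 3L,
                                 fractionFociPositiveCells = 1))
  bg <- subtractBackground(getChannel(sc$image, "lc3b"), 100)
  for (mth in c("otsu", "otsu-foreground")) {
    a <- detectFoci(bg, fociParams(rawThreshold = mth))
    b <- detectFoci(bg * 5.7, fociParams(rawThreshold = mth))
    expect_identical(fociMask(a), fociMask(b))
    expect_equal(fociInfo(a)$area_px, fociInfo(b)$area_px)
  }
})

test_that("cell positivity uses a strict pixel-count cutoff", {
  lab <- matrix(0L, 30, 30)
  lab[5:14, 5:14] <- 1L; lab[5:14, 18:27] <- 2L; lab[18:27, 5:14] <- 3L
  lm <- mkLabelMap(lab)
  mask <- matrix(FALSE, 30, 30)
  mask[6, 19:23] <- TRUE              # exactly 5 px in cell 2
  mask[19:24, 6:7] <- TRUE            # 12 px in cell 3
  res <- callCellsFociPositive(lm, mask, minFociPixelsPerCell = 5L)
  expect_equal(res$perCell$foci_pixels, c(0L, 5L, 12L))
  ## 0 px and exactly-at-cutoff are both negative ("above a threshold")
  expect_equal(res$perCell$positive, c(FALSE, FALSE, TRUE))
  expect_equal(res$fractionPositive, 1 / 3)
  expect_false(res$noCells)

  ## zero cells: flagged, not reported as 0
  empty <- mkLabelMap(matrix(0L, 30, 30))
  res0 <- callCellsFociPositive(empty, mask, minFociPixelsPerCell = 5L)
  expect_true(res0$noCells)
  expect_true(is.na(res0$fractionPositive))
})

test_that("puncta statistics summarize counts and areas by group", {
  df <- data.frame(area_px = c(4, 9, 16), grp = "a")
  st <- punctaStats(df, by = "grp")
  expect_equal(st$n_punctae, 3L)
  expect_equal(st$median_area_px, 9)

  st0 <- punctaStats(data.frame(area_px = numeric(0)))
  expect_equal(st0$n_punctae, 0L)
  expect_true(is.na(st0$median_area_px))

  st2 <- punctaStats(data.frame(area_px = c(2, 3, 50, 80), grp = "a"),
                     by = "grp", largeAreaCutoff = 10)
  expect_equal(st2$n_large, 2L)
  expect_equal(st2$n_small, 2L)
})

test_that("median puncta area scales with the squared focus radius", {
  ## noiseless renders, fixed thresholds: detected area of a Gaussian spot
  ## is ~ 2 pi s^2 log(A/thr), so radius 2 vs 4 gives a ratio near 4
  medArea <- function(r, seeds) {
    areas <- c()
    for (s in seeds) {
      sc <- simulateScene(sceneParams(seed = s, focusRadiusPx = r,
                                      shotNoise = FALSE, readNoiseSd = 0,
                                      fociPerPositiveCellMean = 1.2,
                                      fractionFociPositiveCells = 1))
      bg <- subtractBackground(getChannel(sc$image, "lc3b"), 100)
      ## threshold well above the cytosolic level probes pure spot geometry
      ft <- detectFoci(bg, fociParams(rawThreshold = 300, eqThreshold = 1.05))
      areas <- c(areas, fociInfo(ft)$area_px)
    }
    median(areas)
  }
  m2 <- medArea(2, 901:903)
  m4 <- medArea(4, 901:903)
  expect_gt(m4, m2)
  expect_lt(abs(m4 / m2 - 4) / 4, 0.25)
})

test_that("detected focus counts track ground truth within 10% on average", {
  ratios <- numeric(0)
  for (s in 1:30) {
    sc <- simulateScene(sceneParams(seed = 950L + s))
    bg <- subtractBackground(getChannel(sc$image, "lc3b"), 100)
    ft <- detectFoci(bg, fociParams())
    det <- nrow(fociInfo(ft)) + ft@provenance$nBorderFoci
    tr <- nrow(focusRecords(sc$truth))
    if (tr > 0) ratios <- c(ratios, det / tr)
  }
  expect_gte(length(ratios), 25L)
  expect_gt(mean(ratios), 0.9)
  expect_lt(mean(ratios), 1.1)
})
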
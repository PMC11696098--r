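test_that("per-cell Pearson hits the closed-form anchors", {
  lab <- matrix(0L, 12, 12)
  lab[2:5, 2:5] <- 1L; lab[7:11, 7:11] <- 2L
  lm <- mkLabelMap(lab)
  set.seed(3)
  a <- matrix(runif(144), 12, 12)

  r1 <- pearsonPerCell(a, a, lm)
  expect_equal(r1$pearson_r, c(1, 1), tolerance = 1e-12)
  r2 <- pearsonPerCell(a, max(a) - a, lm)
  expect_equal(r2$pearson_r, c(-1, -1), tolerance = 1e-12)

  ## linearity: r(X, aX + b) = sign(a)
  r3 <- pearsonPerCell(a, 2.5 * a + 7, lm)
  expect_equal(r3$pearson_r, c(1, 1), tolerance = 1e-12)

  ## six-pixel cell against an independent direct-formula computation
  lab6 <- matrix(0L, 2, 6); lab6[1:2, 1:3] <- 1L
  av <- matrix(c(1, 2, 3, 4, 5, 6), 2, 6); av[lab6 == 0L] <- 0
  bv <- matrix(0, 2, 6); bv[lab6 == 1L] <- c(1, 3, 2, 4, 6, 5)
  got <- pearsonPerCell(av, bv, mkLabelMap(lab6))
  expect_equal(got$pearson_r, refPearson(c(1, 2, 3, 4, 5, 6),
                                         c(1, 3, 2, 4, 6, 5)),
               tolerance = 1e-12)

  ## constant channel within a cell: undefined, not zero
  cst <- matrix(5, 12, 12)
  r4 <- pearsonPerCell(a, cst, lm)
  expect_true(all(!r4$defined))
  expect_true(all(is.na(r4$pearson_r)))

  expect_error(pearsonPerCell(a, matrix(1, 5, 5), lm), "dimensions")
})

test_that("donut ratio applies a strict threshold at 1.75", {
  mask <- matrix(FALSE, 24, 24)
  mask[mkDisk(24, 12, 12, 3)] <- TRUE
  ft <- mkFociTable(mask)

  ## focus uniformly 175, surroundings uniformly 100 -> ratio exactly 1.75
  marker <- matrix(100, 24, 24)
  marker[mask] <- 175
  sc <- donutRatio(ft, marker, dilationRadiusPx = 2L,
                   positivityThreshold = 1.75)
  expect_equal(sc$ratio, 1.75, tolerance = 1e-12)
  expect_false(sc$positive)            # strictly greater than, not >=
  expect_true(sc$defined)

  ## flat marker -> ratio 1, negative
  flat <- donutRatio(ft, matrix(7, 24, 24), 2L, 1.75)
  expect_equal(flat$ratio, 1, tolerance = 1e-12)
  expect_false(flat$positive)

  ## ratio just above the threshold -> positive
  marker[mask] <- 175.0001
  expect_true(donutRatio(ft, marker, 2L, 1.75)$positive)
})

test_that("donut rings exclude all foci pixels and match a per-pixel oracle", {
  mask <- matrix(FALSE, 26, 26)
  mask[mkDisk(26, 13, 9, 2)] <- TRUE
  mask[mkDisk(26, 13, 17, 2)] <- TRUE   # centers 8 px apart, edges ~3 px
  ft <- mkFociTable(mask)
  expect_equal(nrow(fociInfo(ft)), 2L)
  set.seed(11)
  marker <- matrix(runif(26 * 26, 10, 60), 26, 26)
  got <- donutRatio(ft, marker, dilationRadiusPx = 2L)
  for (k in 1:2) {
    ref <- refDonut(mask, k, fociLabels(ft), marker, 2)
    expect_equal(got$focus_mean[k], ref$focusMean, tolerance = 1e-12)
    expect_equal(got$ring_mean[k], ref$ringMean, tolerance = 1e-12)
    expect_equal(got$ring_n_pixels[k], ref$ringN)
  }
  ## rings never overlap foci pixels by construction: re-check post hoc
  ## (ring means computed over marker with foci zeroed must be unchanged)
  markerZ <- marker; markerZ[mask] <- 0
  gotZ <- donutRatio(ft, markerZ, dilationRadiusPx = 2L)
  expect_equal(got$ring_mean, gotZ$ring_mean, tolerance = 1e-12)
})

test_that("a zero-intensity ring yields an undefined, negative score", {
  mask <- matrix(FALSE, 20, 20)
  mask[mkDisk(20, 10, 10, 2)] <- TRUE
  ft <- mkFociTable(mask)
  ## bright focus over a completely dark surround: the ratio is undefined
  ## (flagged NA), the focus is scored negative, and a warning is issued
  marker <- matrix(0, 20, 20)
  marker[mask] <- 50
  expect_warning(sc <- donutRatio(ft, marker, dilationRadiusPx = 2L),
                 "undefined")
  expect_true(is.na(sc$ratio))
  expect_false(sc$positive)
  expect_false(sc$defined)
  expect_gt(sc$ring_n_pixels, 0L)
})

test_that("donut ratio is invariant under marker rescaling, not shifts", {
  mask <- matrix(FALSE, 24, 24)
  mask[mkDisk(24, 12, 12, 3)] <- TRUE
  ft <- mkFociTable(mask)
  set.seed(4)
  marker <- matrix(runif(24 * 24, 5, 50), 24, 24)
  a <- donutRatio(ft, marker, 2L)
  b <- donutRatio(ft, marker * 3.14, 2L)
  expect_equal(a$ratio, b$ratio, tolerance = 1e-12)
  shifted <- donutRatio(ft, marker + 100, 2L)
  expect_false(isTRUE(all.equal(a$ratio, shifted$ratio)))
})

test_that("fractions of positive foci aggregate singly and jointly", {
  mk <- function(pos, def = rep(TRUE, 4))
    data.frame(focus_id = 1:4, positive = pos & def, defined = def)
  allPos <- percentFociPositive(mk(rep(TRUE, 4)))
  expect_equal(allPos$percent, 100)

  ## M1 positive on {1,2}, M2 on {2,3} -> joint "both" = 1/4
  both <- percentFociPositive(list(
    M1 = mk(c(TRUE, TRUE, FALSE, FALSE)),
    M2 = mk(c(FALSE, TRUE, TRUE, FALSE))))
  expect_equal(both$fraction, 0.25)
  expect_equal(both$percent, 25)

  ## undefined scores leave the denominator
  part <- percentFociPositive(mk(c(TRUE, TRUE, FALSE, FALSE),
                                 def = c(TRUE, TRUE, FALSE, TRUE)))
  expect_equal(part$n_defined, 3L)
  expect_equal(part$fraction, 2 / 3)

  ## empty group flagged, not zero
  none <- percentFociPositive(mk(rep(FALSE, 4), def = rep(FALSE, 4)))
  expect_true(none$empty)
  expect_true(is.na(none$fraction))
})

test_that("plate aggregation follows median-within, mean-across wells", {
  one <- data.frame(well_id = "A01", field_id = "F01",
                    value = c(0.2, 0.5, 0.9))
  ag <- aggregatePlate(one)
  expect_equal(ag$perImage$image_median, 0.5)
  expect_equal(ag$perWell$well_value, 0.5)

  three <- data.frame(well_id = c("A01", "A02", "A03"),
                      field_id = "F01", value = c(0.1, 0.2, 0.6))
  ag3 <- aggregatePlate(three)
  expect_equal(ag3$acrossWells$mean, 0.3, tolerance = 1e-12)
  expect_equal(ag3$acrossWells$sd, sqrt(sum((c(0.1, 0.2, 0.6) - 0.3)^2) / 2),
               tolerance = 1e-12)
  expect_equal(ag3$acrossWells$sd, 0.2645751, tolerance = 1e-6)

  ## randomized nested values vs an independent flat tapply oracle
  set.seed(8)
  df <- data.frame(
    well_id = sample(sprintf("A%02d", 1:4), 200, replace = TRUE),
    field_id = sample(sprintf("F%02d", 1:3), 200, replace = TRUE),
    value = rnorm(200))
  ag4 <- aggregatePlate(df)
  refImg <- tapply(df$value, paste(df$well_id, df$field_id), median)
  expect_equal(sort(as.numeric(refImg)), sort(ag4$perImage$image_median))
  refWell <- tapply(as.numeric(refImg),
                    sub(" .*", "", names(refImg)), median)
  expect_equal(as.numeric(refWell[ag4$perWell$well_id]),
               ag4$perWell$well_value)
  expect_equal(ag4$acrossWells$mean, mean(as.numeric(refWell)),
               tolerance = 1e-12)
  expect_equal(ag4$acrossWells$sd, sd(as.numeric(refWell)),
               tolerance = 1e-12)

  ## mean-across-images mode
  agM <- aggregatePlate(df, wellStatistic = "mean")
  refWellM <- tapply(as.numeric(refImg), sub(" .*", "", names(refImg)), mean)
  expect_equal(as.numeric(refWellM[agM$perWell$well_id]),
               agM$perWell$well_value)

  ## an image with only undefined values is dropped with a warning
  bad <- data.frame(well_id = c("A01", "A02"), field_id = "F01",
                    value = c(NA, 0.5), defined = c(FALSE, TRUE))
  expect_warning(agB <- aggregatePlate(bad), "dropped")
  expect_equal(agB$perWell$well_id, "A02")
})

test_that("within-cell shuffling of the marker destroys correlation", {
  sc <- simulateScene(sceneParams(seed = 150L, fractionFociPositiveCells = 1))
  bgL <- subtractBackground(getChannel(sc$image, "lc3b"), 100)
  bgM <- subtractBackground(getChannel(sc$image, "marker"), 100)
  lm <- segmentCells(bgL, segmentationParams())
  base <- pearsonPerCell(bgL, bgM, lm)
  expect_gt(median(base$pearson_r[base$defined]), 0.2)
  set.seed(42)
  meds <- replicate(30, {
    shuf <- bgM
    for (k in seq_len(nCells(lm))) {
      idx <- which(labelMatrix(lm) == k)
      shuf[idx] <- bgM[sample(idx)]
    }
    r <- pearsonPerCell(bgL, shuf, lm)
    median(r$pearson_r[r$defined])
  })
  expect_lt(max(abs(meds)), 0.1)
})
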
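test_that("scene parameters validate ranges and name the offending field", {
  expect_s4_class(sceneParams(), "SceneParams")
  expect_error(sceneParams(imageHeightPx = 32L), "imageHeightPx")
  expect_error(sceneParams(fractionFociPositiveCells = 1.2),
               "fractionFociPositiveCells")
  expect_error(sceneParams(psfSigmaPx = 0), "psfSigmaPx")
  expect_error(sceneParams(fociAnnulus = c(0.6, 0.2)), "fociAnnulus")
})

test_that("an empty scene is background plus noise with empty records", {
  sc <- simulateScene(sceneParams(nCells = 0L, seed = 5L))
  expect_equal(nrow(cellRecords(sc$truth)), 0L)
  expect_equal(nrow(focusRecords(sc$truth)), 0L)
  ## noiseless empty scene equals the (ramped) background exactly
  sc0 <- simulateScene(sceneParams(nCells = 0L, seed = 5L, shotNoise = FALSE,
                                   readNoiseSd = 0, backgroundGradient = 0))
  expect_equal(unname(getChannel(sc0$image, "lc3b")),
               matrix(40, 256, 256))
  expect_equal(unname(getChannel(sc0$image, "marker")),
               matrix(40, 256, 256))
})

test_that("identical parameters give bit-identical scenes", {
  p <- sceneParams(seed = 42L)
  a <- simulateScene(p); b <- simulateScene(p)
  expect_identical(a$image@channels, b$image@channels)
  expect_identical(cellRecords(a$truth), cellRecords(b$truth))
  expect_identical(focusRecords(a$truth), focusRecords(b$truth))
  ## and the generator does not disturb the caller's RNG stream
  set.seed(7); before <- runif(3)
  set.seed(7); invisible(simulateScene(p)); after <- runif(3)
  expect_identical(before, after)
})

test_that("cell disks are placed without overlap and inside the field", {
  sc <- simulateScene(sceneParams(seed = 9L))
  cr <- cellRecords(sc$truth)
  expect_gte(nrow(cr), 1L)
  d <- as.matrix(dist(cr[, c("center_row", "center_col")]))
  sep <- outer(cr$radius_px, cr$radius_px, "+")
  diag(d) <- Inf
  expect_true(all(d > sep))
  expect_true(all(cr$center_row - cr$radius_px > 0))
  expect_true(all(cr$center_row + cr$radius_px < 256))
  ## every focus references an existing cell
  fr <- focusRecords(sc$truth)
  expect_true(all(fr$cell_id %in% cr$cell_id))
})

test_that("foci per positive cell follow the zero-truncated Poisson", {
  ## oracle: closed-form mean of Poisson(lambda) conditioned on >= 1
  lambda <- 4
  truthMean <- lambda / (1 - exp(-lambda))
  ks <- integer(0)
  for (s in 1:12) {
    sc <- simulateScene(sceneParams(seed = 800L + s,
                                    fractionFociPositiveCells = 1))
    cr <- cellRecords(sc$truth)
    ks <- c(ks, cr$n_foci[cr$is_foci_positive])
  }
  expect_gte(length(ks), 150L)
  expect_true(all(ks >= 1L))
  se <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - truthMean), 3 * se)
})

test_that("noiseless renders are exact and conserve focus intensity", {
  p <- sceneParams(seed = 21L, shotNoise = FALSE, readNoiseSd = 0)
  a <- simulateScene(p); b <- simulateScene(p)
  expect_identical(a$image@channels, b$image@channels)

  ## focus layer = scene minus the same scene rendered without foci;
  ## its total intensity must equal nFoci x the analytic kernel integral
  p0 <- p; p0@focusAmplitude <- 0
  noFoci <- simulateScene(p0)
  layer <- getChannel(a$image, "lc3b") - getChannel(noFoci$image, "lc3b")
  nFoci <- nrow(focusRecords(a$truth))
  sFoc <- p@focusRadiusPx / 2
  analytic <- nFoci * p@focusAmplitude * 2 * pi * sFoc^2
  expect_lt(abs(sum(layer) - analytic) / analytic, 0.005)
})

test_that("marker foci appear only at marker-positive lc3b foci", {
  p <- sceneParams(seed = 33L, shotNoise = FALSE, readNoiseSd = 0,
                   markerDiffuseAmplitude = 0, backgroundLevel = 0,
                   fractionFociPositiveCells = 1)
  sc <- simulateScene(p)
  marker <- getChannel(sc$image, "marker")
  fr <- focusRecords(sc$truth)
  pos <- fr[fr$is_marker_positive, ]
  neg <- fr[!fr$is_marker_positive, ]
  ## distance of every bright marker pixel to the nearest positive focus
  idx <- which(marker > 1)
  rows <- (idx - 1) %% 256 + 1; cols <- (idx - 1) %/% 256 + 1
  dPos <- sapply(seq_along(idx), function(k)
    min(sqrt((pos$center_row - rows[k])^2 + (pos$center_col - cols[k])^2)))
  expect_true(all(dPos < 8))
  ## marker signal vanishes at marker-negative foci
  if (nrow(neg) > 0) {
    at <- marker[cbind(round(neg$center_row), round(neg$center_col))]
    expect_true(all(at < 1))
  }
  ## total marker intensity matches the analytic integral over positive foci
  sFoc <- p@focusRadiusPx / 2
  analytic <- nrow(pos) * p@markerFocusAmplitude * 2 * pi * sFoc^2
  expect_lt(abs(sum(marker) - analytic) / analytic, 0.005)
})

test_that("plates enumerate wells deterministically with working overrides", {
  p <- smallScene(1L)
  plate <- simulatePlate(p, nWells = 2L, fieldsPerWell = 3L)
  expect_length(plate, 6L)
  keys <- vapply(plate, function(f) paste(f$wellId, f$fieldId), "")
  expect_false(anyDuplicated(keys) > 0)

  plate2 <- simulatePlate(p, nWells = 2L, fieldsPerWell = 3L)
  for (i in seq_along(plate))
    expect_identical(plate[[i]]$image@channels, plate2[[i]]$image@channels)

  ## wells differing in foci fraction are ordered in ground truth
  pl <- simulatePlate(sceneParams(seed = 2L), nWells = 2L, fieldsPerWell = 4L,
                      perWellOverrides = list(
                        A01 = list(fractionFociPositiveCells = 0.1),
                        A02 = list(fractionFociPositiveCells = 0.8)))
  fracOf <- function(w) {
    cr <- do.call(rbind, lapply(Filter(function(f) f$wellId == w, pl),
                                function(f) cellRecords(f$truth)))
    mean(cr$is_foci_positive)
  }
  expect_lt(fracOf("A01"), fracOf("A02"))

  expect_error(simulatePlate(p, 2L, 1L,
                             perWellOverrides = list(Z99 = list(nCells = 1L))),
               "unknown well")
  expect_error(simulatePlate(p, 0L, 1L), ">= 1")
})

test_that("quantization rounds to integer ADU within 16-bit range", {
  sc <- simulateScene(smallScene(4L))
  q <- quantizeImage(sc$image)
  for (ch in channelNames(q)) {
    p <- getChannel(q, ch)
    expect_true(all(p == round(p)))
    expect_true(all(p >= 0 & p <= 65535))
  }
})
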
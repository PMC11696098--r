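#' Parameters for the synthetic microscopy scene generator
#'
#' Builds a validated [SceneParams-class] object. The defaults describe the
#' study conditions the package is validated under: a 256 x 256 px field of
#' 15 non-overlapping adherent cells of radius 18 +/- 2 px rendered as
#' soft-edged disks, a cytosolic LC3B-like channel at amplitude 120 ADU over
#' a 40 ADU background, with half of the cells carrying on average 4 bright
#' (800 ADU) perinuclear foci of nominal radius 3 px; a marker channel
#' carries a 600 ADU spot on each focus with probability `pMarkerColoc`
#' (default 0.8) over a 30 ADU diffuse cytosolic level; the render is
#' convolved with a 1 px Gaussian PSF and degraded with Poisson shot noise
#' plus 5 ADU Gaussian read noise.
#'
#' @param imageHeightPx,imageWidthPx image dimensions in pixels (>= 64).
#' @param nCells number of cells to place.
#' @param cellRadiusMeanPx,cellRadiusSdPx cell radius distribution (px).
#' @param fractionFociPositiveCells probability a cell carries foci.
#' @param fociPerPositiveCellMean Poisson rate of foci per positive cell,
#'   conditioned on >= 1.
#' @param focusRadiusPx nominal focus radius (rendered as a Gaussian spot of
#'   sigma = focusRadiusPx / 2).
#' @param focusAmplitude,cytosolAmplitude,backgroundLevel intensities (ADU).
#' @param backgroundGradient fractional linear background ramp across the
#'   field width.
#' @param psfSigmaPx point-spread sigma (px).
#' @param pMarkerColoc probability a focus carries marker signal.
#' @param markerFocusAmplitude,markerDiffuseAmplitude marker intensities.
#' @param nucleusAmplitude,nucleusRadiusFrac nucleus channel blob parameters.
#' @param fociAnnulus perinuclear annulus (fractions of the cell radius)
#'   within which foci are placed.
#' @param edgeSoftnessPx softness of the cell edge sigmoid (px).
#' @param readNoiseSd Gaussian read noise sd (ADU).
#' @param shotNoise apply Poisson shot noise?
#' @param quantize round intensities to integer ADU (16-bit clipped)?
#' @param seed integer seed.
#' @return a [SceneParams-class] object.
#' @seealso [simulateScene()], [simulatePlate()]
#' @export
sceneParams <- function(imageHeightPx = 256L, imageWidthPx = 256L,
                        nCells = 15L,
                        cellRadiusMeanPx = 18, cellRadiusSdPx = 2,
                        fractionFociPositiveCells = 0.5,
                        fociPerPositiveCellMean = 4,
                        focusRadiusPx = 3,
                        focusAmplitude = 800, cytosolAmplitude = 120,
                        backgroundLevel = 40, backgroundGradient = 0.1,
                        psfSigmaPx = 1,
                        pMarkerColoc = 0.8,
                        markerFocusAmplitude = 600,
                        markerDiffuseAmplitude = 30,
                        nucleusAmplitude = 500, nucleusRadiusFrac = 0.35,
                        fociAnnulus = c(0.2, 0.6),
                        edgeSoftnessPx = 1.5,
                        readNoiseSd = 5, shotNoise = TRUE,
                        quantize = FALSE, seed = 1L) {
  new("SceneParams",
      imageHeightPx = as.integer(imageHeightPx),
      imageWidthPx = as.integer(imageWidthPx),
      nCells = as.integer(nCells),
      cellRadiusMeanPx = as.numeric(cellRadiusMeanPx),
      cellRadiusSdPx = as.numeric(cellRadiusSdPx),
      fractionFociPositiveCells = as.numeric(fractionFociPositiveCells),
      fociPerPositiveCellMean = as.numeric(fociPerPositiveCellMean),
      focusRadiusPx = as.numeric(focusRadiusPx),
      focusAmplitude = as.numeric(focusAmplitude),
      cytosolAmplitude = as.numeric(cytosolAmplitude),
      backgroundLevel = as.numeric(backgroundLevel),
      backgroundGradient = as.numeric(backgroundGradient),
      psfSigmaPx = as.numeric(psfSigmaPx),
      pMarkerColoc = as.numeric(pMarkerColoc),
      markerFocusAmplitude = as.numeric(markerFocusAmplitude),
      markerDiffuseAmplitude = as.numeric(markerDiffuseAmplitude),
      nucleusAmplitude = as.numeric(nucleusAmplitude),
      nucleusRadiusFrac = as.numeric(nucleusRadiusFrac),
      fociAnnulus = as.numeric(fociAnnulus),
      edgeSoftnessPx = as.numeric(edgeSoftnessPx),
      readNoiseSd = as.numeric(readNoiseSd),
      shotNoise = isTRUE(shotNoise),
      quantize = isTRUE(quantize),
      seed = as.integer(seed))
}

# Copy of `params` with named fields replaced; names are validated.
updateSceneParams <- function(params, overrides) {
  if (length(overrides) == 0L) return(params)
  nms <- names(overrides)
  bad <- setdiff(nms, slotNames("SceneParams"))
  if (length(bad))
    stop(sprintf("unknown SceneParams field(s): %s", paste(bad, collapse = ", ")))
  for (nm in nms) {
    val <- overrides[[nm]]
    cls <- class(slot(params, nm))
    slot(params, nm) <- if (cls == "integer") as.integer(val)
      else if (cls == "logical") isTRUE(val) else as.numeric(val)
  }
  validObject(params)
  params
}

# Add a Gaussian spot (already PSF-folded) to `plane` on a cropped window.
addGaussianSpot <- function(plane, row, col, amplitude, sigma) {
  nr <- nrow(plane); nc <- ncol(plane)
  w <- ceiling(6 * sigma)
  r1 <- max(1L, floor(row - w)); r2 <- min(nr, ceiling(row + w))
  c1 <- max(1L, floor(col - w)); c2 <- min(nc, ceiling(col + w))
  if (r1 > r2 || c1 > c2) return(plane)
  dr2 <- (seq(r1, r2) - row)^2
  dc2 <- (seq(c1, c2) - col)^2
  plane[r1:r2, c1:c2] <- plane[r1:r2, c1:c2] +
    amplitude * exp(-outer(dr2, dc2, "+") / (2 * sigma^2))
  plane
}

# Add a unit-amplitude soft-edged disk (radial sigmoid) on a cropped window.
addSoftDisk <- function(plane, row, col, radius, edge) {
  nr <- nrow(plane); nc <- ncol(plane)
  w <- ceiling(radius + 8 * edge)
  r1 <- max(1L, floor(row - w)); r2 <- min(nr, ceiling(row + w))
  c1 <- max(1L, floor(col - w)); c2 <- min(nc, ceiling(col + w))
  if (r1 > r2 || c1 > c2) return(plane)
  dr2 <- (seq(r1, r2) - row)^2
  dc2 <- (seq(c1, c2) - col)^2
  d <- sqrt(outer(dr2, dc2, "+"))
  plane[r1:r2, c1:c2] <- plane[r1:r2, c1:c2] + 1 / (1 + exp((d - radius) / edge))
  plane
}

# Poisson draw conditioned on >= 1 (simple rejection; rate > 0).
rpoisTrunc1 <- function(lambda) {
  repeat {
    k <- stats::rpois(1L, lambda)
    if (k >= 1L) return(k)
  }
}

#' Simulate one multi-channel field of view with ground truth
#'
#' Renders the channels `nucleus`, `lc3b` and `marker` for one synthetic
#' field: a smooth (optionally ramped) background, soft-edged cytosolic cell
#' disks and perinuclear foci Gaussians in the LC3B channel (all convolved
#' at `psfSigmaPx`), a diffuse cytosolic level plus per-focus spots for the
#' marker channel (spots only on foci drawn marker-positive), and a Gaussian
#' nuclear blob per cell. Noise is applied last: optional Poisson shot noise
#' on the noiseless render, then additive Gaussian read noise, then clipping
#' at zero. Identical parameters (including the seed) give bit-identical
#' output.
#'
#' Cell centers are placed by rejection sampling so that cell disks do not
#' overlap; if placement fails after a bounded number of attempts, fewer
#' cells are placed and the shortfall is recorded in the ground truth.
#'
#' @param params a [SceneParams-class] object (see [sceneParams()]).
#' @param wellId,fieldId identifiers stamped on the output image.
#' @return a list with elements `image` ([MultiChannelImage-class]) and
#'   `truth` ([GroundTruth-class]).
#' @examples
#' sc <- simulateScene(sceneParams(nCells = 4L, seed = 7L))
#' sc$image
#' sc$truth
#' @export
simulateScene <- function(params, wellId = "SIM", fieldId = "F01") {
  validObject(params)
  withSeed(params@seed, simulateSceneImpl(params, wellId, fieldId))
}

simulateSceneImpl <- function(params, wellId, fieldId) {
  nr <- params@imageHeightPx; nc <- params@imageWidthPx

  ## --- placement (rejection sampling of non-overlapping disks) ------------
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  maxAttempts <- 200L * max(1L, params@nCells)
  attempts <- 0L
  while (nrow(centers) < params@nCells && attempts < maxAttempts) {
    attempts <- attempts + 1L
    r <- max(4, stats::rnorm(1L, params@cellRadiusMeanPx, params@cellRadiusSdPx))
    ## keep whole cells (plus soft edge and PSF tails) well inside the
    ## field so cells never touch the border
    lo <- r + 8; hiR <- nr - r - 7; hiC <- nc - r - 7
    if (hiR <= lo || hiC <= lo) next
    cr <- stats::runif(1L, lo, hiR)
    cc <- stats::runif(1L, lo, hiC)
    if (nrow(centers) > 0L) {
      ## disks must not overlap, including their rendered soft edges
      ## (the sigmoid skirt extends ~3 softness lengths beyond the radius)
      d <- sqrt((centers[, 1] - cr)^2 + (centers[, 2] - cc)^2)
      if (any(d < radii + r + 6 * params@edgeSoftnessPx + 1)) next
    }
    centers <- rbind(centers, c(cr, cc))
    radii <- c(radii, r)
  }
  nPlaced <- nrow(centers)

  ## --- truth labels --------------------------------------------------------
  isPos <- if (nPlaced > 0L)
    stats::runif(nPlaced) < params@fractionFociPositiveCells else logical(0)
  nFociPerCell <- integer(nPlaced)
  focusRows <- list()
  fid <- 0L
  for (i in seq_len(nPlaced)) {
    if (!isPos[i]) next
    k <- rpoisTrunc1(params@fociPerPositiveCellMean)
    nFociPerCell[i] <- k
    ## place foci in the perinuclear annulus with a minimum pairwise
    ## separation (rejection sampling) so individual foci stay resolvable;
    ## if no candidate satisfies it, the best-separated candidate is used,
    ## keeping the drawn focus count exact
    minSep <- 3 * params@focusRadiusPx
    fr <- fc <- numeric(k)
    for (j in seq_len(k)) {
      best <- c(NA, NA); bestD <- -Inf
      for (a in 1:150) {
        u <- stats::runif(1, params@fociAnnulus[1], params@fociAnnulus[2]) *
          radii[i]
        th <- stats::runif(1, 0, 2 * pi)
        cand <- centers[i, ] + u * c(sin(th), cos(th))
        d <- if (j == 1L) Inf else
          min(sqrt((fr[seq_len(j - 1)] - cand[1])^2 +
                     (fc[seq_len(j - 1)] - cand[2])^2))
        if (d > bestD) { bestD <- d; best <- cand }
        if (d >= minSep) break
      }
      fr[j] <- best[1]; fc[j] <- best[2]
    }
    mk <- stats::runif(k) < params@pMarkerColoc
    for (j in seq_len(k)) {
      fid <- fid + 1L
      focusRows[[fid]] <- data.frame(
        focus_id = fid, cell_id = i, center_row = fr[j], center_col = fc[j],
        radius_px = params@focusRadiusPx, is_marker_positive = mk[j])
    }
  }
  focusRecords <- if (length(focusRows)) do.call(rbind, focusRows) else
    data.frame(focus_id = integer(0), cell_id = integer(0),
               center_row = numeric(0), center_col = numeric(0),
               radius_px = numeric(0), is_marker_positive = logical(0))
  cellRecords <- data.frame(
    cell_id = seq_len(nPlaced),
    center_row = if (nPlaced) centers[, 1] else numeric(0),
    center_col = if (nPlaced) centers[, 2] else numeric(0),
    radius_px = radii, is_foci_positive = isPos, n_foci = nFociPerCell)

  ## --- noiseless render ----------------------------------------------------
  ramp <- if (nc > 1)
    params@backgroundGradient * ((seq_len(nc) - 1) / (nc - 1) - 0.5) else 0
  background <- matrix(params@backgroundLevel, nr, nc) *
    (1 + matrix(ramp, nr, nc, byrow = TRUE))

  unitCyto <- matrix(0, nr, nc)
  nucleus <- background
  for (i in seq_len(nPlaced)) {
    unitCyto <- addSoftDisk(unitCyto, centers[i, 1], centers[i, 2],
                            radii[i], params@edgeSoftnessPx)
    sn <- params@nucleusRadiusFrac * radii[i]
    sEff <- sqrt(sn^2 + params@psfSigmaPx^2)
    nucleus <- addGaussianSpot(nucleus, centers[i, 1], centers[i, 2],
                               params@nucleusAmplitude * sn^2 / sEff^2, sEff)
  }
  unitCytoBlur <- if (nPlaced > 0L) gaussBlur(unitCyto, params@psfSigmaPx)
    else unitCyto

  sFoc <- params@focusRadiusPx / 2
  sFocEff <- sqrt(sFoc^2 + params@psfSigmaPx^2)
  fociLc3b <- matrix(0, nr, nc)
  fociMarker <- matrix(0, nr, nc)
  for (j in seq_len(nrow(focusRecords))) {
    fr <- focusRecords[j, ]
    fociLc3b <- addGaussianSpot(fociLc3b, fr$center_row, fr$center_col,
                                params@focusAmplitude * sFoc^2 / sFocEff^2,
                                sFocEff)
    if (fr$is_marker_positive)
      fociMarker <- addGaussianSpot(fociMarker, fr$center_row, fr$center_col,
                                    params@markerFocusAmplitude *
                                      sFoc^2 / sFocEff^2, sFocEff)
  }

  lc3b <- background + params@cytosolAmplitude * unitCytoBlur + fociLc3b
  marker <- background + params@markerDiffuseAmplitude * unitCytoBlur +
    fociMarker

  ## --- noise (shot, then read, then clip at 0) -----------------------------
  applyNoise <- function(plane) {
    v <- as.numeric(plane)
    if (params@shotNoise) v <- as.numeric(stats::rpois(length(v), v))
    if (params@readNoiseSd > 0)
      v <- v + stats::rnorm(length(v), 0, params@readNoiseSd)
    matrix(pmax(v, 0), nr, nc)
  }
  channels <- list(nucleus = applyNoise(nucleus),
                   lc3b = applyNoise(lc3b),
                   marker = applyNoise(marker))
  if (params@quantize)
    channels <- lapply(channels, function(p) pmin(round(p), 65535))

  img <- multiChannelImage(channels, wellId = wellId, fieldId = fieldId,
                           bitDepth = if (params@quantize) 16 else NA_real_)
  truth <- new("GroundTruth", cellRecords = cellRecords,
               focusRecords = focusRecords, params = params,
               nRequested = params@nCells, nPlaced = as.integer(nPlaced))
  list(image = img, truth = truth)
}

#' Simulate a multi-well plate of fields
#'
#' Generates `nWells * fieldsPerWell` fields. Each field's scene seed is
#' derived deterministically from `params@seed` and the (well, field) index,
#' so a given plate is fully reproducible and individual wells can differ
#' via `perWellOverrides` (e.g. treated vs untreated foci fractions).
#'
#' @param params base [SceneParams-class].
#' @param nWells,fieldsPerWell plate layout (both >= 1).
#' @param perWellOverrides named list: well id -> named list of SceneParams
#'   fields to override for that well. Referencing an unknown well is an
#'   error.
#' @return a list of per-field entries, each a list with elements `wellId`,
#'   `fieldId`, `image` and `truth`.
#' @examples
#' plate <- simulatePlate(sceneParams(nCells = 3L), nWells = 2L,
#'                        fieldsPerWell = 1L,
#'                        perWellOverrides = list(
#'                          A02 = list(fractionFociPositiveCells = 0.9)))
#' vapply(plate, `[[`, "", "wellId")
#' @export
simulatePlate <- function(params, nWells, fieldsPerWell,
                          perWellOverrides = list()) {
  validObject(params)
  nWells <- as.integer(nWells); fieldsPerWell <- as.integer(fieldsPerWell)
  if (nWells < 1L || fieldsPerWell < 1L)
    stop("nWells and fieldsPerWell must both be >= 1")
  wellIds <- plateWellIds(nWells)
  if (length(perWellOverrides)) {
    bad <- setdiff(names(perWellOverrides), wellIds)
    if (length(bad))
      stop(sprintf("perWellOverrides references unknown well(s): %s",
                   paste(bad, collapse = ", ")))
  }
  out <- vector("list", nWells * fieldsPerWell)
  k <- 0L
  for (wi in seq_len(nWells)) {
    wId <- wellIds[wi]
    p <- updateSceneParams(params, perWellOverrides[[wId]])
    for (fi in seq_len(fieldsPerWell)) {
      pf <- p
      pf@seed <- deriveSeed(params@seed, wi, fi)
      fId <- sprintf("F%02d", fi)
      sc <- simulateScene(pf, wellId = wId, fieldId = fId)
      k <- k + 1L
      out[[k]] <- list(wellId = wId, fieldId = fId,
                       image = sc$image, truth = sc$truth)
    }
  }
  out
}

# 96-well-style well ids: A01..A12, B01..B12, ...
plateWellIds <- function(n) {
  i <- seq_len(n) - 1L
  paste0(LETTERS[i %/% 12L + 1L], sprintf("%02d", i %% 12L + 1L))
}

#' Quantize an image to integer ADU
#'
#' Rounds every channel to integer intensities and clips to the 16-bit range
#' (0..65535), emulating camera output for TIFF export.
#'
#' @param img a [MultiChannelImage-class].
#' @return the quantized [MultiChannelImage-class].
#' @export
quantizeImage <- function(img) {
  img@channels <- lapply(img@channels, function(p) pmin(pmax(round(p), 0), 65535))
  img@bitDepth <- 16
  validObject(img)
  img
}
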
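#' Parameters for cell segmentation
#'
#' Builds a validated [SegmentationParams-class]. Defaults suit the
#' synthetic study conditions (cells of radius ~18 px): the cell-scale blur
#' is roughly a quarter of a cell radius, the threshold is Otsu's on the blurred plane, and
#' the area gate keeps components between 100 and 5000 px.
#'
#' @param bgSigmaPx background-estimation sigma for [subtractBackground()];
#'   choose several times the typical cell radius so the background
#'   estimate does not absorb cell-scale mass.
#' @param blurSigmaPx cell-scale blur before thresholding/watershed.
#' @param intensityThreshold `"otsu"` or an explicit non-negative number.
#' @param minCellAreaPx,maxCellAreaPx component area gate in pixels.
#' @param excludeBorderCells drop cells touching the image border
#'   (default TRUE; border cells are truncated and would bias per-cell
#'   statistics).
#' @param watershedTolFrac watershed merge tolerance as a fraction of the
#'   maximum blurred foreground intensity.
#' @return a [SegmentationParams-class] object.
#' @export
segmentationParams <- function(bgSigmaPx = 100, blurSigmaPx = 5,
                               intensityThreshold = "otsu",
                               minCellAreaPx = 100L, maxCellAreaPx = 5000L,
                               excludeBorderCells = TRUE,
                               watershedTolFrac = 0.25) {
  new("SegmentationParams",
      bgSigmaPx = as.numeric(bgSigmaPx), blurSigmaPx = as.numeric(blurSigmaPx),
      intensityThreshold = intensityThreshold,
      minCellAreaPx = as.integer(minCellAreaPx),
      maxCellAreaPx = as.integer(maxCellAreaPx),
      excludeBorderCells = isTRUE(excludeBorderCells),
      watershedTolFrac = as.numeric(watershedTolFrac))
}

#' Automated background subtraction
#'
#' Estimates the smooth background of a plane as a wide Gaussian blur of the
#' plane itself and subtracts it, clipping at zero:
#' `max(0, plane - G_bg(plane))`. With edge-replicating smoothing a constant
#' plane maps to all zeros; structure much smaller than `bgSigmaPx` (cells,
#' foci) is retained.
#'
#' @param plane 2D numeric matrix of finite, non-negative intensities.
#' @param bgSigmaPx positive Gaussian sigma of the background estimate;
#'   should be large relative to the structures of interest (at least twice
#'   the typical cell radius).
#' @return background-subtracted plane (same shape, everywhere >= 0).
#' @examples
#' p <- matrix(10, 64, 64); p[30:34, 30:34] <- 200
#' bs <- subtractBackground(p, bgSigmaPx = 20)
#' bs[32, 32] > 0
#' @export
subtractBackground <- function(plane, bgSigmaPx) {
  stopIfNotFinitePlane(plane)
  if (any(plane < 0)) stop("plane must be non-negative")
  if (!is.numeric(bgSigmaPx) || length(bgSigmaPx) != 1L ||
      is.na(bgSigmaPx) || bgSigmaPx <= 0)
    stop("bgSigmaPx must be a single positive number")
  pmax(plane - gaussBlur(plane, bgSigmaPx), 0)
}

#' Watershed segmentation of single cells
#'
#' Segments individual cells from a (background-subtracted) cytosolic plane
#' by the fixed pipeline: (1) Gaussian blur at `blurSigmaPx`; (2) foreground
#' mask by thresholding the blurred plane (Otsu's threshold on the blurred
#' plane when `intensityThreshold = "otsu"`); (3) watershed of the blurred
#' intensity landscape seeded at its regional maxima within the mask, with
#' maxima closer than about twice `blurSigmaPx` or shallower than the merge
#' tolerance suppressed; (4) the watershed separating lines are imposed on
#' the mask as background; (5) connected components are labeled
#' (4-connected); (6) components outside the area gate are removed; (7)
#' optionally, components touching the image border are removed; (8) labels
#' are renumbered `1..nCells` in raster order of the component centroids.
#'
#' An empty foreground is not an error: the result is a valid
#' [CellLabelMap-class] with `nCells = 0`.
#'
#' @param plane 2D numeric matrix; expected to be background-subtracted
#'   (the caller's responsibility, recorded in provenance).
#' @param params a [SegmentationParams-class] (see [segmentationParams()]).
#' @return a [CellLabelMap-class].
#' @examples
#' sc <- simulateScene(sceneParams(nCells = 5L, seed = 11L))
#' pl <- subtractBackground(getChannel(sc$image, "lc3b"), 40)
#' lm <- segmentCells(pl, segmentationParams())
#' nCells(lm)
#' @export
segmentCells <- function(plane, params = segmentationParams()) {
  stopIfNotFinitePlane(plane)
  validObject(params)
  nr <- nrow(plane); nc <- ncol(plane)

  blurred <- gaussBlur(plane, params@blurSigmaPx)
  thr <- if (identical(params@intensityThreshold, "otsu"))
    otsuThreshold(blurred) else params@intensityThreshold
  mask <- blurred >= thr

  emptyMap <- function() new("CellLabelMap",
    labels = matrix(0L, nr, nc), nCells = 0L,
    provenance = list(params = params, thresholdUsed = thr,
                      connectivity = 4L, lineConnectivity = 4L))
  if (!any(mask)) return(emptyMap())

  ## watershed of the blurred landscape restricted to the mask
  tol <- params@watershedTolFrac * max(blurred[mask])
  ## regional maxima closer than ~2 blur sigmas (about half a cell radius)
  ## are treated as one seed: foci-scale texture would otherwise double-seed
  ext <- max(1L, ceiling(2 * params@blurSigmaPx))
  ws <- EBImage::watershed(EBImage::Image(blurred * mask),
                           tolerance = tol, ext = ext)
  ws <- matrix(as.integer(ws), nr, nc)

  ## impose 1-px separating lines where forward neighbors carry a
  ## different nonzero watershed label (E, S, SE, SW), then relabel
  line <- matrix(FALSE, nr, nc)
  differs <- function(a, b) a > 0L & b > 0L & a != b
  line[, 1:(nc - 1)] <- line[, 1:(nc - 1)] |
    differs(ws[, 1:(nc - 1)], ws[, 2:nc])                      # E
  line[1:(nr - 1), ] <- line[1:(nr - 1), ] |
    differs(ws[1:(nr - 1), ], ws[2:nr, ])                      # S
  line[1:(nr - 1), 1:(nc - 1)] <- line[1:(nr - 1), 1:(nc - 1)] |
    differs(ws[1:(nr - 1), 1:(nc - 1)], ws[2:nr, 2:nc])        # SE
  line[1:(nr - 1), 2:nc] <- line[1:(nr - 1), 2:nc] |
    differs(ws[1:(nr - 1), 2:nc], ws[2:nr, 1:(nc - 1)])        # SW
  sepMask <- mask & ws > 0L & !line

  lab <- matrix(as.integer(EBImage::bwlabel(sepMask)), nr, nc)
  n0 <- max(lab)
  if (n0 == 0L) return(emptyMap())

  ## area gate
  areas <- tabulate(lab[lab > 0L], nbins = n0)
  keep <- which(areas >= params@minCellAreaPx & areas <= params@maxCellAreaPx)

  ## border exclusion
  if (params@excludeBorderCells && length(keep)) {
    borderLabs <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    keep <- setdiff(keep, borderLabs[borderLabs > 0L])
  }
  if (!length(keep)) return(emptyMap())

  ## renumber 1..n in raster order of component centroids
  cent <- labelCentroids(lab, n0)[keep, , drop = FALSE]
  ord <- order(cent[, "row"], cent[, "col"])
  keep <- keep[ord]
  remap <- integer(n0)
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nr, nc)
  pos <- lab > 0L
  out[pos] <- remap[lab[pos]]

  new("CellLabelMap", labels = out, nCells = length(keep),
      provenance = list(params = params, thresholdUsed = thr,
                        watershedTolerance = tol, watershedExt = ext,
                        connectivity = 4L, lineConnectivity = 4L,
                        inputAssumedBackgroundSubtracted = TRUE))
}

#' Count mask pixels per segmented cell
#'
#' For each cell label, counts the pixels of a boolean mask that fall inside
#' that cell's pixel set. Counts sum to the size of the intersection of the
#' mask with the labeled area.
#'
#' @param labelMap a [CellLabelMap-class].
#' @param mask logical matrix of the same dimensions.
#' @return integer vector of length `nCells(labelMap)`, named by cell label.
#' @export
assignPixelsToCells <- function(labelMap, mask) {
  stopifnot(is(labelMap, "CellLabelMap"))
  if (!identical(dim(labelMap@labels), dim(mask)))
    stop("label map and mask dimensions differ")
  mask <- mask != 0
  n <- labelMap@nCells
  lab <- labelMap@labels[mask]
  counts <- tabulate(lab[lab > 0L], nbins = n)
  names(counts) <- if (n > 0L) as.character(seq_len(n)) else character(0)
  counts
}
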
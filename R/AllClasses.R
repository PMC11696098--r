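#' @import methods
NULL

setClassUnion("numericOrCharacter", c("numeric", "character"))

#' MultiChannelImage: one multi-channel field of view
#'
#' Container for the named 2D intensity planes of a single field of view,
#' together with acquisition metadata. All planes must share the same
#' dimensions and hold finite, non-negative intensities.
#'
#' @slot channels named list of numeric matrices, one per channel.
#' @slot wellId,fieldId character identifiers of the well and field.
#' @slot pixelSizeUm physical pixel size in micrometres (`NA` if unknown).
#' @slot bitDepth acquisition bit depth (`NA` if unknown).
#'
#' @seealso [multiChannelImage()], [getChannel()], [readField()]
#' @exportClass MultiChannelImage
setClass("MultiChannelImage",
  representation(
    channels = "list",
    wellId = "character",
    fieldId = "character",
    pixelSizeUm = "numeric",
    bitDepth = "numeric"
  ),
  prototype(
    channels = list(), wellId = NA_character_, fieldId = NA_character_,
    pixelSizeUm = NA_real_, bitDepth = NA_real_
  )
)

setValidity("MultiChannelImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("'channels' must contain at least one plane")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("'channels' must be a uniquely named list")
  if (!all(vapply(ch, function(p) is.matrix(p) && is.numeric(p), logical(1))))
    return("all channels must be numeric matrices")
  dims <- vapply(ch, dim, integer(2))
  if (!all(dims == dims[, 1]))
    return("all channel planes must share identical dimensions")
  for (nm in names(ch)) {
    p <- ch[[nm]]
    if (!all(is.finite(p))) return(sprintf("channel '%s' has non-finite pixels", nm))
    if (any(p < 0)) return(sprintf("channel '%s' has negative pixels", nm))
  }
  TRUE
})

#' CellLabelMap: integer-labeled single-cell segmentation
#'
#' Integer label image for one field: 0 marks background, values `1..nCells`
#' mark individual cells. The parameters that produced the map are kept in
#' `provenance` (including the connected-component connectivity used).
#'
#' @slot labels integer matrix of cell labels.
#' @slot nCells number of labeled cells.
#' @slot provenance list of segmentation parameters and derived settings.
#'
#' @seealso [segmentCells()], [labelMatrix()], [nCells()]
#' @exportClass CellLabelMap
setClass("CellLabelMap",
  representation(labels = "matrix", nCells = "integer", provenance = "list"),
  prototype(labels = matrix(0L, 0, 0), nCells = 0L, provenance = list())
)

setValidity("CellLabelMap", function(object) {
  lab <- object@labels
  if (!is.integer(lab)) return("'labels' must be an integer matrix")
  u <- sort(unique(as.vector(lab)))
  expected <- if (object@nCells > 0L) c(0L, seq_len(object@nCells)) else 0L
  # an all-cell image with no background pixel is legal
  if (!all(u %in% expected))
    return("label values must be exactly {0} U {1..nCells}")
  if (object@nCells > 0L && !all(seq_len(object@nCells) %in% u))
    return("every label 1..nCells must occur in the label matrix")
  TRUE
})

#' SceneParams: generating parameters of a synthetic field
#'
#' Complete parameter set of the synthetic microscopy scene generator. The
#' defaults describe a 256x256 px field of ~15 well-separated adherent cells
#' (soft-edged disks of radius 18 +/- 2 px) of which half carry, on average,
#' four bright perinuclear foci in the LC3B channel; marker signal co-occurs
#' with a focus with probability `pMarkerColoc`. Camera noise is Poisson shot
#' noise followed by additive Gaussian read noise.
#'
#' @slot imageHeightPx,imageWidthPx image dimensions in pixels (>= 64).
#' @slot nCells number of cells requested (placement may fall short; the
#'   shortfall is recorded in the [GroundTruth]).
#' @slot cellRadiusMeanPx,cellRadiusSdPx normal distribution of cell radii.
#' @slot fractionFociPositiveCells probability a cell is foci-positive.
#' @slot fociPerPositiveCellMean Poisson rate of foci per positive cell,
#'   conditioned on at least one focus.
#' @slot focusRadiusPx nominal focus radius; foci are rendered as Gaussian
#'   spots with sigma = focusRadiusPx / 2.
#' @slot focusAmplitude,cytosolAmplitude,backgroundLevel intensities (ADU).
#' @slot backgroundGradient fractional linear ramp of the background across
#'   the field (0 = flat background).
#' @slot psfSigmaPx Gaussian point-spread sigma applied to the render.
#' @slot pMarkerColoc probability a focus also carries marker signal.
#' @slot markerFocusAmplitude,markerDiffuseAmplitude marker intensities.
#' @slot nucleusAmplitude,nucleusRadiusFrac nuclear channel Gaussian blob
#'   amplitude and radius as a fraction of the cell radius.
#' @slot fociAnnulus two fractions of the cell radius bounding the
#'   perinuclear annulus in which foci are placed.
#' @slot edgeSoftnessPx softness of the cell-edge sigmoid in pixels.
#' @slot readNoiseSd additive Gaussian read noise sd (ADU).
#' @slot shotNoise apply Poisson shot noise before read noise?
#' @slot quantize round intensities to integer ADU clipped to 16-bit range?
#' @slot seed integer seed; identical parameters give bit-identical scenes.
#'
#' @seealso [sceneParams()], [simulateScene()]
#' @exportClass SceneParams
setClass("SceneParams",
  representation(
    imageHeightPx = "integer", imageWidthPx = "integer", nCells = "integer",
    cellRadiusMeanPx = "numeric", cellRadiusSdPx = "numeric",
    fractionFociPositiveCells = "numeric", fociPerPositiveCellMean = "numeric",
    focusRadiusPx = "numeric", focusAmplitude = "numeric",
    cytosolAmplitude = "numeric", backgroundLevel = "numeric",
    backgroundGradient = "numeric", psfSigmaPx = "numeric",
    pMarkerColoc = "numeric", markerFocusAmplitude = "numeric",
    markerDiffuseAmplitude = "numeric", nucleusAmplitude = "numeric",
    nucleusRadiusFrac = "numeric", fociAnnulus = "numeric",
    edgeSoftnessPx = "numeric", readNoiseSd = "numeric",
    shotNoise = "logical", quantize = "logical", seed = "integer"
  )
)

setValidity("SceneParams", function(object) {
  chk <- function(cond, msg) if (!cond) msg else NULL
  msgs <- c(
    chk(object@imageHeightPx >= 64L, "imageHeightPx: must be >= 64"),
    chk(object@imageWidthPx >= 64L, "imageWidthPx: must be >= 64"),
    chk(object@nCells >= 0L, "nCells: must be non-negative"),
    chk(object@cellRadiusMeanPx > 0, "cellRadiusMeanPx: must be positive"),
    chk(object@cellRadiusSdPx >= 0, "cellRadiusSdPx: must be non-negative"),
    chk(object@fractionFociPositiveCells >= 0 &&
        object@fractionFociPositiveCells <= 1,
        "fractionFociPositiveCells: must lie in [0, 1]"),
    chk(object@fociPerPositiveCellMean > 0,
        "fociPerPositiveCellMean: must be positive"),
    chk(object@focusRadiusPx > 0, "focusRadiusPx: must be positive"),
    chk(object@focusAmplitude >= 0, "focusAmplitude: must be non-negative"),
    chk(object@cytosolAmplitude >= 0, "cytosolAmplitude: must be non-negative"),
    chk(object@backgroundLevel >= 0, "backgroundLevel: must be non-negative"),
    chk(object@psfSigmaPx > 0, "psfSigmaPx: must be positive"),
    chk(object@pMarkerColoc >= 0 && object@pMarkerColoc <= 1,
        "pMarkerColoc: must lie in [0, 1]"),
    chk(object@markerFocusAmplitude >= 0,
        "markerFocusAmplitude: must be non-negative"),
    chk(object@markerDiffuseAmplitude >= 0,
        "markerDiffuseAmplitude: must be non-negative"),
    chk(object@readNoiseSd >= 0, "readNoiseSd: must be non-negative"),
    chk(length(object@fociAnnulus) == 2L && all(object@fociAnnulus >= 0) &&
        all(object@fociAnnulus <= 1) && diff(object@fociAnnulus) > 0,
        "fociAnnulus: must be two increasing fractions in [0, 1]"),
    chk(object@edgeSoftnessPx > 0, "edgeSoftnessPx: must be positive"),
    chk(length(object@seed) == 1L && !is.na(object@seed),
        "seed: must be a single integer")
  )
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' GroundTruth: generating truth of a synthetic field
#'
#' Per-cell and per-focus truth labels of a simulated field, plus the
#' [SceneParams] that generated it. `cellRecords` has one row per placed cell
#' (`cell_id`, `center_row`, `center_col`, `radius_px`, `is_foci_positive`,
#' `n_foci`); `focusRecords` one row per focus (`focus_id`, `cell_id`,
#' `center_row`, `center_col`, `radius_px`, `is_marker_positive`). The
#' realized foci-positive fraction is a binomial draw and is read from the
#' records, never assumed equal to the requested fraction.
#'
#' @slot cellRecords,focusRecords data frames as described above.
#' @slot params the [SceneParams] used.
#' @slot nRequested,nPlaced requested and actually placed cell counts
#'   (placement is by rejection sampling; a shortfall is legal and recorded).
#'
#' @seealso [simulateScene()], [cellRecords()], [focusRecords()]
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    cellRecords = "data.frame", focusRecords = "data.frame",
    params = "SceneParams", nRequested = "integer", nPlaced = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  cr <- object@cellRecords; fr <- object@focusRecords
  need_c <- c("cell_id", "center_row", "center_col", "radius_px",
              "is_foci_positive", "n_foci")
  need_f <- c("focus_id", "cell_id", "center_row", "center_col",
              "radius_px", "is_marker_positive")
  if (!all(need_c %in% names(cr))) return("cellRecords: missing columns")
  if (!all(need_f %in% names(fr))) return("focusRecords: missing columns")
  if (nrow(fr) > 0L && !all(fr$cell_id %in% cr$cell_id))
    return("every focus record must reference an existing cell record")
  if (object@nPlaced != nrow(cr))
    return("nPlaced must equal the number of cell records")
  TRUE
})

#' SegmentationParams: parameters of cell segmentation
#'
#' @slot bgSigmaPx Gaussian sigma of the background estimate used by
#'   [subtractBackground()]; should be large relative to the cell radius.
#' @slot blurSigmaPx cell-scale Gaussian blur applied before thresholding and
#'   watershed (a half-cell-radius is a good heuristic).
#' @slot intensityThreshold `"otsu"` or an explicit non-negative threshold
#'   applied to the blurred plane.
#' @slot minCellAreaPx,maxCellAreaPx area bounds (px) for surviving cells.
#' @slot excludeBorderCells drop components touching the image border?
#' @slot watershedTolFrac watershed merge tolerance as a fraction of the
#'   maximum blurred foreground intensity; peaks shallower than this relative
#'   depth are merged with their neighbor (suppresses over-segmentation from
#'   intra-cell texture).
#'
#' @seealso [segmentationParams()], [segmentCells()]
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(
    bgSigmaPx = "numeric", blurSigmaPx = "numeric",
    intensityThreshold = "numericOrCharacter",
    minCellAreaPx = "integer", maxCellAreaPx = "integer",
    excludeBorderCells = "logical", watershedTolFrac = "numeric"
  )
)

setValidity("SegmentationParams", function(object) {
  if (object@bgSigmaPx <= 0) return("bgSigmaPx: must be positive")
  if (object@blurSigmaPx <= 0) return("blurSigmaPx: must be positive")
  thr <- object@intensityThreshold
  if (is.character(thr)) {
    if (!identical(thr, "otsu"))
      return("intensityThreshold: must be \"otsu\" or a non-negative number")
  } else if (length(thr) != 1L || is.na(thr) || thr < 0) {
    return("intensityThreshold: must be \"otsu\" or a non-negative number")
  }
  if (object@minCellAreaPx <= 0L) return("minCellAreaPx: must be positive")
  if (object@minCellAreaPx >= object@maxCellAreaPx)
    return("minCellAreaPx must be smaller than maxCellAreaPx")
  if (object@watershedTolFrac < 0 || object@watershedTolFrac >= 1)
    return("watershedTolFrac: must lie in [0, 1)")
  TRUE
})

#' FociParams: parameters of foci detection and cell positivity
#'
#' @slot eqSigmaPx sigma of the cell-sized equalization blur used by
#'   [equalizeLocal()].
#' @slot rawThreshold `"otsu"`, `"otsu-foreground"` (two-stage Otsu over
#'   the pixels above the plain Otsu split) or an explicit non-negative
#'   threshold on the raw (background-subtracted) plane.
#' @slot eqThreshold cutoff (> 1) on the equalized ratio plane.
#' @slot minFocusAreaPx,maxFocusAreaPx area bounds (px) for foci.
#' @slot circularityMin `"off"` or a minimum circularity in \[0, 1\]
#'   (circularity = 4 * pi * area / perimeter^2).
#' @slot minFociPixelsPerCell a cell is called foci-positive when its count
#'   of foci-mask pixels is strictly greater than this cutoff.
#'
#' @seealso [fociParams()], [detectFoci()], [callCellsFociPositive()]
#' @exportClass FociParams
setClass("FociParams",
  representation(
    eqSigmaPx = "numeric", rawThreshold = "numericOrCharacter",
    eqThreshold = "numeric", minFocusAreaPx = "integer",
    maxFocusAreaPx = "integer", circularityMin = "numericOrCharacter",
    minFociPixelsPerCell = "integer"
  )
)

setValidity("FociParams", function(object) {
  if (object@eqSigmaPx <= 0) return("eqSigmaPx: must be positive")
  thr <- object@rawThreshold
  if (is.character(thr)) {
    if (!thr %in% c("otsu", "otsu-foreground"))
      return("rawThreshold: must be \"otsu\", \"otsu-foreground\" or a non-negative number")
  } else if (length(thr) != 1L || is.na(thr) || thr < 0) {
    return("rawThreshold: must be \"otsu\", \"otsu-foreground\" or a non-negative number")
  }
  if (object@eqThreshold <= 1)
    return("eqThreshold: must be greater than 1")
  if (object@minFocusAreaPx <= 0L) return("minFocusAreaPx: must be positive")
  if (object@minFocusAreaPx > object@maxFocusAreaPx)
    return("minFocusAreaPx must not exceed maxFocusAreaPx")
  cm <- object@circularityMin
  if (is.character(cm)) {
    if (!identical(cm, "off"))
      return("circularityMin: must be \"off\" or a number in [0, 1]")
  } else if (length(cm) != 1L || is.na(cm) || cm < 0 || cm > 1) {
    return("circularityMin: must be \"off\" or a number in [0, 1]")
  }
  if (object@minFociPixelsPerCell <= 0L)
    return("minFociPixelsPerCell: must be positive")
  TRUE
})

#' FociTable: per-focus records of one field
#'
#' Detected punctae/foci of one field. `info` has one row per focus kept in
#' the table (`focus_id`, `cell_id`, `area_px`, `perimeter_px`,
#' `circularity`, `centroid_row`, `centroid_col`, plus one
#' `mean_<channel>` column per measured channel). `mask` is the boolean foci
#' mask after size/circularity filtering and includes border-touching foci
#' (those drive per-cell pixel tallies but carry no table row, since their
#' dilation rings would be truncated); `labels` labels exactly the table's
#' foci.
#'
#' @slot info per-focus data frame (see above).
#' @slot mask logical matrix, the filtered foci mask.
#' @slot labels integer matrix labeling the table rows' pixels.
#' @slot params the [FociParams] used.
#' @slot provenance list: thresholds actually applied, counts of components
#'   removed by each filter, border-focus count.
#'
#' @seealso [detectFoci()], [fociInfo()], [fociMask()], [donutRatio()]
#' @exportClass FociTable
setClass("FociTable",
  representation(
    info = "data.frame", mask = "matrix", labels = "matrix",
    params = "FociParams", provenance = "list"
  )
)

setValidity("FociTable", function(object) {
  info <- object@info
  need <- c("focus_id", "cell_id", "area_px", "perimeter_px", "circularity",
            "centroid_row", "centroid_col")
  if (!all(need %in% names(info))) return("info: missing columns")
  if (!identical(dim(object@mask), dim(object@labels)))
    return("mask and labels must share dimensions")
  if (nrow(info) > 0L) {
    if (any(info$circularity <= 0)) return("circularity must be positive")
    if (!all(sort(info$focus_id) == seq_len(nrow(info))))
      return("focus_id must be 1..nrow(info)")
    lab <- object@labels
    if (!all(sort(unique(as.vector(lab[lab > 0L]))) == seq_len(nrow(info))))
      return("labels must label exactly the table's foci")
    if (any(!object@mask[object@labels > 0L]))
      return("labeled focus pixels must lie inside the foci mask")
  }
  TRUE
})
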
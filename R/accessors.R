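#' Construct a MultiChannelImage
#'
#' @param channels named list of numeric matrices (equal dimensions, finite,
#'   non-negative).
#' @param wellId,fieldId identifiers.
#' @param pixelSizeUm optional physical pixel size in micrometres.
#' @param bitDepth optional acquisition bit depth.
#' @return a validated [MultiChannelImage-class].
#' @examples
#' img <- multiChannelImage(list(lc3b = matrix(1, 64, 64)))
#' channelNames(img)
#' @export
multiChannelImage <- function(channels, wellId = NA_character_,
                              fieldId = NA_character_,
                              pixelSizeUm = NA_real_, bitDepth = NA_real_) {
  channels <- lapply(channels, function(p) {
    storage.mode(p) <- "double"
    p
  })
  new("MultiChannelImage", channels = channels,
      wellId = as.character(wellId), fieldId = as.character(fieldId),
      pixelSizeUm = as.numeric(pixelSizeUm), bitDepth = as.numeric(bitDepth))
}

#' @rdname MultiChannelImage-class
#' @export
setMethod("channelNames", "MultiChannelImage", function(x) names(x@channels))

#' @rdname MultiChannelImage-class
#' @export
setMethod("getChannel", "MultiChannelImage", function(x, name) {
  if (!name %in% names(x@channels))
    stop(sprintf("no channel named '%s' (available: %s)", name,
                 paste(names(x@channels), collapse = ", ")))
  x@channels[[name]]
})

#' @rdname MultiChannelImage-class
#' @export
setMethod("wellId", "MultiChannelImage", function(x) x@wellId)

#' @rdname MultiChannelImage-class
#' @export
setMethod("fieldId", "MultiChannelImage", function(x) x@fieldId)

#' @rdname MultiChannelImage-class
#' @export
setMethod("dim", "MultiChannelImage", function(x) dim(x@channels[[1]]))

setMethod("show", "MultiChannelImage", function(object) {
  d <- dim(object)
  cat(sprintf("MultiChannelImage %d x %d px, %d channel(s): %s\n",
              d[1], d[2], length(object@channels),
              paste(names(object@channels), collapse = ", ")))
  cat(sprintf("  well: %s  field: %s\n", object@wellId, object@fieldId))
})

#' @rdname CellLabelMap-class
#' @export
setMethod("labelMatrix", "CellLabelMap", function(x) x@labels)

#' @rdname CellLabelMap-class
#' @export
setMethod("nCells", "CellLabelMap", function(x) x@nCells)

#' @rdname CellLabelMap-class
#' @export
setMethod("provenance", "CellLabelMap", function(x) x@provenance)

setMethod("show", "CellLabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("CellLabelMap %d x %d px, %d cell(s)\n",
              d[1], d[2], object@nCells))
})

#' @rdname GroundTruth-class
#' @export
setMethod("cellRecords", "GroundTruth", function(x) x@cellRecords)

#' @rdname GroundTruth-class
#' @export
setMethod("focusRecords", "GroundTruth", function(x) x@focusRecords)

#' @rdname GroundTruth-class
#' @export
setMethod("simParams", "GroundTruth", function(x) x@params)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d/%d cell(s) placed, %d foci-positive, %d focus record(s)\n",
    object@nPlaced, object@nRequested,
    sum(object@cellRecords$is_foci_positive), nrow(object@focusRecords)))
})

#' @rdname FociTable-class
#' @export
setMethod("fociInfo", "FociTable", function(x) x@info)

#' @rdname FociTable-class
#' @export
setMethod("fociMask", "FociTable", function(x) x@mask)

#' @rdname FociTable-class
#' @export
setMethod("fociLabels", "FociTable", function(x) x@labels)

#' @rdname FociTable-class
#' @param row.names,optional,... passed on conventionally; ignored.
#' @export
setMethod("as.data.frame", "FociTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@info)

setMethod("show", "FociTable", function(object) {
  cat(sprintf("FociTable: %d focus rows, %d foci-mask pixel(s)\n",
              nrow(object@info), sum(object@mask)))
  if (length(object@provenance$nBorderFoci) &&
      object@provenance$nBorderFoci > 0)
    cat(sprintf("  (%d border-touching foci in mask only)\n",
                object@provenance$nBorderFoci))
})

setMethod("show", "SceneParams", function(object) {
  cat(sprintf(
    "SceneParams: %d x %d px, %d cells (r = %.1f +/- %.1f px), %.0f%% foci-positive\n",
    object@imageHeightPx, object@imageWidthPx, object@nCells,
    object@cellRadiusMeanPx, object@cellRadiusSdPx,
    100 * object@fractionFociPositiveCells))
  cat(sprintf("  foci/positive cell ~ %.1f (truncated Poisson), p(marker) = %.2f, seed = %d\n",
              object@fociPerPositiveCellMean, object@pMarkerColoc, object@seed))
})
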
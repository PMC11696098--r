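#' @rdname MultiChannelImage-class
#' @param x object to access.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname MultiChannelImage-class
#' @param name channel name.
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname MultiChannelImage-class
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))

#' @rdname MultiChannelImage-class
#' @export
setGeneric("fieldId", function(x) standardGeneric("fieldId"))

#' @rdname CellLabelMap-class
#' @param x object to access.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname CellLabelMap-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname CellLabelMap-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname GroundTruth-class
#' @param x object to access.
#' @export
setGeneric("cellRecords", function(x) standardGeneric("cellRecords"))

#' @rdname GroundTruth-class
#' @export
setGeneric("focusRecords", function(x) standardGeneric("focusRecords"))

#' @rdname GroundTruth-class
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))

#' @rdname FociTable-class
#' @param x object to access.
#' @export
setGeneric("fociInfo", function(x) standardGeneric("fociInfo"))

#' @rdname FociTable-class
#' @export
setGeneric("fociMask", function(x) standardGeneric("fociMask"))

#' @rdname FociTable-class
#' @export
setGeneric("fociLabels", function(x) standardGeneric("fociLabels"))
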
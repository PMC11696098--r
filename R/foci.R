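#' Parameters for foci detection
#'
#' Builds a validated [FociParams-class]. Defaults: equalization over
#' cell-sized regions (`eqSigmaPx = 15`), a foreground-restricted Otsu
#' threshold on the raw plane, equalized-ratio cutoff 1.5, focus area
#' between 5 and 400 px, circularity filter off, and a cell called
#' foci-positive when strictly more than 10 foci pixels fall inside it.
#'
#' @param eqSigmaPx equalization blur sigma (cell-sized, px).
#' @param rawThreshold `"otsu-foreground"` (Otsu's threshold computed over
#'   the pixels above the plain Otsu split, so that the cut falls between
#'   cytosol and punctae rather than between background and cells),
#'   `"otsu"` (plain), or an explicit non-negative threshold on the raw
#'   plane.
#' @param eqThreshold cutoff (> 1) on the equalized ratio plane.
#' @param minFocusAreaPx,maxFocusAreaPx focus area gate (px).
#' @param circularityMin `"off"` or a minimum circularity in \[0, 1\].
#' @param minFociPixelsPerCell strict per-cell positivity cutoff (pixels).
#' @return a [FociParams-class] object.
#' @export
fociParams <- function(eqSigmaPx = 15, rawThreshold = "otsu-foreground",
                       eqThreshold = 1.5, minFocusAreaPx = 5L,
                       maxFocusAreaPx = 400L, circularityMin = "off",
                       minFociPixelsPerCell = 10L) {
  new("FociParams",
      eqSigmaPx = as.numeric(eqSigmaPx), rawThreshold = rawThreshold,
      eqThreshold = as.numeric(eqThreshold),
      minFocusAreaPx = as.integer(minFocusAreaPx),
      maxFocusAreaPx = as.integer(maxFocusAreaPx),
      circularityMin = circularityMin,
      minFociPixelsPerCell = as.integer(minFociPixelsPerCell))
}

#' Plate-level raw threshold for foci detection
#'
#' Computes one raw-intensity threshold from the pooled pixels of many
#' (background-subtracted) planes, for use as an explicit `rawThreshold` in
#' [detectFoci()] across all fields of a plate or condition. Thresholding
#' per plate rather than per field keeps wells comparable and is robust on
#' fields that themselves contain few or no foci, where a per-field
#' adaptive threshold has no punctate intensity class to find and collapses
#' into the cytosolic population.
#'
#' @param planes list of 2D numeric planes (background-subtracted).
#' @param method `"otsu-foreground"` (default) or `"otsu"`.
#' @param maxPixels pooled pixels are subsampled (deterministically, by
#'   regular striding) beyond this count.
#' @return a single threshold value.
#' @seealso [detectFoci()], [runPipeline()]
#' @export
plateRawThreshold <- function(planes, method = c("otsu-foreground", "otsu"),
                              maxPixels = 4e6) {
  method <- match.arg(method)
  v <- unlist(lapply(planes, as.numeric), use.names = FALSE)
  if (length(v) > maxPixels)
    v <- v[seq(1L, length(v), by = ceiling(length(v) / maxPixels))]
  m <- matrix(v, ncol = 1L)
  if (method == "otsu") otsuThreshold(m) else otsuThresholdForeground(m)
}

#' Local intensity equalization by Gaussian division
#'
#' Equalizes cell-sized intensity variation by dividing the plane by a
#' Gaussian blur of itself: `(plane + delta) / (G_eq(plane) + delta)`, with
#' the fixed regularizer `delta = 1e-6 * mean of the positive pixels` (1 if
#' there are none). The output is strictly positive, ~1 wherever the plane
#' is locally flat, > 1 on structures brighter than their surroundings, and
#' invariant under multiplication of the input by a positive scalar (up to
#' regularizer effects). An all-zero plane returns an all-ones plane by
#' convention.
#'
#' @param plane 2D numeric matrix, finite and non-negative.
#' @param eqSigmaPx positive blur sigma (choose roughly cell-sized).
#' @return ratio plane of the same shape.
#' @export
equalizeLocal <- function(plane, eqSigmaPx) {
  stopIfNotFinitePlane(plane)
  if (any(plane < 0)) stop("plane must be non-negative")
  if (!is.numeric(eqSigmaPx) || length(eqSigmaPx) != 1L ||
      is.na(eqSigmaPx) || eqSigmaPx <= 0)
    stop("eqSigmaPx must be a single positive number")
  pos <- plane[plane > 0]
  delta <- 1e-6 * (if (length(pos)) mean(pos) else 1)
  (plane + delta) / (gaussBlur(plane, eqSigmaPx) + delta)
}

#' Detect punctae/foci by dual-intensity selection
#'
#' Detects bright punctate structures as pixels with high intensity in
#' *both* the raw plane and the locally equalized plane: the foci mask is
#' `(plane >= rawThreshold) & (equalizeLocal(plane) >= eqThreshold)`.
#' Connected components of the mask (4-connected) are filtered by area and,
#' when `circularityMin` is numeric, by circularity
#' `4 * pi * area / perimeter^2` (perimeter by the Crofton estimator, see
#' [maskPerimeter()]). Components touching the image border are kept in the
#' returned mask (they count toward per-cell foci-pixel tallies) but are
#' excluded from the per-focus table, since their dilation rings would be
#' truncated. Each table focus is assigned to the cell containing its
#' centroid (`NA` when the centroid falls on background or no label map is
#' given). Rows are sorted by `(cell_id, centroid)` and renumbered.
#'
#' @param plane 2D numeric matrix; expected background-subtracted.
#' @param params a [FociParams-class] (see [fociParams()]).
#' @param labelMap optional [CellLabelMap-class] for cell assignment.
#' @param channels optional named list of planes on which to record
#'   per-focus mean intensities; defaults to `list(intensity = plane)`.
#' @return a [FociTable-class]; zero detected foci gives a valid empty table.
#' @export
detectFoci <- function(plane, params = fociParams(), labelMap = NULL,
                       channels = NULL) {
  stopIfNotFinitePlane(plane)
  validObject(params)
  if (is.null(channels)) channels <- list(intensity = plane)
  for (ch in channels)
    if (!identical(dim(ch), dim(plane)))
      stop("all measurement channels must match the plane dimensions")
  if (!is.null(labelMap)) {
    stopifnot(is(labelMap, "CellLabelMap"))
    if (!identical(dim(labelMap@labels), dim(plane)))
      stop("label map dimensions differ from the plane")
  }
  nr <- nrow(plane); nc <- ncol(plane)

  rawThr <- if (identical(params@rawThreshold, "otsu")) otsuThreshold(plane)
    else if (identical(params@rawThreshold, "otsu-foreground"))
      otsuThresholdForeground(plane)
    else params@rawThreshold
  eq <- equalizeLocal(plane, params@eqSigmaPx)
  mask <- (plane >= rawThr) & (eq >= params@eqThreshold)

  prov <- list(params = params, rawThresholdUsed = rawThr,
               connectivity = 4L, nRemovedArea = 0L,
               nRemovedCircularity = 0L, nBorderFoci = 0L)
  emptyInfo <- data.frame(
    focus_id = integer(0), cell_id = integer(0), area_px = integer(0),
    perimeter_px = numeric(0), circularity = numeric(0),
    centroid_row = numeric(0), centroid_col = numeric(0))
  for (nm in names(channels))
    emptyInfo[[paste0("mean_", nm)]] <- numeric(0)

  mkTable <- function(info, keptMask, labels, prov)
    new("FociTable", info = info, mask = keptMask, labels = labels,
        params = params, provenance = prov)

  if (!any(mask))
    return(mkTable(emptyInfo, matrix(FALSE, nr, nc), matrix(0L, nr, nc), prov))

  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nr, nc)
  n0 <- max(lab)
  pix <- splitByLabel(lab, n0)
  areas <- lengths(pix)

  keep <- areas >= params@minFocusAreaPx & areas <= params@maxFocusAreaPx
  prov$nRemovedArea <- sum(!keep)

  perims <- rep(NA_real_, n0)
  circs <- rep(NA_real_, n0)
  for (k in which(keep)) {
    cm <- cropMask(lab, pix[[k]])
    perims[k] <- maskPerimeterMat(cm$mask)
    circs[k] <- 4 * pi * areas[k] / perims[k]^2
  }
  if (is.numeric(params@circularityMin)) {
    drop <- keep & circs < params@circularityMin
    prov$nRemovedCircularity <- sum(drop, na.rm = TRUE)
    keep <- keep & !drop
  }
  if (!any(keep))
    return(mkTable(emptyInfo, matrix(FALSE, nr, nc), matrix(0L, nr, nc), prov))

  ## mask of all surviving components (border foci included)
  keptMask <- matrix(FALSE, nr, nc)
  for (k in which(keep)) keptMask[pix[[k]]] <- TRUE

  ## border-touching components: mask only, no table row
  borderLabs <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  borderLabs <- borderLabs[borderLabs > 0L]
  inTable <- keep
  inTable[borderLabs] <- FALSE
  prov$nBorderFoci <- sum(keep) - sum(inTable)

  ids <- which(inTable)
  if (!length(ids))
    return(mkTable(emptyInfo, keptMask, matrix(0L, nr, nc), prov))

  cent <- labelCentroids(lab, n0)[ids, , drop = FALSE]
  cellId <- rep(NA_integer_, length(ids))
  if (!is.null(labelMap)) {
    cr <- pmin(pmax(round(cent[, "row"]), 1L), nr)
    cc <- pmin(pmax(round(cent[, "col"]), 1L), nc)
    v <- labelMap@labels[cbind(cr, cc)]
    cellId <- ifelse(v > 0L, v, NA_integer_)
  }
  info <- data.frame(
    focus_id = seq_along(ids), cell_id = cellId,
    area_px = as.integer(areas[ids]), perimeter_px = perims[ids],
    circularity = circs[ids],
    centroid_row = cent[, "row"], centroid_col = cent[, "col"])
  for (nm in names(channels)) {
    chp <- channels[[nm]]
    info[[paste0("mean_", nm)]] <-
      vapply(ids, function(k) mean(chp[pix[[k]]]), numeric(1))
  }

  ## sort by (cell_id, raster centroid), renumber, relabel pixel sets
  ord <- order(is.na(info$cell_id), info$cell_id,
               info$centroid_row, info$centroid_col)
  info <- info[ord, , drop = FALSE]
  labels <- matrix(0L, nr, nc)
  for (j in seq_along(ord)) labels[pix[[ids[ord[j]]]]] <- j
  info$focus_id <- seq_along(ord)
  rownames(info) <- NULL

  mkTable(info, keptMask, labels, prov)
}

#' Call cells foci-positive by in-cell foci pixel counts
#'
#' A cell is called foci-positive when the number of foci-mask pixels inside
#' it is *strictly greater* than `minFociPixelsPerCell` (a count exactly
#' equal to the cutoff is negative). The summary fraction is
#' `positives / nCells`; with zero cells the fraction is undefined and
#' flagged (`NA`, `noCells = TRUE`), never reported as 0.
#'
#' @param labelMap a [CellLabelMap-class].
#' @param fociTable a [FociTable-class] (its full mask, including
#'   border-touching foci, drives the counts) or a logical foci mask.
#' @param minFociPixelsPerCell strict positivity cutoff; defaults to the
#'   value stored in the foci table's parameters.
#' @return list with `perCell` (data frame: `cell_id`, `foci_pixels`,
#'   `positive`), `nCells`, `fractionPositive` and `noCells`.
#' @export
callCellsFociPositive <- function(labelMap, fociTable,
                                  minFociPixelsPerCell = NULL) {
  stopifnot(is(labelMap, "CellLabelMap"))
  mask <- if (is(fociTable, "FociTable")) fociTable@mask else fociTable
  if (is.null(minFociPixelsPerCell)) {
    if (!is(fociTable, "FociTable"))
      stop("minFociPixelsPerCell must be given when passing a raw mask")
    minFociPixelsPerCell <- fociTable@params@minFociPixelsPerCell
  }
  counts <- assignPixelsToCells(labelMap, mask)
  n <- labelMap@nCells
  positive <- counts > minFociPixelsPerCell    # strict: "above a threshold"
  perCell <- data.frame(cell_id = seq_len(n),
                        foci_pixels = as.integer(counts),
                        positive = as.logical(positive))
  list(perCell = perCell, nCells = n,
       fractionPositive = if (n > 0L) sum(positive) / n else NA_real_,
       noCells = n == 0L)
}

#' Summarize puncta number and size distributions
#'
#' Per-group puncta counts and area distributions (median and interquartile
#' range), with an optional large-vs-small split at a caller-given area
#' cutoff (large "punctae" being the foci-scale structures).
#'
#' @param foci a [FociTable-class] or a data frame with an `area_px` column.
#' @param by optional character vector of grouping column names present in
#'   the data (e.g. `"well_id"`, `"condition"`); `NULL` treats all rows as
#'   one group.
#' @param largeAreaCutoff optional area cutoff (px) for the split.
#' @return data frame with one row per group: `n_punctae`, `median_area_px`,
#'   `q25_area_px`, `q75_area_px` and, when a cutoff is given, `n_large`
#'   and `n_small`. Empty groups yield `n_punctae = 0` with `NA` quantiles.
#' @export
punctaStats <- function(foci, by = NULL, largeAreaCutoff = NULL) {
  df <- if (is(foci, "FociTable")) foci@info else foci
  stopifnot(is.data.frame(df), "area_px" %in% names(df) || nrow(df) == 0L)
  if (is.null(by) && nrow(df) > 0L) {
    df$.group <- "all"
    by <- ".group"
  }
  if (nrow(df) == 0L) {
    out <- data.frame(n_punctae = 0L, median_area_px = NA_real_,
                      q25_area_px = NA_real_, q75_area_px = NA_real_)
    if (!is.null(largeAreaCutoff)) { out$n_large <- 0L; out$n_small <- 0L }
    return(out)
  }
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(lv) {
    sub <- df[key == lv, , drop = FALSE]
    a <- sub$area_px
    r <- cbind(unique(sub[by])[1, , drop = FALSE],
               data.frame(n_punctae = length(a),
                          median_area_px = stats::median(a),
                          q25_area_px = unname(stats::quantile(a, 0.25)),
                          q75_area_px = unname(stats::quantile(a, 0.75))))
    if (!is.null(largeAreaCutoff)) {
      r$n_large <- sum(a >= largeAreaCutoff)
      r$n_small <- sum(a < largeAreaCutoff)
    }
    r
  })
  out <- do.call(rbind, rows)
  out[[".group"]] <- NULL
  rownames(out) <- NULL
  out
}
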
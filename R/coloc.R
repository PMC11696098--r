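#' Per-cell Pearson correlation between two channels
#'
#' Computes, for every segmented cell, the Pearson correlation of the two
#' planes over that cell's pixels. Cells with fewer than two pixels or with
#' zero variance in either channel are flagged undefined (`NA`), never
#' coerced to 0, and should be excluded from downstream medians (they are,
#' by [aggregatePlate()]).
#'
#' @param planeA,planeB 2D numeric matrices of identical dimensions.
#' @param labelMap a [CellLabelMap-class] of the same dimensions.
#' @return data frame with one row per cell: `cell_id`, `pearson_r`,
#'   `n_pixels`, `defined`.
#' @examples
#' lm <- new("CellLabelMap", labels = matrix(rep(1:2, each = 50), 10),
#'           nCells = 2L)
#' a <- matrix(runif(100), 10)
#' pearsonPerCell(a, a, lm)$pearson_r  # 1 for both cells
#' @export
pearsonPerCell <- function(planeA, planeB, labelMap) {
  stopIfNotFinitePlane(planeA, "planeA")
  stopIfNotFinitePlane(planeB, "planeB")
  stopifnot(is(labelMap, "CellLabelMap"))
  if (!identical(dim(planeA), dim(planeB)) ||
      !identical(dim(planeA), dim(labelMap@labels)))
    stop("planeA, planeB and the label map must share dimensions")
  n <- labelMap@nCells
  pix <- splitByLabel(labelMap@labels, n)
  r <- rep(NA_real_, n)
  np <- lengths(pix)
  for (k in seq_len(n)) {
    a <- planeA[pix[[k]]]; b <- planeB[pix[[k]]]
    if (np[k] >= 2L && stats::sd(a) > 0 && stats::sd(b) > 0)
      r[k] <- stats::cor(a, b)
  }
  data.frame(cell_id = seq_len(n), pearson_r = r,
             n_pixels = as.integer(np), defined = !is.na(r))
}

# Integer offsets of a disk-shaped structuring element of radius r.
diskOffsets <- function(r) {
  d <- -r:r
  off <- expand.grid(dr = d, dc = d)
  off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
}

#' Donut-ratio marker positivity of individual foci
#'
#' For each focus in the table, dilates its pixel set with a disk of radius
#' `dilationRadiusPx` and subtracts the union of *all* foci pixels (and any
#' out-of-image pixels) to obtain a surrounding ring ("donut") free of
#' overlapping foci. The score is
#' `ratio = mean(marker over focus pixels) / mean(marker over ring pixels)`;
#' a focus is called marker-positive iff `ratio > positivityThreshold`
#' (strictly greater: a ratio exactly at the threshold is negative). A ring
#' that is empty or has zero mean marker intensity makes the ratio
#' undefined (`NA`, `positive = FALSE`); such foci are counted in the
#' result and should be excluded from positivity denominators.
#'
#' The ratio is invariant under multiplicative rescaling of the marker
#' plane but not under additive offsets: the marker plane must be
#' background-subtracted upstream.
#'
#' @param fociTable a [FociTable-class].
#' @param markerPlane 2D numeric matrix (background-subtracted).
#' @param dilationRadiusPx disk radius of the dilation (>= 1).
#' @param positivityThreshold strict ratio cutoff (default 1.75).
#' @param markerName marker channel name recorded in the output.
#' @return data frame with one row per table focus: `focus_id`, `cell_id`,
#'   `marker_channel`, `focus_mean`, `ring_mean`, `ring_n_pixels`, `ratio`,
#'   `positive`, `defined`.
#' @export
donutRatio <- function(fociTable, markerPlane, dilationRadiusPx = 2L,
                       positivityThreshold = 1.75, markerName = "marker") {
  stopifnot(is(fociTable, "FociTable"))
  stopIfNotFinitePlane(markerPlane, "markerPlane")
  if (!identical(dim(fociTable@mask), dim(markerPlane)))
    stop("marker plane dimensions differ from the foci mask")
  dilationRadiusPx <- as.integer(dilationRadiusPx)
  if (dilationRadiusPx < 1L) stop("dilationRadiusPx must be >= 1")

  info <- fociTable@info
  nf <- nrow(info)
  nr <- nrow(markerPlane); nc <- ncol(markerPlane)
  off <- diskOffsets(dilationRadiusPx)
  allFoci <- fociTable@mask
  pix <- splitByLabel(fociTable@labels, nf)

  focusMean <- ringMean <- ratio <- rep(NA_real_, nf)
  ringN <- integer(nf)
  for (k in seq_len(nf)) {
    p <- pix[[k]]
    rows <- (p - 1L) %% nr + 1L
    cols <- (p - 1L) %/% nr + 1L
    dr <- outer(rows, off$dr, "+")
    dc <- outer(cols, off$dc, "+")
    inside <- dr >= 1L & dr <= nr & dc >= 1L & dc <= nc
    cand <- unique((dc[inside] - 1L) * nr + dr[inside])
    ring <- cand[!allFoci[cand]]
    ringN[k] <- length(ring)
    focusMean[k] <- mean(markerPlane[p])
    if (length(ring)) ringMean[k] <- mean(markerPlane[ring])
    if (length(ring) && ringMean[k] > 0)
      ratio[k] <- focusMean[k] / ringMean[k]
  }
  defined <- !is.na(ratio)
  nUndef <- sum(!defined)
  if (nUndef > 0L)
    warning(sprintf("%d focus/foci with undefined donut ratio (empty or zero-intensity ring)",
                    nUndef))
  data.frame(focus_id = info$focus_id, cell_id = info$cell_id,
             marker_channel = markerName, focus_mean = focusMean,
             ring_mean = ringMean, ring_n_pixels = ringN, ratio = ratio,
             positive = defined & ratio > positivityThreshold,
             defined = defined)
}

#' Fraction of foci positive for one or several markers
#'
#' Computes, per group, the fraction of foci called marker-positive among
#' foci with a defined donut ratio. When `scores` is a named list of score
#' tables over the *same* foci (one per marker), the joint ("both"-type)
#' fraction of foci positive in all listed channels is computed; a focus is
#' only counted in the denominator when its ratio is defined in every
#' channel.
#'
#' @param scores a data frame from [donutRatio()], or a named list of such
#'   data frames over the same foci.
#' @param by optional character vector of grouping columns (must be present
#'   in the score tables); `NULL` treats all rows as one group.
#' @return data frame with one row per group: grouping columns, `n_foci`,
#'   `n_defined`, `n_positive`, `fraction`, `percent` and `empty` (TRUE for
#'   a group with no defined scores, whose fraction is `NA`, not 0).
#' @export
percentFociPositive <- function(scores, by = NULL) {
  if (is.data.frame(scores)) {
    df <- scores[c(by, "focus_id", "positive", "defined")]
  } else {
    stopifnot(is.list(scores), length(scores) >= 1L)
    key <- c(by, "focus_id")
    df <- scores[[1]][key]
    df$positive <- scores[[1]]$positive
    df$defined <- scores[[1]]$defined
    for (s in scores[-1]) {
      if (nrow(s) != nrow(df))
        stop("all score tables must cover the same foci")
      m <- merge(df, s[c(key, "positive", "defined")], by = key,
                 suffixes = c("", ".y"))
      m$positive <- m$positive & m$positive.y
      m$defined <- m$defined & m$defined.y
      df <- m[c(key, "positive", "defined")]
    }
  }
  grp <- if (is.null(by)) factor(rep("all", nrow(df))) else
    interaction(df[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(grp), function(lv) {
    sub <- df[grp == lv, , drop = FALSE]
    nDef <- sum(sub$defined)
    nPos <- sum(sub$positive & sub$defined)
    stat <- data.frame(
      n_foci = nrow(sub), n_defined = nDef, n_positive = nPos,
      fraction = if (nDef > 0L) nPos / nDef else NA_real_,
      percent = if (nDef > 0L) 100 * nPos / nDef else NA_real_,
      empty = nDef == 0L)
    if (is.null(by)) stat else
      cbind(unique(sub[by])[1, , drop = FALSE], stat)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-cell or per-focus values over a plate
#'
#' Implements the plate-level aggregation ladder: per image, the median of
#' the defined values; per well, the median (default) or mean of its
#' per-image medians; across wells (within a condition, when a condition
#' map is given), the mean and standard deviation (n - 1 denominator) of
#' the per-well values. Images with zero defined values are dropped from
#' their well with a warning; undefined values never enter any aggregate.
#'
#' @param values data frame with columns `well_id`, `field_id`, `value` and
#'   optionally `defined` (rows with `defined = FALSE` or `NA` values are
#'   excluded).
#' @param wellStatistic `"median"` (default) or `"mean"`: how per-image
#'   medians are combined within a well.
#' @param conditionMap optional data frame with columns `well_id`,
#'   `condition` grouping wells into conditions.
#' @return list of data frames: `perImage` (`well_id`, `field_id`,
#'   `n_values`, `image_median`), `perWell` (`well_id`, `n_images`,
#'   `well_value`), `acrossWells` (`condition`, `n_wells`, `mean`, `sd`).
#' @examples
#' v <- data.frame(well_id = "A01", field_id = "F01",
#'                 value = c(0.2, 0.5, 0.9))
#' aggregatePlate(v)$perImage$image_median  # 0.5
#' @export
aggregatePlate <- function(values, wellStatistic = c("median", "mean"),
                           conditionMap = NULL) {
  wellStatistic <- match.arg(wellStatistic)
  stopifnot(is.data.frame(values),
            all(c("well_id", "field_id", "value") %in% names(values)))
  if (!"defined" %in% names(values)) values$defined <- !is.na(values$value)
  allImages <- unique(paste(values$well_id, values$field_id))
  values <- values[values$defined & !is.na(values$value), , drop = FALSE]

  imgKey <- interaction(values$well_id, values$field_id, drop = TRUE,
                        lex.order = TRUE)
  perImage <- do.call(rbind, lapply(levels(imgKey), function(lv) {
    sub <- values[imgKey == lv, , drop = FALSE]
    data.frame(well_id = sub$well_id[1], field_id = sub$field_id[1],
               n_values = nrow(sub),
               image_median = stats::median(sub$value))
  }))
  if (is.null(perImage))
    perImage <- data.frame(well_id = character(0), field_id = character(0),
                           n_values = integer(0), image_median = numeric(0))

  dropped <- setdiff(allImages, paste(perImage$well_id, perImage$field_id))
  if (length(dropped))
    warning(sprintf("image(s) with zero defined values dropped: %s",
                    paste(dropped, collapse = ", ")))

  perWell <- do.call(rbind, lapply(unique(perImage$well_id), function(w) {
    sub <- perImage[perImage$well_id == w, , drop = FALSE]
    data.frame(well_id = w, n_images = nrow(sub),
               well_value = if (wellStatistic == "median")
                 stats::median(sub$image_median) else mean(sub$image_median))
  }))
  if (is.null(perWell))
    perWell <- data.frame(well_id = character(0), n_images = integer(0),
                          well_value = numeric(0))

  if (!is.null(conditionMap)) {
    stopifnot(all(c("well_id", "condition") %in% names(conditionMap)))
    perWell$condition <- conditionMap$condition[
      match(perWell$well_id, conditionMap$well_id)]
  } else {
    perWell$condition <- "all"
  }
  acrossWells <- do.call(rbind, lapply(unique(perWell$condition), function(cd) {
    sub <- perWell[perWell$condition == cd, , drop = FALSE]
    data.frame(condition = cd, n_wells = nrow(sub),
               mean = mean(sub$well_value),
               sd = if (nrow(sub) > 1L) stats::sd(sub$well_value) else NA_real_)
  }))
  if (is.null(acrossWells))
    acrossWells <- data.frame(condition = character(0), n_wells = integer(0),
                              mean = numeric(0), sd = numeric(0))
  list(perImage = perImage, perWell = perWell, acrossWells = acrossWells)
}
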
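#' Read one multi-channel field from a TIFF file
#'
#' Reads a (multi-page) TIFF and maps pages to named channels. Integer data
#' are widened to real-valued planes without rescaling (a 16-bit page reads
#' back as intensities 0..65535).
#'
#' Errors carry distinct condition classes: `fqUnreadableFile`,
#' `fqMissingChannel`, `fqShapeMismatch`.
#'
#' @param path TIFF file path.
#' @param channelMap named integer vector or list mapping channel names to
#'   page numbers, e.g. `c(nucleus = 1, lc3b = 2, marker = 3)`.
#' @param wellId,fieldId identifiers stamped on the result.
#' @return a [MultiChannelImage-class].
#' @seealso [writeField()]
#' @export
readField <- function(path, channelMap, wellId = NA_character_,
                      fieldId = NA_character_) {
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) stop(errorCondition(
      sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)),
      class = c("fqUnreadableFile", "error", "condition"))))
  if (is.matrix(pages)) pages <- list(pages)
  channelMap <- unlist(channelMap)
  bad <- channelMap[channelMap < 1 | channelMap > length(pages)]
  if (length(bad))
    stop(errorCondition(
      sprintf("channel(s) %s map to pages outside 1..%d of '%s'",
              paste(names(bad), collapse = ", "), length(pages), path),
      class = c("fqMissingChannel", "error", "condition")))
  planes <- lapply(channelMap, function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1]   # drop extra samples
    storage.mode(p) <- "double"
    p
  })
  names(planes) <- names(channelMap)
  dims <- vapply(planes, dim, integer(2))
  if (!all(dims == dims[, 1]))
    stop(errorCondition(
      sprintf("channel planes of '%s' differ in shape", path),
      class = c("fqShapeMismatch", "error", "condition")))
  multiChannelImage(planes, wellId = wellId, fieldId = fieldId)
}

#' Write a multi-channel field as a 16-bit multi-page TIFF
#'
#' Quantizes each channel to integer ADU (clipped to 0..65535) and writes
#' one page per channel, in channel order. Reading the file back with
#' [readField()] reproduces the quantized planes pixel-identically.
#'
#' @param img a [MultiChannelImage-class].
#' @param path output file path.
#' @return invisibly, the channel-name-to-page map of the written file.
#' @export
writeField <- function(img, path) {
  stopifnot(is(img, "MultiChannelImage"))
  q <- quantizeImage(img)
  pages <- lapply(q@channels, function(p) p / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(stats::setNames(seq_along(pages), names(pages)))
}

#' Write a cell label map as a 16-bit TIFF plus a per-cell CSV
#'
#' @param labelMap a [CellLabelMap-class].
#' @param tiffPath output label TIFF (label k stored as intensity k).
#' @param csvPath optional per-cell CSV (`label`, `area_px`, `centroid_row`,
#'   `centroid_col`).
#' @return invisibly, the per-cell data frame.
#' @export
writeLabelMap <- function(labelMap, tiffPath, csvPath = NULL) {
  stopifnot(is(labelMap, "CellLabelMap"))
  tiff::writeTIFF(labelMap@labels / 65535, tiffPath, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  n <- labelMap@nCells
  cent <- labelCentroids(labelMap@labels, n)
  df <- data.frame(label = seq_len(n),
                   area_px = as.integer(tabulate(
                     labelMap@labels[labelMap@labels > 0L], nbins = n)),
                   centroid_row = cent[, "row"], centroid_col = cent[, "col"])
  if (!is.null(csvPath))
    utils::write.csv(df, csvPath, row.names = FALSE, na = "")
  invisible(df)
}

#' Write ground truth tables of a simulated field
#'
#' @param truth a [GroundTruth-class].
#' @param cellsPath,fociPath CSV output paths.
#' @return invisibly, `NULL`.
#' @export
writeGroundTruth <- function(truth, cellsPath, fociPath) {
  stopifnot(is(truth, "GroundTruth"))
  utils::write.csv(truth@cellRecords, cellsPath, row.names = FALSE, na = "")
  utils::write.csv(truth@focusRecords, fociPath, row.names = FALSE, na = "")
  invisible(NULL)
}

#' Round-trippable scene parameter files
#'
#' Scene parameters serialize to a flat YAML mapping and read back into an
#' identical [SceneParams-class] object.
#'
#' @param params a [SceneParams-class].
#' @param path YAML file path.
#' @return `writeSceneParams`: invisibly, the path; `readSceneParams`: the
#'   [SceneParams-class] object.
#' @export
writeSceneParams <- function(params, path) {
  stopifnot(is(params, "SceneParams"))
  vals <- lapply(slotNames("SceneParams"), function(s) slot(params, s))
  names(vals) <- slotNames("SceneParams")
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname writeSceneParams
#' @export
readSceneParams <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sceneParams, vals)
}

## ---------------------------------------------------------------------------
## Run configuration

#' Default end-to-end run configuration
#'
#' Returns the configuration list consumed by [runPipeline()], describing a
#' small simulated plate. The list round-trips losslessly through
#' [writeRunConfig()] / [readRunConfig()]. Replace the `simulate` block with
#' an `input` block (`dir`, `pattern` with `{well}`/`{field}` placeholders,
#' `channelMap`) to analyze data on disk.
#'
#' @param seed integer seed for the run.
#' @return a named configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    aggregation = "median",
    channels = list(segmentation = "lc3b", markers = list("marker")),
    simulate = list(nWells = 2L, fieldsPerWell = 2L, scene = list(),
                    perWellOverrides = list()),
    segmentation = list(),
    foci = list(),
    coloc = list(dilationRadiusPx = 2L, positivityThreshold = 1.75),
    conditions = NULL
  )
}

validateRunConfig <- function(config) {
  if (is.null(config$channels$segmentation))
    stop("config: channels$segmentation must name the segmentation channel")
  if (length(config$channels$markers) < 1L)
    stop("config: channels$markers must name at least one marker channel")
  if (is.null(config$simulate) && is.null(config$input))
    stop("config: needs either a 'simulate' or an 'input' block")
  if (is.null(config$aggregation)) config$aggregation <- "median"
  if (!config$aggregation %in% c("median", "mean"))
    stop("config: aggregation must be 'median' or 'mean'")
  if (is.null(config$seed)) config$seed <- 1L
  config
}

#' Read and write run configurations
#'
#' @param config configuration list (see [defaultRunConfig()]).
#' @param path YAML file path.
#' @return `readRunConfig`: the validated configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  validateRunConfig(yaml::read_yaml(path))
}

## ---------------------------------------------------------------------------
## End-to-end pipeline

# List input fields from an input block: returns list of (wellId, fieldId,
# image) read from disk.
readInputFields <- function(input) {
  stopifnot(!is.null(input$dir), !is.null(input$channelMap))
  pattern <- if (is.null(input$pattern)) "{well}_{field}.tif" else input$pattern
  rx <- paste0("^", gsub("\\{field\\}", "(?<field>[A-Za-z0-9]+)",
               gsub("\\{well\\}", "(?<well>[A-Za-z0-9]+)",
               gsub("([.\\^$+()\\[\\]|\\\\-])", "\\\\\\1", pattern))), "$")
  files <- list.files(input$dir)
  m <- regexpr(rx, files, perl = TRUE)
  hit <- which(m > 0)
  if (!length(hit)) stop(sprintf("no input files in '%s' match '%s'",
                                 input$dir, pattern))
  lapply(hit, function(i) {
    st <- attr(m, "capture.start")[i, ]
    len <- attr(m, "capture.length")[i, ]
    w <- substr(files[i], st["well"], st["well"] + len["well"] - 1L)
    f <- substr(files[i], st["field"], st["field"] + len["field"] - 1L)
    list(wellId = w, fieldId = f,
         image = readField(file.path(input$dir, files[i]),
                           input$channelMap, wellId = w, fieldId = f),
         truth = NULL)
  })
}

runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read -> background subtraction -> cell segmentation ->
#' foci detection -> cell positivity -> per-cell Pearson -> donut-ratio
#' colocalization -> plate aggregation, writing per-cell, per-focus,
#' per-image and per-well CSVs, label-map TIFFs, and a run manifest with a
#' content hash of every output file. Given an identical configuration
#' (including the seed) the outputs are byte-identical.
#'
#' Unless `config$thresholdScope = "field"`, the foci raw threshold is
#' computed once from the pooled background-subtracted pixels of all
#' fields ([plateRawThreshold()]), keeping wells of one plate comparable.
#'
#' @param config configuration list (see [defaultRunConfig()],
#'   [readRunConfig()]).
#' @param outputDir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outputDir) {
  config <- validateRunConfig(config)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outputDir, "labels"), showWarnings = FALSE)
  warningsLog <- character(0)
  logWarn <- function(w) warningsLog <<- c(warningsLog, w)

  segCh <- config$channels$segmentation
  markers <- unlist(config$channels$markers)

  ## stage: acquire fields
  fields <- runStage("acquire", {
    if (!is.null(config$simulate)) {
      sp <- do.call(sceneParams, c(config$simulate$scene,
                                   list(seed = config$seed)))
      ov <- config$simulate$perWellOverrides
      simulatePlate(sp, config$simulate$nWells, config$simulate$fieldsPerWell,
                    perWellOverrides = if (is.null(ov)) list() else ov)
    } else {
      readInputFields(config$input)
    }
  })

  segP <- do.call(segmentationParams, config$segmentation)
  fociP <- do.call(fociParams, config$foci)
  thresholdScope <- if (is.null(config$thresholdScope)) "plate" else
    config$thresholdScope
  if (!thresholdScope %in% c("plate", "field"))
    stop("config: thresholdScope must be 'plate' or 'field'")
  dil <- if (is.null(config$coloc$dilationRadiusPx)) 2L else
    as.integer(config$coloc$dilationRadiusPx)
  thrDonut <- if (is.null(config$coloc$positivityThreshold)) 1.75 else
    as.numeric(config$coloc$positivityThreshold)

  ## background subtraction for all fields, then (by default) one raw
  ## foci threshold pooled over the whole plate for well comparability
  bgFields <- runStage("background", lapply(fields, function(fd) {
    bg <- lapply(fd$image@channels, subtractBackground,
                 bgSigmaPx = segP@bgSigmaPx)
    if (!segCh %in% names(bg))
      stop(sprintf("segmentation channel '%s' not among channels: %s",
                   segCh, paste(names(bg), collapse = ", ")))
    bg
  }))
  if (thresholdScope == "plate" && is.character(fociP@rawThreshold)) {
    mth <- if (identical(fociP@rawThreshold, "otsu")) "otsu" else
      "otsu-foreground"
    fociP@rawThreshold <- plateRawThreshold(
      lapply(bgFields, `[[`, segCh), method = mth)
  }

  cellTabs <- fociTabs <- donutTabs <- imgTabs <- list()
  for (i in seq_along(fields)) {
    fd <- fields[[i]]
    key <- data.frame(well_id = fd$wellId, field_id = fd$fieldId)
    bg <- bgFields[[i]]
    lm <- runStage("segment", segmentCells(bg[[segCh]], segP))
    ft <- runStage("foci", detectFoci(bg[[segCh]], fociP, labelMap = lm,
                                      channels = bg))
    posv <- runStage("positivity", callCellsFociPositive(lm, ft))
    pr <- runStage("pearson", pearsonPerCell(bg[[segCh]], bg[[markers[1]]], lm))

    scores <- list()
    for (mk in markers) {
      if (!mk %in% names(bg))
        stop(sprintf("marker channel '%s' not among channels", mk))
      sc <- runStage("donut", withCallingHandlers(
        donutRatio(ft, bg[[mk]], dilationRadiusPx = dil,
                   positivityThreshold = thrDonut, markerName = mk),
        warning = function(w) {
          logWarn(sprintf("%s/%s: %s", fd$wellId, fd$fieldId,
                          conditionMessage(w)))
          invokeRestart("muffleWarning")
        }))
      scores[[mk]] <- cbind(key, sc, row.names = NULL)
    }
    donutTabs[[i]] <- do.call(rbind, scores)

    cellDf <- merge(posv$perCell, pr, by = "cell_id")
    cellTabs[[i]] <- cbind(key, cellDf, row.names = NULL)
    fociTabs[[i]] <- if (nrow(ft@info)) cbind(key, ft@info, row.names = NULL)
      else NULL

    pctFoci <- lapply(scores, function(s) {
      p <- percentFociPositive(s)
      if (p$empty) NA_real_ else p$percent
    })
    imgTab <- cbind(key, data.frame(
      n_cells = posv$nCells,
      fraction_cells_foci_positive =
        if (posv$noCells) NA_real_ else posv$fractionPositive,
      no_cells = posv$noCells,
      median_pearson = if (any(pr$defined))
        stats::median(pr$pearson_r[pr$defined]) else NA_real_))
    for (mk in markers)
      imgTab[[paste0("pct_foci_positive_", mk)]] <- pctFoci[[mk]]
    imgTabs[[i]] <- imgTab
    if (posv$noCells)
      logWarn(sprintf("%s/%s: no cells segmented", fd$wellId, fd$fieldId))

    writeLabelMap(lm, file.path(outputDir, "labels",
                                sprintf("%s_%s_labels.tif", fd$wellId,
                                        fd$fieldId)))
    if (!is.null(fd$truth))
      writeGroundTruth(fd$truth,
        file.path(outputDir, "labels",
                  sprintf("%s_%s_truth_cells.csv", fd$wellId, fd$fieldId)),
        file.path(outputDir, "labels",
                  sprintf("%s_%s_truth_foci.csv", fd$wellId, fd$fieldId)))
  }

  cells <- do.call(rbind, cellTabs)
  foci <- do.call(rbind, Filter(Negate(is.null), fociTabs))
  if (is.null(foci)) foci <- data.frame()
  donut <- do.call(rbind, donutTabs)
  images <- do.call(rbind, imgTabs)

  ## plate aggregation
  agg <- runStage("aggregate", {
    condMap <- if (!is.null(config$conditions))
      data.frame(well_id = names(config$conditions),
                 condition = unlist(config$conditions)) else NULL
    prVals <- data.frame(well_id = cells$well_id, field_id = cells$field_id,
                         value = cells$pearson_r, defined = cells$defined)
    pearsonAgg <- withCallingHandlers(
      aggregatePlate(prVals, wellStatistic = config$aggregation,
                     conditionMap = condMap),
      warning = function(w) { logWarn(conditionMessage(w))
                              invokeRestart("muffleWarning") })
    fracVals <- data.frame(well_id = images$well_id,
                           field_id = images$field_id,
                           value = images$fraction_cells_foci_positive)
    fracAgg <- withCallingHandlers(
      aggregatePlate(fracVals, wellStatistic = config$aggregation,
                     conditionMap = condMap),
      warning = function(w) { logWarn(conditionMessage(w))
                              invokeRestart("muffleWarning") })
    wells <- merge(pearsonAgg$perWell[c("well_id", "condition", "n_images",
                                        "well_value")],
                   fracAgg$perWell[c("well_id", "well_value")],
                   by = "well_id", suffixes = c("_pearson", "_frac_positive"))
    names(wells)[names(wells) == "well_value_pearson"] <- "median_pearson"
    names(wells)[names(wells) == "well_value_frac_positive"] <-
      "fraction_cells_foci_positive"
    list(wells = wells, pearson = pearsonAgg, fraction = fracAgg)
  })

  writeCsv <- function(df, name) {
    path <- file.path(outputDir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    path
  }
  outFiles <- c(
    writeCsv(cells, "per_cell.csv"),
    writeCsv(foci, "per_focus.csv"),
    writeCsv(donut, "per_focus_donut.csv"),
    writeCsv(images, "per_image.csv"),
    writeCsv(agg$wells, "per_well.csv"),
    writeCsv(agg$pearson$acrossWells, "across_wells_pearson.csv"),
    writeCsv(agg$fraction$acrossWells, "across_wells_fraction_positive.csv"),
    list.files(file.path(outputDir, "labels"), full.names = TRUE))

  manifest <- list(
    version = as.character(utils::packageVersion("fociQuant")),
    config = config,
    files = lapply(stats::setNames(outFiles,
                                   sub(paste0("^", outputDir, "/?"), "",
                                       outFiles)),
                   function(f) unname(tools::md5sum(f))),
    warnings = as.list(warningsLog),
    nWarnings = length(warningsLog))
  yaml::write_yaml(manifest, file.path(outputDir, "manifest.yaml"))
  invisible(manifest)
}
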
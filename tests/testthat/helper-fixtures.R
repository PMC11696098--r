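# Fixtures and independent oracles shared across the suite. Oracles are
# deliberately implemented from first principles (direct loops, explicit
# kernels), independent of the package's code paths.

# binary disk mask on an n x n canvas
mkDisk <- function(n, centerRow, centerCol, r) {
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - centerRow)^2 + (j - centerCol)^2 <= r^2)
}

# direct convolution with an explicitly constructed, normalized Gaussian
# kernel and edge-replicating padding (reference for Gaussian smoothing)
refGaussBlur <- function(plane, sigma) {
  sz <- 2 * ceiling(3 * sigma) + 1
  half <- (sz - 1) %/% 2
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- outer(g1, g1)
  k <- k / sum(k)
  nr <- nrow(plane); nc <- ncol(plane)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -half:half) for (dj in -half:half) {
      ii <- min(max(i + di, 1L), nr)
      jj <- min(max(j + dj, 1L), nc)
      acc <- acc + k[di + half + 1, dj + half + 1] * plane[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# direct-formula Pearson correlation (no stats::cor)
refPearson <- function(a, b) {
  am <- sum(a) / length(a); bm <- sum(b) / length(b)
  num <- sum((a - am) * (b - bm))
  num / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# wrap an integer matrix as a CellLabelMap
mkLabelMap <- function(labels) {
  storage.mode(labels) <- "integer"
  new("CellLabelMap", labels = labels, nCells = max(labels, 0L),
      provenance = list(connectivity = 4L))
}

# build a FociTable directly from a boolean mask (one table row per
# 4-connected component), bypassing detection — for donut-ratio fixtures
mkFociTable <- function(mask, cellIds = NULL) {
  storage.mode(mask) <- "logical"
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask))
  n <- max(lab)
  info <- do.call(rbind, lapply(seq_len(n), function(k) {
    idx <- which(lab == k)
    rows <- (idx - 1) %% nrow(mask) + 1
    cols <- (idx - 1) %/% nrow(mask) + 1
    data.frame(focus_id = k,
               cell_id = if (is.null(cellIds)) NA_integer_ else cellIds[k],
               area_px = length(idx),
               perimeter_px = maskPerimeter(lab == k),
               circularity = maskCircularity(lab == k),
               centroid_row = mean(rows), centroid_col = mean(cols))
  }))
  if (is.null(info))
    info <- data.frame(focus_id = integer(0), cell_id = integer(0),
                       area_px = integer(0), perimeter_px = numeric(0),
                       circularity = numeric(0), centroid_row = numeric(0),
                       centroid_col = numeric(0))
  new("FociTable", info = info, mask = mask, labels = lab,
      params = fociParams(), provenance = list(nBorderFoci = 0L))
}

# brute-force per-pixel donut oracle: for one focus, the ring is every
# in-image pixel within `rad` (Euclidean) of some focus pixel, minus all
# foci pixels; means tallied with explicit loops
refDonut <- function(mask, focusLabel, labels, marker, rad) {
  nr <- nrow(mask); nc <- ncol(mask)
  fpix <- which(labels == focusLabel)
  ring <- matrix(FALSE, nr, nc)
  for (p in fpix) {
    pr <- (p - 1) %% nr + 1; pc <- (p - 1) %/% nr + 1
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if ((i - pr)^2 + (j - pc)^2 <= rad^2) ring[i, j] <- TRUE
    }
  }
  ring[mask] <- FALSE
  list(focusMean = mean(marker[fpix]),
       ringMean = if (any(ring)) mean(marker[ring]) else NA_real_,
       ringN = sum(ring))
}

# small scene parameter sets for fast unit tests (not the study defaults)
smallScene <- function(seed, ...) {
  args <- list(imageHeightPx = 128L, imageWidthPx = 128L, nCells = 4L,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sceneParams, args)
}
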
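## Synthetic confocal-section simulator and the fixed-ROI nucleo-cytoplasmic
## quantification: mean nuclear / cytoplasmic intensities over >= 120 nuclei,
## n/c ratio and fold-change time courses.

#' Describe a synthetic fluorescence scene
#'
#' Nuclei are disks placed on a jittered grid so that nuclei never overlap
#' and every nucleus has a clear cytoplasmic patch at a fixed offset for the
#' paired cytoplasm ROI. Intensities model photon-limited detection:
#' per-pixel Poisson shot noise on the signal plus additive Gaussian read
#' noise.
#'
#' @param width,height image size in pixels.
#' @param nNuclei number of nuclei (default 120, the minimum used for
#'   headline statistics).
#' @param nucleusRadius disk radius in pixels (default 5).
#' @param cytoplasmMean ground-truth cytoplasmic mean intensity (photons).
#' @param shotNoise apply Poisson noise to the signal.
#' @param readNoiseSd additive Gaussian read noise SD.
#' @param background additive flat background level.
#' @param seed integer seed making the scene fully reproducible.
#' @return a list of class \code{"ShuttlingScene"}.
#' @export
shuttlingScene <- function(width = 512L, height = 512L, nNuclei = 120L,
                           nucleusRadius = 5L, cytoplasmMean = 100,
                           shotNoise = TRUE, readNoiseSd = 2,
                           background = 0, seed = 1L) {
  spacing <- 4L * nucleusRadius + 8L
  nx <- (width - spacing) %/% spacing
  ny <- (height - spacing) %/% spacing
  if (nx * ny < nNuclei)
    stop(sprintf("cannot place %d non-overlapping nuclei in a %dx%d image",
                 nNuclei, width, height))
  structure(list(width = as.integer(width), height = as.integer(height),
                 nNuclei = as.integer(nNuclei),
                 nucleusRadius = as.integer(nucleusRadius),
                 cytoplasmMean = cytoplasmMean, shotNoise = isTRUE(shotNoise),
                 readNoiseSd = readNoiseSd, background = background,
                 seed = as.integer(seed), spacing = spacing,
                 nx = nx, ny = ny),
            class = "ShuttlingScene")
}

.placeNuclei <- function(scene) {
  ## jittered grid; jitter bounded so disks stay apart and the cytoplasm ROI
  ## offset (+x by 2r+3) stays clear of every nucleus
  r <- scene$nucleusRadius; sp <- scene$spacing
  centers <- expand.grid(
    x = sp %/% 2L + sp * seq_len(scene$nx),
    y = sp %/% 2L + sp * seq_len(scene$ny))
  centers <- centers[seq_len(scene$nNuclei), , drop = FALSE]
  jit <- 1L
  centers$x <- centers$x + sample(seq(-jit, jit), nrow(centers), replace = TRUE)
  centers$y <- centers$y + sample(seq(-jit, jit), nrow(centers), replace = TRUE)
  centers
}

.diskIdx <- function(cx, cy, r, width, height) {
  xs <- max(1L, cx - r):min(width, cx + r)
  ys <- max(1L, cy - r):min(height, cy + r)
  g <- expand.grid(x = xs, y = ys)
  g <- g[(g$x - cx)^2 + (g$y - cy)^2 <= r^2, , drop = FALSE]
  cbind(g$y, g$x)  # matrix is [row = y, col = x]
}

#' Simulate a fluorescence image series with known nuclear enrichment
#'
#' One grayscale image per time point; nuclear pixels have expected value
#' \code{cytoplasmMean * enrichment[t]}, cytoplasmic pixels
#' \code{cytoplasmMean}. Deterministic given the scene seed.
#'
#' @param scene a \code{\link{shuttlingScene}}.
#' @param timePoints numeric vector of time points (minutes); the first is
#'   taken as t = 0 for fold-change baselines.
#' @param enrichment ground-truth nuclear enrichment factor per time point
#'   (> 0).
#' @return list with \code{images} (list of matrices), \code{nucCenters},
#'   \code{cytoCenters} (data.frames x,y), \code{timePoints},
#'   \code{enrichment} and the scene.
#' @export
simulateShuttlingSeries <- function(scene, timePoints, enrichment) {
  stopifnot(length(timePoints) == length(enrichment))
  if (any(enrichment <= 0)) stop("enrichment factors must be > 0")
  set.seed(scene$seed)
  centers <- .placeNuclei(scene)
  r <- scene$nucleusRadius
  ## pairwise non-overlap check (grid construction should guarantee it)
  d2 <- as.matrix(stats::dist(centers))
  diag(d2) <- Inf
  if (min(d2) < 2 * r)
    stop("internal error: overlapping nuclei generated")
  cyto <- data.frame(x = centers$x + 2L * r + 3L, y = centers$y)
  masks <- lapply(seq_len(nrow(centers)), function(i)
    .diskIdx(centers$x[i], centers$y[i], r, scene$width, scene$height))
  images <- vector("list", length(timePoints))
  for (t in seq_along(timePoints)) {
    img <- matrix(scene$cytoplasmMean, nrow = scene$height, ncol = scene$width)
    nucVal <- scene$cytoplasmMean * enrichment[t]
    for (m in masks) img[m] <- nucVal
    if (scene$shotNoise)
      img[] <- stats::rpois(length(img), lambda = img)
    if (scene$readNoiseSd > 0)
      img <- img + stats::rnorm(length(img), 0, scene$readNoiseSd)
    img <- img + scene$background
    images[[t]] <- img
  }
  list(images = images, nucCenters = centers, cytoCenters = cyto,
       timePoints = timePoints, enrichment = enrichment, scene = scene)
}

#' Measure fixed-size circular ROIs
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param centers data.frame with columns x, y.
#' @param roiRadius disk radius in pixels.
#' @return numeric vector of per-ROI mean intensities.
#' @export
measureNuclei <- function(image, centers, roiRadius) {
  h <- nrow(image); w <- ncol(image)
  if (any(centers$x - roiRadius < 1 | centers$x + roiRadius > w |
          centers$y - roiRadius < 1 | centers$y + roiRadius > h))
    stop("ROI extends outside the image")
  vapply(seq_len(nrow(centers)), function(i) {
    mean(image[.diskIdx(centers$x[i], centers$y[i], roiRadius, w, h)])
  }, numeric(1))
}

#' Nucleo-cytoplasmic shuttling profile of an image series
#'
#' Per time point: mean nuclear and cytoplasmic intensity over all ROIs, the
#' n/c ratio, the fold-change of the nuclear mean relative to the first time
#' point, and the SD across nuclei (reported as biological dispersion rather
#' than a statistical error).
#'
#' @param series output of \code{\link{simulateShuttlingSeries}}, or a list
#'   with \code{images}, \code{nucCenters}, \code{cytoCenters},
#'   \code{timePoints}.
#' @param roiRadius ROI radius; defaults to the scene's nucleus radius.
#' @return data.frame with columns time, nucMean, cytoMean, ncRatio,
#'   foldChange, nucSd, n.
#' @export
shuttlingProfile <- function(series, roiRadius = NULL) {
  if (length(series$timePoints) < 2L)
    stop("need at least 2 time points")
  if (is.null(roiRadius))
    roiRadius <- if (!is.null(series$scene)) series$scene$nucleusRadius else 5L
  nNuc <- nrow(series$nucCenters)
  if (nNuc < 120L)
    warning("fewer than 120 nuclei (", nNuc, "); headline statistics underpowered")
  rows <- lapply(seq_along(series$timePoints), function(t) {
    img <- series$images[[t]]
    nuc <- measureNuclei(img, series$nucCenters, roiRadius)
    cyt <- measureNuclei(img, series$cytoCenters, roiRadius)
    if (mean(cyt) == 0) stop("zero cytoplasmic mean at time ", series$timePoints[t])
    data.frame(time = series$timePoints[t], nucMean = mean(nuc),
               cytoMean = mean(cyt), ncRatio = mean(nuc) / mean(cyt),
               nucSd = stats::sd(nuc), n = length(nuc))
  })
  df <- do.call(rbind, rows)
  df$foldChange <- df$nucMean / df$nucMean[1L]
  df[, c("time", "nucMean", "cytoMean", "ncRatio", "foldChange", "nucSd", "n")]
}
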
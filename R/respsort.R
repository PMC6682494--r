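## Respiration-resolved sorting: body segmentation (threshold + Chan-Vese
## refinement), body-area respiration surrogate with moving-average
## detrending, local binning into N respiratory states with outlier
## exclusion, and resampling of each state's scattered slices onto a regular
## isotropic grid.

#' Segment the body outline in every slice
#'
#' Tissue-air interfaces are roughly estimated with a low intensity threshold
#' inside the region of interest and refined with an iterative Chan-Vese
#' two-phase active contour, implemented as a smoothed threshold-dynamics
#' scheme: each iteration re-estimates the inside/outside mean intensities,
#' reclassifies pixels by the Chan-Vese data term, and regularizes the
#' interface with a Gaussian smoothing of the indicator function (the
#' curvature term).
#'
#' @param stack a \linkS4class{SliceStack}
#' @param roi region of interest, c(y0, y1, x0, x1) in pixels (1-based,
#'   inclusive); defaults to the full image
#' @param initThreshold initial intensity threshold
#' @param cvIters Chan-Vese iterations
#' @param smoothSigma Gaussian sigma of the curvature regularization, pixels
#' @return logical array [ny, nx, nSlices] of body masks
#' @export
segmentBody <- function(stack, roi = NULL, initThreshold = 0.5, cvIters = 20,
                        smoothSigma = 2) {
  d <- dim(stack@images)
  if (is.null(roi)) roi <- c(1L, d[1], 1L, d[2])
  if (roi[1] < 1 || roi[2] > d[1] || roi[3] < 1 || roi[4] > d[2] ||
      roi[1] > roi[2] || roi[3] > roi[4])
    stop("roi must be c(y0, y1, x0, x1) within the image bounds")
  ys <- roi[1]:roi[2]; xs <- roi[3]:roi[4]
  masks <- array(FALSE, dim = d)
  for (i in seq_len(d[3])) {
    img <- stack@images[ys, xs, i]
    mask <- img > initThreshold
    if (!any(mask))
      stop(sprintf("empty initialization in slice %d: threshold excludes everything", i))
    for (it in seq_len(cvIters)) {
      c1 <- mean(img[mask])
      c2 <- if (all(mask)) 0 else mean(img[!mask])
      dataIn <- (img - c2)^2 - (img - c1)^2   # > 0 favours inside
      u <- 0.5 * mask + 0.5 * (dataIn > 0)
      u <- EBImage::gblur(u, sigma = smoothSigma)
      newMask <- u > 0.5
      if (identical(newMask, mask)) { mask <- newMask; break }
      mask <- newMask
    }
    masks[ys, xs, i] <- mask
  }
  masks
}

#' Body-area respiration surrogate
#'
#' The per-slice mask pixel count is the raw body area; a centred moving
#' average (shrinking symmetrically at the edges) captures the slow
#' anatomical variation along z and is subtracted off, leaving the
#' respiratory component.
#'
#' @param masks logical array [ny, nx, nSlices] from \code{segmentBody}, or a
#'   numeric vector of per-slice areas
#' @param window moving-average window, slices (odd, >= 3); defaults to 15
#'   percent of the series length (rounded up to odd)
#' @return a \linkS4class{RespSignal} (unbinned: all labels NA-free zero
#'   states pending \code{binSlices})
#' @export
respirationSignal <- function(masks, window = NULL) {
  area <- if (is.array(masks)) apply(masks, 3, sum) else as.numeric(masks)
  n <- length(area)
  if (is.null(window)) window <- max(3L, oddify(ceiling(0.15 * n)))
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  if (window >= n) stop("window must be shorter than the series")
  trend <- movingAverage(area, window)
  new("RespSignal", rawArea = area, detrended = area - trend,
      stateLabel = rep(NA_integer_, n), excluded = rep(FALSE, n),
      localMean = rep(NA_real_, n), localSd = rep(NA_real_, n),
      nStates = 0L)
}

oddify <- function(k) if (k %% 2 == 0) k + 1L else as.integer(k)

# centred moving average; the window shrinks symmetrically at the edges so
# the trend estimate stays unbiased under a locally linear trend (a one-sided
# shrink would drag the edge trend toward the interior and spuriously flag
# edge slices as outliers)
movingAverage <- function(x, window) {
  h <- (window - 1) %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  i <- seq_len(n)
  hEff <- pmin(h, i - 1L, n - i)
  lo <- i - hEff; hi <- i + hEff
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Bin slices into respiratory states with local outlier rejection
#'
#' For every slice, the mean and standard deviation of the detrended signal
#' are computed over the sliding window of all slices within
#' \code{localFrac}/2 of the series length on either side.  Slices deviating
#' from the local mean by more than \code{outlierK} local SDs are excluded;
#' the remaining slices are assigned to \code{nStates} equal-count bins of
#' the detrended value within their window (state 1 = most expired, state
#' nStates = most inspired).
#'
#' @param sig a \linkS4class{RespSignal}
#' @param nStates number of respiratory states (>= 2)
#' @param localFrac locality as a fraction of the series length (default
#'   0.15: all slices within 15 percent of the total)
#' @param outlierK exclusion multiplier on the local SD (default 1.8)
#' @return the \linkS4class{RespSignal} with state labels, exclusion flags
#'   and local statistics filled in
#' @export
binSlices <- function(sig, nStates = 5, localFrac = 0.15, outlierK = 1.8) {
  nStates <- as.integer(nStates)
  if (nStates < 2) stop("nStates must be >= 2")
  if (localFrac <= 0 || localFrac >= 1) stop("localFrac must be in (0, 1)")
  x <- sig@detrended
  n <- length(x)
  h <- max(2L, as.integer(floor(localFrac * n / 2)))
  if (2L * h + 1L < 5L) stop("local window too small to estimate the SD")
  lm <- numeric(n); ls <- numeric(n); excl <- logical(n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - h):min(n, i + h)]
    lm[i] <- mean(w); ls[i] <- stats::sd(w)
    excl[i] <- is.finite(ls[i]) && ls[i] > 0 &&
      abs(x[i] - lm[i]) > outlierK * ls[i]
  }
  lab <- rep(NA_integer_, n)
  keep <- which(!excl)
  for (i in keep) {
    wIdx <- intersect(max(1L, i - h):min(n, i + h), keep)
    r <- (rank(x[wIdx], ties.method = "average")[match(i, wIdx)] - 0.5) / length(wIdx)
    lab[i] <- min(nStates, max(1L, as.integer(ceiling(r * nStates))))
  }
  out <- sig
  out@stateLabel <- lab
  out@excluded <- excl
  out@localMean <- lm
  out@localSd <- ls
  out@nStates <- as.integer(nStates)
  out
}

#' Resample the binned stack into a respiration-resolved 4D volume
#'
#' Per state and per in-plane pixel, the intensities at that state's
#' scattered slice positions are interpolated onto a regular z grid with
#' isotropic spacing.  With regular in-plane sampling the scattered problem
#' is one-dimensional along z, where natural-neighbour interpolation reduces
#' to linear interpolation between the bracketing slices (the default
#' \code{method = "linear"}); \code{method = "idw"} offers an
#' inverse-distance-weighted alternative using the \code{idwNeighbors}
#' nearest slices.  In-plane resampling to the output spacing is bilinear.
#' Voxels outside a state's z hull are NA.
#'
#' @param stack a \linkS4class{SliceStack}
#' @param sig a binned \linkS4class{RespSignal}
#' @param voxelMm isotropic output voxel spacing, mm; defaults to the
#'   in-plane pixel spacing
#' @param method "linear" (natural-neighbour degenerate case) or "idw"
#' @param idwNeighbors neighbours for the idw mode
#' @return a \linkS4class{Volume4D}
#' @export
reconstruct4D <- function(stack, sig, voxelMm = NULL, method = c("linear", "idw"),
                          idwNeighbors = 3L) {
  method <- match.arg(method)
  if (sig@nStates < 2) stop("bin the respiration signal before reconstructing")
  px <- stack@meta$pixel_mm
  if (is.null(px)) stop("stack meta must record pixel_mm")
  if (is.null(voxelMm)) voxelMm <- px
  d <- dim(stack@images)
  zOut <- seq(min(stack@zMm), max(stack@zMm), by = voxelMm)

  # in-plane resampling factor
  nyOut <- max(2L, round(d[1] * px / voxelMm))
  nxOut <- max(2L, round(d[2] * px / voxelMm))
  resample <- !(nyOut == d[1] && nxOut == d[2])

  vol <- array(NA_real_, dim = c(nyOut, nxOut, length(zOut), sig@nStates))
  centers <- numeric(sig@nStates)
  for (s in seq_len(sig@nStates)) {
    idx <- which(!is.na(sig@stateLabel) & sig@stateLabel == s)
    if (length(idx) < 2)
      stop(sprintf("state %d has fewer than 2 slices", s))
    centers[s] <- mean(sig@detrended[idx])
    zS <- stack@zMm[idx]
    ord <- order(zS); zS <- zS[ord]; idx <- idx[ord]
    imgs <- stack@images[, , idx, drop = FALSE]
    if (resample) {
      imgs2 <- array(0, dim = c(nyOut, nxOut, length(idx)))
      for (j in seq_along(idx))
        imgs2[, , j] <- EBImage::resize(imgs[, , j], w = nyOut, h = nxOut)
      imgs <- imgs2
    }
    inHull <- zOut >= zS[1] & zOut <= zS[length(zS)]
    for (k in which(inHull)) {
      if (method == "linear") {
        j <- findInterval(zOut[k], zS, rightmost.closed = TRUE)
        j <- min(max(j, 1L), length(zS) - 1L)
        wz <- (zOut[k] - zS[j]) / (zS[j + 1] - zS[j])
        vol[, , k, s] <- (1 - wz) * imgs[, , j] + wz * imgs[, , j + 1]
      } else {
        dist <- abs(zS - zOut[k])
        nb <- order(dist)[seq_len(min(idwNeighbors, length(zS)))]
        w <- 1 / pmax(dist[nb], 1e-6)^2
        w <- w / sum(w)
        acc <- 0
        for (q in seq_along(nb)) acc <- acc + w[q] * imgs[, , nb[q]]
        vol[, , k, s] <- acc
      }
    }
  }
  new("Volume4D", values = vol, voxelMm = voxelMm, zMm = zOut,
      stateCenters = centers)
}
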
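test_that("segmentation recovers the phantom body area", {
  ph <- smallPhantom(noiseSd = 0)
  masks <- segmentBody(ph, initThreshold = 0.5)
  area <- apply(masks, 3, sum)
  truth <- ph@meta$truthArea
  expect_lt(max(abs(area - truth) / truth), 0.02)

  # threshold that already matches truth: refinement moves area < 1%
  # (checked at a pixel size fine enough that half-pixel boundary moves
  # stay below that bound)
  phF <- makePhantom(phantomParams(nSlices = 40, inPlaneMatrix = 112,
                                   pixelMm = 1.4, noiseSd = 0, seed = 7))
  areaF <- apply(segmentBody(phF, initThreshold = 0.5), 3, sum)
  initF <- apply(stackImages(phF) > 0.5, 3, sum)
  expect_lt(max(abs(areaF - initF) / initF), 0.01)

  # all-zero image errors (empty initialization)
  phz <- ph
  phz@images <- array(0, dim = dim(ph@images))
  expect_error(segmentBody(phz, initThreshold = 0.5), "empty init")
  expect_error(segmentBody(ph, roi = c(0, 10, 1, 10)), "roi")
})

test_that("detrending removes constants and passes fast oscillations", {
  # constant series -> exactly zero
  sigC <- respirationSignal(rep(100, 60), window = 9)
  expect_equal(max(abs(detrendedSignal(sigC))), 0)

  # sinusoid with period much shorter than the window survives with < 10%
  # attenuation (moving-average transfer function at that period)
  n <- 400; per <- 8; w <- 81
  x <- sin(2 * pi * (1:n) / per)
  d <- detrendedSignal(respirationSignal(x + 500, window = w))
  mid <- 100:300
  expect_gt(max(d[mid]) / 1, 0.9)

  expect_error(respirationSignal(rep(1, 10), window = 11), "window")
  expect_error(respirationSignal(rep(1, 10), window = 4), "odd")
})

test_that("binning uses the documented defaults and is conservative on
           clean data", {
  expect_identical(formals(binSlices)$localFrac, 0.15)
  expect_identical(formals(binSlices)$outlierK, 1.8)

  # constant signal, no noise: all slices keep the middle state, none excluded
  sig <- respirationSignal(rep(250, 80), window = 11)
  b <- binSlices(sig, nStates = 5)
  expect_equal(sum(b@excluded), 0)
  expect_true(all(stateLabels(b) == 3L))

  # noise-free phantom: zero excluded at k = 1.8
  ph <- smallPhantom(noiseSd = 0)
  bN <- binSlices(respirationSignal(segmentBody(ph, initThreshold = 0.5)))
  expect_equal(sum(bN@excluded), 0)

  # adding a constant to all areas changes no state labels
  areas <- apply(segmentBody(ph, initThreshold = 0.5), 3, sum)
  b1 <- binSlices(respirationSignal(areas))
  b2 <- binSlices(respirationSignal(areas + 1234))
  expect_identical(stateLabels(b1), stateLabels(b2))
})

test_that("phantom slices are assigned to their ground-truth-phase states", {
  ph <- smallPhantom()          # SNR 20
  sig <- binSlices(respirationSignal(segmentBody(ph, initThreshold = 0.5)))
  truthB <- binSlices(respirationSignal(ph@meta$truthArea))
  agree <- mean(stateLabels(sig) == stateLabels(truthB), na.rm = TRUE)
  # the small coarse-pixel phantom quantizes the area surrogate harder than
  # the full-size stack (which is held to >= 90% in the end-to-end suite)
  expect_gte(agree, 0.75)
  expect_lt(mean(sig@excluded), 0.1)
  expect_gt(cor(detrendedSignal(sig), sin(ph@truthPhase)), 0.9)
})

test_that("4D resampling is the identity on a single-state uniform stack and
           reports missing coverage monotonically", {
  ph <- smallPhantom(noiseSd = 0)
  px <- ph@meta$pixel_mm

  # force all slices into one state via a constant series, with the z step
  # equal to the voxel size: interpolation must return the inputs
  zStep <- diff(ph@zMm[1:2])
  sub <- seq(1, nSlices(ph), by = max(1L, round(px / zStep)))
  st <- new("SliceStack", images = stackImages(ph)[, , sub],
            zMm = (seq_along(sub) - 1) * px, tS = ph@tS[sub],
            truthPhase = numeric(0), meta = list(pixel_mm = px))
  n <- length(sub)
  sig <- new("RespSignal", rawArea = rep(1, n), detrended = rep(0, n),
             stateLabel = rep(c(1L, 2L), length.out = n),
             excluded = rep(FALSE, n), localMean = rep(0, n),
             localSd = rep(0, n), nStates = 2L)
  sig@stateLabel <- rep(1L, n); sig@nStates <- 2L
  expect_error(reconstruct4D(st, sig), "fewer than 2")
  sig@stateLabel[c(1L, n)] <- 2L                   # give state 2 its hull
  vol <- reconstruct4D(st, sig, voxelMm = px)
  v1 <- vol@values[, , , 1]
  inz <- which(vol@zMm %in% st@zMm[sig@stateLabel == 1L])
  for (k in inz[2:4])
    expect_lt(max(abs(v1[, , k] -
                      stackImages(st)[, , which(st@zMm == vol@zMm[k])])), 1e-6)

  # more states -> more uncovered voxels
  phB <- smallPhantom()
  sigB <- binSlices(respirationSignal(segmentBody(phB, initThreshold = 0.5)))
  v5 <- reconstruct4D(phB, sigB)
  v3 <- reconstruct4D(phB, binSlices(respirationSignal(
    segmentBody(phB, initThreshold = 0.5)), nStates = 3))
  expect_gt(missingFraction(v5), missingFraction(v3))
  # covered voxels are finite
  expect_true(all(is.finite(v5@values[!is.na(v5@values)])))
})
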
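test_that("zero flips give zero signal and static slices give symmetric
           steady profiles", {
  par0 <- sweepParams(rs = 0, tr = 6, npe = 40, scheme = "ascending_dynamics",
                      nSlices = 1, nDynamics = 1, startupPulses = 0)
  fm <- buildFlipMatrix(bssfpPulse(), par0)
  fmZ <- fm; fmZ@values <- fm@values * 0
  smZ <- simulateSignalMatrix(fmZ, muscleTissue())
  expect_equal(max(Mod(smZ@values)), 0)

  # static single slice: profile symmetric about the slice centre, and the
  # peak matches the single-column EPG route
  parL <- sweepParams(rs = 0, tr = 6, npe = 900, scheme = "ascending_dynamics",
                      nSlices = 1, nDynamics = 1, startupPulses = 0)
  fmL <- buildFlipMatrix(bssfpPulse(), parL)
  smL <- simulateSignalMatrix(fmL, muscleTissue())
  prof <- Mod(smL@values[, 900])
  m <- profileMetrics(smL, 900)
  expect_lt(abs(m$skewness), 0.05)
  expect_lt(abs(m$centroid - fmL@centers[1]), fmL@grid@dz)
  expect_lte(max(Mod(smL@values)), 1 + 1e-9)    # |S| never exceeds M0
  # peak element equals a plain train simulation at the peak flip
  ctr <- which.max(fmL@values[, 1])
  tr1 <- pulseTrain(fmL@values[ctr, ], tr = 6, kind = "bssfp",
                    phases = fmL@phases)
  s1 <- simulateTrain(tr1, muscleTissue())
  expect_equal(Mod(smL@values[ctr, 900]), Mod(s1[900]), tolerance = 1e-10)
})

test_that("swept stable-state profiles are leading-edge skewed and narrow
           with increasing sweep rate", {
  fw <- c(); sk <- c()
  for (rs in c(0.1, 0.5, 1)) {
    par <- sweepParams(rs = rs, tr = 6, npe = 900, scheme = "sweep")
    fm <- buildFlipMatrix(bssfpPulse(), par)
    sm <- simulateSignalMatrix(fm, muscleTissue())
    m <- profileMetrics(sm, 900)
    fw <- c(fw, m$fwhm); sk <- c(sk, m$skewness)
  }
  expect_true(all(sk > 0))                      # skewed toward leading edge
  expect_true(all(diff(fw) < 0))                # FWHM decreases with rate

  # and the static profile is wider than all swept ones
  parS <- sweepParams(rs = 0, tr = 6, npe = 900, scheme = "ascending_dynamics",
                      nSlices = 1, nDynamics = 1, startupPulses = 0)
  smS <- simulateSignalMatrix(buildFlipMatrix(bssfpPulse(), parS), muscleTissue())
  expect_gt(profileMetrics(smS, 900)$fwhm, max(fw))
})

test_that("measured slice signal: sweep is stable, a restarting staircase is
           not", {
  st <- runStabilityStudy(npe = 60, nSlices = 4, nDynamics = 2,
                          settleAfter = 300)
  expect_lt(st$sweep$cv, 0.01)
  expect_gt(st$dense_ascending$cv, 5 * st$sweep$cv)
  expect_equal(length(st$sweep$signal), 4 * 2 * 60)
})

test_that("profile metrics reject degenerate inputs", {
  par <- sweepParams(rs = 0.5, tr = 6, npe = 30, scheme = "sweep")
  fm <- buildFlipMatrix(bssfpPulse(), par)
  fm@values <- fm@values * 0
  sm <- simulateSignalMatrix(fm, muscleTissue())
  expect_error(profileMetrics(sm, 10), "zero")
})

test_that("the stable state recovers after sudden motion blips", {
  recov <- function(rs, n = 1700) {
    par <- if (rs > 0) sweepParams(rs = rs, tr = 6, npe = n, scheme = "sweep")
      else sweepParams(rs = 0, tr = 6, npe = n, scheme = "ascending_dynamics",
                       nSlices = 1, nDynamics = 1, startupPulses = 0)
    fm <- buildFlipMatrix(bssfpPulse(), par, motionMargin = 3)
    d <- displacementSeries(motionModel("blips", blipTimes = 800,
                                        blipSizes = 1.5), ncol(fm@values), 6)
    fmM <- applyMotion(fm, d)
    sm <- simulateSignalMatrix(fmM, muscleTissue())
    sig <- measuredSliceSignal(sm, fmM)
    pre <- mean(sig[750:799])
    dev <- abs(sig - pre) / pre
    stays <- rev(cummax(rev(dev > 0.01)))
    which(seq_along(sig) >= 800 & stays == 0)[1] - 800
  }
  rM2d <- recov(0)
  rSweep <- recov(1)
  expect_false(is.na(rM2d)); expect_false(is.na(rSweep))
  # signal returns to within 1% of its pre-blip value, and the swept
  # acquisition recovers within twice the M2D time
  expect_lt(rSweep, 2 * rM2d)
})
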
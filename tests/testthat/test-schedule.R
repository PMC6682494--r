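test_that("excitation frequency is the linear slice-select relation", {
  # z = 0 gives the Larmor frequency
  expect_equal(excitationFrequency(0, gss = 10, b0 = 3), 42.577 * 3 * 1e6)
  # 10 mT/m at 1 mm offsets the frequency by 425.77 Hz
  expect_equal(excitationFrequency(1, gss = 10) - excitationFrequency(0, gss = 10),
               425.77, tolerance = 1e-9)
  # linearity in z
  z1 <- 3.2; z2 <- -1.7
  expect_equal(excitationFrequency(z1 + z2, 10) - excitationFrequency(z1, 10),
               excitationFrequency(z2, 10) - excitationFrequency(0, 10),
               tolerance = 1e-6)
})

test_that("effective thickness reproduces the printed protocol values", {
  expect_equal(effectiveThickness(3.0, 0, 64), 3.0)       # M2D limit
  expect_equal(effectiveThickness(3.0, 0.05, 64), 3.096, tolerance = 1e-12)
  expect_equal(effectiveThickness(4.0, 0.17, 60), 4.408, tolerance = 1e-12)
  # the printed table rounds to 2 decimals
  expect_lt(abs(effectiveThickness(3.0, 0.05, 64) - 3.09), 0.01)
  expect_lt(abs(effectiveThickness(4.0, 0.17, 60) - 4.40), 0.01)
})

test_that("phase-encode counts derive from the printed protocol parameters", {
  expect_equal(npeFromAcceleration(320, 0.6, 3), 64)
  expect_equal(npeFromDuration(240, 550, 7.3), 60)
})

test_that("adjacent swept slices share ~97% of excited tissue at rs 0.05%", {
  expect_lt(abs(adjacentSliceSharing(3.0, 0.05, 64) - 97), 0.5)
  expect_equal(adjacentSliceSharing(3.0, 0, 64), 100)
})

test_that("centre positions follow the scheme definitions", {
  # sweep: strictly increasing arithmetic progression with step rs/100*dz
  par <- sweepParams(rs = 0.14, tr = 6, npe = 200, scheme = "sweep")
  cp <- centerPositions(par, 4)
  expect_equal(diff(cp$centers), rep(0.0056, 199), tolerance = 1e-12)
  expect_true(all(diff(cp$centers) > 0))
  expect_true(all(cp$acquired))

  # dense ascending: nSlices*nDynamics steps spanning the sweep travel
  parD <- sweepParams(rs = 0.14, tr = 6, npe = 40, scheme = "dense_ascending",
                      nSlices = 5, nDynamics = 3, startupPulses = 0)
  cpD <- centerPositions(parD, 4)
  steps <- unique(cpD$centers)
  expect_length(steps, 15)
  travel <- 0.0056 * (5 * 3 * 40 - 1)
  expect_equal(max(steps), travel, tolerance = 1e-9)
  expect_equal(diff(steps), rep(travel / 14, 14), tolerance = 1e-9)

  # interleaved: all slices once, then repeated nDynamics times
  parI <- sweepParams(rs = 0, tr = 6, npe = 10, scheme = "interleaved",
                      nSlices = 3, nDynamics = 2, startupPulses = 2)
  cpI <- centerPositions(parI, 4)
  blockPos <- cpI$centers[cpI$sliceStart]
  expect_equal(blockPos, c(0, 4, 8, 0, 4, 8))
  expect_equal(sum(cpI$acquired), 3 * 2 * 10)

  # ascending with contiguous dynamics: one block per slice
  parA <- sweepParams(rs = 0, tr = 6, npe = 10, scheme = "ascending_dynamics",
                      nSlices = 3, nDynamics = 2, startupPulses = 2)
  cpA <- centerPositions(parA, 4)
  expect_equal(sum(cpA$sliceStart), 3)
  expect_equal(sum(cpA$acquired), 60)
})

test_that("flip matrix columns are exact translated copies of one profile", {
  par <- sweepParams(rs = 0.14, tr = 6, npe = 120, scheme = "sweep")
  fm <- buildFlipMatrix(bssfpPulse(), par)
  v <- flipValues(fm)
  # per-pulse centre step and peak flip
  expect_equal(diff(fm@centers[1:2]), 0.0056, tolerance = 1e-12)
  expect_equal(max(v), 22, tolerance = 1e-6)
  # column t+1 is column t shifted by exactly one step (integer cells)
  s <- round(0.0056 / fm@grid@dz)
  n <- nrow(v)
  for (t in c(1, 50, 119)) {
    expect_identical(v[(s + 1):n, t + 1], v[1:(n - s), t])
  }

  # rs = 0: all columns identical
  par0 <- sweepParams(rs = 0, tr = 6, npe = 30, scheme = "ascending_dynamics",
                      nSlices = 1, nDynamics = 1, startupPulses = 0)
  fm0 <- buildFlipMatrix(bssfpPulse(), par0)
  expect_equal(max(abs(fm0@values - fm0@values[, 1])), 0)
})

test_that("bSSFP M2D slices get a half-alpha first pulse and phase restart", {
  par <- sweepParams(rs = 0.14, tr = 6, npe = 20, scheme = "dense_ascending",
                     nSlices = 2, nDynamics = 1, startupPulses = 4,
                     sequence = "bssfp")
  fm <- buildFlipMatrix(bssfpPulse(), par)
  starts <- which(c(TRUE, diff(fm@centers) != 0))
  expect_equal(max(fm@values[, starts[2]]), 11, tolerance = 1e-6)  # alpha/2
  expect_equal(fm@phases[starts[2] + 0:3], c(0, 180, 0, 180))
  expect_false(any(fm@acquired[starts[2] + 0:3]))
})

test_that("invalid schedule parameters are rejected", {
  expect_error(sweepParams(rs = 0, tr = 6, npe = 10, scheme = "sweep"),
               "rs > 0")
  expect_error(sweepParams(rs = -1, tr = 6, npe = 10, scheme = "sweep"))
  expect_error(centerPositions(sweepParams(rs = 0.1, tr = 6, npe = 10,
                                           scheme = "nonsense"), 4))
})
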
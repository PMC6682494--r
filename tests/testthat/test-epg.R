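test_that("RF rotation has the expected fixed points and single-pulse action", {
  eq <- equilibriumState()

  # zero flip is the identity for any phase and any state
  s <- rfRotation(eq, 30, 10)
  for (ph in c(0, 45, 180, 273)) {
    expect_identical(rfRotation(s, 0, ph)@fplus, s@fplus)
    expect_identical(rfRotation(s, 0, ph)@zk, s@zk)
  }

  # 90-degree pulse fully excites equilibrium
  s90 <- rfRotation(eq, 90, 0)
  expect_equal(Mod(s90@fplus[1]), 1, tolerance = 1e-12)
  expect_equal(Mod(s90@zk[1]), 0, tolerance = 1e-12)

  # 45-degree pulse at phase 90 equals rotating [0,0,1] by 45 deg about y:
  # Mxy = sin(45), Mz = cos(45) (frozen from the 3x3 rotation-matrix oracle)
  s45 <- rfRotation(eq, 45, 90)
  expect_equal(s45@fplus[1], complex(real = sin(pi / 4)), tolerance = 1e-12)
  expect_equal(s45@zk[1], complex(real = cos(pi / 4)), tolerance = 1e-12)
})

test_that("RF rotation conserves the per-order state norm", {
  set.seed(42)
  st <- equilibriumState(kmax = 6)
  for (i in 1:40) {
    st2 <- rfRotation(st, runif(1, -180, 180), runif(1, 0, 360))
    expect_equal(stateNorm(st2), stateNorm(st), tolerance = 1e-10)
    st <- st2
    # no step creates magnetization beyond m0 (norm form bounded by 2 m0^2)
    expect_lte(stateNorm(st), 2 + 1e-9)
  }
})

test_that("relaxation has the equilibrium fixed point and closed-form decay", {
  tis <- muscleTissue()
  eq <- equilibriumState(kmax = 3)

  # zero duration changes nothing
  ex <- rfRotation(eq, 37, 12)
  r0 <- relaxAndShift(ex, tis, 0)
  expect_equal(r0@fplus, ex@fplus)
  expect_equal(r0@zk, ex@zk)

  # equilibrium is a fixed point for any duration without shift
  r <- relaxAndShift(eq, tis, 123)
  expect_equal(r@zk[1], 1 + 0i, tolerance = 1e-12)
  expect_equal(Mod(r@fplus[1]), 0)

  # pure F0 state decays as exp(-t/T2) over t = T2
  st <- rfRotation(equilibriumState(), 90, 0)
  st <- relaxAndShift(st, tis, 50)
  expect_equal(Mod(st@fplus[1]), exp(-1), tolerance = 1e-12)

  expect_error(relaxAndShift(eq, tis, -1), "duration")
})

test_that("the k-shift moves transverse orders up and discards beyond kmax", {
  tis <- muscleTissue()
  st <- rfRotation(equilibriumState(kmax = 2), 90, 0)
  f0 <- st@fplus[1]
  sh <- relaxAndShift(st, tis, 0, doShift = TRUE)
  expect_equal(sh@fplus[2], f0)
  expect_equal(Mod(sh@fplus[1]), 0)          # nothing refocuses yet
  # shifting kmax+1 times discards everything transverse
  for (i in 1:3) sh <- relaxAndShift(sh, tis, 0, doShift = TRUE)
  expect_equal(max(Mod(sh@fplus)), 0)
})

test_that("EPG equals the isochromat Bloch oracle on short trains", {
  tis <- muscleTissue()
  # balanced: alternating-phase train vs a single on-resonance isochromat
  trB <- pulseTrain(22, tr = 6, kind = "bssfp", n = 50)
  eB <- simulateTrain(trB, tis)
  oB <- blochTrain(trB, tis)
  expect_lt(max(Mod(eB - oB)), 1e-4 * max(Mod(oB)))

  # spoiled: quadratic RF-spoiling train vs 2000 uniformly dephased spins
  trS <- pulseTrain(15, tr = 5, kind = "spgr", n = 50)
  eS <- simulateTrain(trS, tis)
  oS <- blochTrain(trS, tis, nSpins = 2000)
  expect_lt(max(Mod(eS - oS)), 1e-4 * max(Mod(oS)))

  # also with the flow-study tissues and a different flip/TR
  trS2 <- pulseTrain(70, tr = 15, kind = "spgr", n = 50)
  for (tis2 in list(bloodT(), greyT())) {
    e2 <- simulateTrain(trS2, tis2)
    o2 <- blochTrain(trS2, tis2, nSpins = 2000)
    expect_lt(max(Mod(e2 - o2)), 1e-4 * max(Mod(o2)))
  }
})

test_that("long trains reach the closed-form steady states", {
  tis <- muscleTissue()

  # alternating-phase bSSFP converges to the on-resonance closed form
  # (echo at TE = TR/2 carries an extra exp(-TE/T2))
  trB <- pulseTrain(22, tr = 6, kind = "bssfp", n = 2500)
  sB <- simulateTrain(trB, tis)
  ssB <- bssfpSignal(22, 6, tis) * exp(-3 / 50)
  expect_lt(abs(Mod(sB[2500]) - ssB) / ssB, 1e-3)

  # spoiled train in the ideal-spoiling limit matches the Ernst formula
  trS <- pulseTrain(15, tr = 5, kind = "spgr", n = 400)
  sS <- simulateTrain(trS, tis, kmax = 0)
  ssS <- ernstSignal(15, 5, tis) * exp(-2.5 / 50)
  expect_lt(abs(Mod(sS[400]) - ssS) / ssS, 1e-3)

  # quadratic 150-degree RF spoiling settles to a stable pseudo steady state
  # in the vicinity of (but not exactly at) the Ernst value
  sR <- simulateTrain(pulseTrain(15, tr = 5, kind = "spgr", n = 1500), tis)
  lastM <- Mod(sR[1401:1500])
  expect_lt(stats::sd(lastM) / mean(lastM), 1e-3)
  expect_lt(abs(mean(lastM) - ssS) / ssS, 0.10)
})

test_that("bSSFP transient settles within 1 to 5 T1", {
  tis <- muscleTissue()
  trB <- pulseTrain(22, tr = 6, kind = "bssfp", n = 2500)
  s <- Mod(simulateTrain(trB, tis))
  ss <- bssfpSignal(22, 6, tis) * exp(-3 / 50)
  dev <- abs(s - ss) / ss
  nSettle <- which(rev(cummax(rev(dev))) <= 0.01)[1]
  tSettle <- nSettle * 6           # ms
  expect_gt(tSettle, tis@t1)
  expect_lt(tSettle, 5 * tis@t1)
  # the oscillation envelope (block maxima of the deviation) decays
  # monotonically toward the steady state
  dev <- abs(s[1:1000] - ss)
  env <- apply(matrix(dev, nrow = 25), 2, max)
  expect_true(all(diff(env) < 0))
})

test_that("degenerate trains are handled", {
  tis <- muscleTissue()
  tr0 <- pulseTrain(0, tr = 6, kind = "bssfp", n = 20)
  expect_equal(max(Mod(simulateTrain(tr0, tis))), 0)
  expect_error(pulseTrain(10, tr = 5, kind = "nope", n = 5))
  expect_error(pulseTrain(10, tr = 5, kind = "bssfp", n = 5, te = 9))
})
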
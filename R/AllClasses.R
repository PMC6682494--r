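#' @import methods
#' @importFrom stats approx fft rnorm runif sd quantile filter
#' @importFrom utils head tail
#' @useDynLib sweepmri, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## Tissue
## ---------------------------------------------------------------------------

#' Tissue relaxation parameters
#'
#' Bundle of longitudinal (T1) and transverse (T2) relaxation times in
#' milliseconds plus the equilibrium magnetization M0 (dimensionless, default
#' 1).  T1 >= T2 > 0 is enforced.
#'
#' @slot t1 longitudinal relaxation time, ms
#' @slot t2 transverse relaxation time, ms
#' @slot m0 equilibrium magnetization (dimensionless)
#' @export
setClass("Tissue", representation(t1 = "numeric", t2 = "numeric", m0 = "numeric"))

setValidity("Tissue", function(object) {
  if (length(object@t1) != 1L || length(object@t2) != 1L || length(object@m0) != 1L)
    return("t1, t2 and m0 must be scalars")
  if (!is.finite(object@t1) || !is.finite(object@t2) || !is.finite(object@m0))
    return("t1, t2 and m0 must be finite")
  if (object@t2 <= 0) return("t2 must be > 0")
  if (object@t1 < object@t2) return("t1 must be >= t2")
  if (object@m0 <= 0) return("m0 must be > 0")
  TRUE
})

#' Create a Tissue object
#'
#' @param t1 longitudinal relaxation time, ms
#' @param t2 transverse relaxation time, ms
#' @param m0 equilibrium magnetization, default 1
#' @return a \linkS4class{Tissue}
#' @examples
#' tissue(1412, 50)   # skeletal muscle at 3T
#' @export
tissue <- function(t1, t2, m0 = 1) new("Tissue", t1 = t1, t2 = t2, m0 = m0)

setMethod("show", "Tissue", function(object) {
  cat(sprintf("Tissue: T1 = %g ms, T2 = %g ms, M0 = %g\n",
              object@t1, object@t2, object@m0))
})

## ---------------------------------------------------------------------------
## EPGState
## ---------------------------------------------------------------------------

#' Extended-phase-graph configuration state
#'
#' Complex configuration-state amplitudes for one tissue element: \code{fplus}
#' holds F_k for k = 0..kmax, \code{fminus} holds conj(F_{-k}), and \code{zk}
#' the longitudinal amplitudes Z_k.  At equilibrium Z_0 = m0 and every other
#' amplitude is zero.
#'
#' @slot fplus complex vector, transverse configuration amplitudes F_k
#' @slot fminus complex vector, conj(F_{-k})
#' @slot zk complex vector, longitudinal configuration amplitudes Z_k
#' @slot m0 equilibrium magnetization the state relaxes toward
#' @export
setClass("EPGState", representation(fplus = "complex", fminus = "complex",
                                    zk = "complex", m0 = "numeric"))

setValidity("EPGState", function(object) {
  n <- length(object@fplus)
  if (length(object@fminus) != n || length(object@zk) != n)
    return("fplus, fminus and zk must have equal length")
  if (n < 1L) return("state must retain at least order k = 0")
  if (abs(object@fminus[1] - Conj(object@fplus[1])) > 1e-9)
    return("fminus[k=0] must equal conj(fplus[k=0])")
  TRUE
})

#' Equilibrium EPG state
#'
#' @param m0 equilibrium magnetization
#' @param kmax maximum configuration order retained
#' @return an \linkS4class{EPGState} with Z_0 = m0 and all other amplitudes 0
#' @export
equilibriumState <- function(m0 = 1, kmax = 0) {
  z <- complex(real = rep(0, kmax + 1))
  z[1] <- m0 + 0i
  new("EPGState", fplus = complex(real = rep(0, kmax + 1)),
      fminus = complex(real = rep(0, kmax + 1)), zk = z, m0 = m0)
}

setMethod("show", "EPGState", function(object) {
  cat(sprintf("EPGState: kmax = %d, |F0| = %.4g, Z0 = %.4g\n",
              length(object@fplus) - 1L, Mod(object@fplus[1]),
              Re(object@zk[1])))
})

## ---------------------------------------------------------------------------
## PulseTrain
## ---------------------------------------------------------------------------

#' RF pulse train
#'
#' Flip angles and RF phases (degrees, one per TR) together with the timing
#' and the sequence family: \code{"bssfp"} (balanced, no gradient dephasing
#' between pulses) or \code{"spgr"} (spoiled, unit k-shift per TR).
#'
#' @slot flips numeric, flip angle per pulse, degrees
#' @slot phases numeric, RF phase per pulse, degrees
#' @slot tr repetition time, ms
#' @slot te echo time, ms
#' @slot kind "bssfp" or "spgr"
#' @export
setClass("PulseTrain", representation(flips = "numeric", phases = "numeric",
                                      tr = "numeric", te = "numeric",
                                      kind = "character"))

setValidity("PulseTrain", function(object) {
  if (length(object@flips) < 1L) return("train must contain at least one pulse")
  if (length(object@phases) != length(object@flips))
    return("flips and phases must have equal length")
  if (!(object@kind %in% c("bssfp", "spgr")))
    return(sprintf("unknown sequence kind '%s'", object@kind))
  if (object@te < 0 || object@te > object@tr) return("need 0 <= te <= tr")
  TRUE
})

#' Create a pulse train
#'
#' If \code{phases} is NULL a default schedule is used: alternating {0, 180}
#' degrees for bSSFP, quadratic RF-spoiling phase with a 150 degree increment
#' (phi_n = 150 * n(n+1)/2) for SPGR.  TE defaults to TR/2.
#'
#' @param flips flip angle per pulse, degrees (recycled if scalar with n)
#' @param tr repetition time, ms
#' @param kind "bssfp" or "spgr"
#' @param n number of pulses when \code{flips} is scalar
#' @param phases RF phase per pulse, degrees, or NULL for the default schedule
#' @param te echo time, ms (default TR/2)
#' @param phase_increment RF-spoiling phase increment for SPGR, degrees
#' @return a \linkS4class{PulseTrain}
#' @export
pulseTrain <- function(flips, tr, kind = c("bssfp", "spgr"), n = length(flips),
                       phases = NULL, te = tr / 2, phase_increment = 150) {
  kind <- match.arg(kind)
  if (length(flips) == 1L && n > 1L) flips <- rep(flips, n)
  if (is.null(phases)) {
    phases <- defaultPhases(length(flips), kind, phase_increment)
  }
  new("PulseTrain", flips = flips, phases = phases, tr = tr, te = te, kind = kind)
}

defaultPhases <- function(n, kind, phase_increment = 150) {
  if (kind == "bssfp") {
    rep(c(0, 180), length.out = n)
  } else {
    idx <- seq_len(n) - 1
    (phase_increment * idx * (idx + 1) / 2) %% 360
  }
}

setMethod("show", "PulseTrain", function(object) {
  cat(sprintf("PulseTrain (%s): %d pulses, TR = %g ms, TE = %g ms, flips %g..%g deg\n",
              object@kind, length(object@flips), object@tr, object@te,
              min(object@flips), max(object@flips)))
})

## ---------------------------------------------------------------------------
## PulseSpec / SpatialGrid
## ---------------------------------------------------------------------------

#' Slice-selective RF pulse specification
#'
#' Parameterized sinc-Gauss envelope: \code{"sinc_gauss_symmetric"} keeps the
#' full symmetric apodized envelope (balanced sequences),
#' \code{"sinc_gauss_asymmetric"} truncates the trailing half of the envelope
#' (short-TE spoiled sequences).  The nominal thickness is the full width at
#' half maximum of the flip-angle profile.
#'
#' @slot shape "sinc_gauss_symmetric" or "sinc_gauss_asymmetric"
#' @slot timeBandwidth dimensionless time-bandwidth product
#' @slot nominalFlip peak flip angle, degrees
#' @slot nominalThickness FWHM slice thickness, mm
#' @export
setClass("PulseSpec", representation(shape = "character", timeBandwidth = "numeric",
                                     nominalFlip = "numeric",
                                     nominalThickness = "numeric"))

setValidity("PulseSpec", function(object) {
  if (!(object@shape %in% c("sinc_gauss_symmetric", "sinc_gauss_asymmetric")))
    return(sprintf("unknown pulse shape '%s'", object@shape))
  if (object@timeBandwidth <= 0) return("timeBandwidth must be > 0")
  if (object@nominalThickness <= 0) return("nominalThickness must be > 0")
  TRUE
})

#' Create a pulse specification
#' @param shape envelope shape
#' @param nominalFlip peak flip angle, degrees
#' @param nominalThickness FWHM slice thickness, mm
#' @param timeBandwidth time-bandwidth product (default 2: the soft profile of
#'   a short RF pulse)
#' @return a \linkS4class{PulseSpec}
#' @export
pulseSpec <- function(shape = c("sinc_gauss_symmetric", "sinc_gauss_asymmetric"),
                      nominalFlip = 22, nominalThickness = 4, timeBandwidth = 2) {
  shape <- match.arg(shape)
  new("PulseSpec", shape = shape, timeBandwidth = timeBandwidth,
      nominalFlip = nominalFlip, nominalThickness = nominalThickness)
}

#' Regular 1D spatial grid along the slice direction
#'
#' @slot z0 position of the first element, mm
#' @slot dz grid spacing, mm
#' @slot n number of elements
#' @export
setClass("SpatialGrid", representation(z0 = "numeric", dz = "numeric", n = "integer"))

setValidity("SpatialGrid", function(object) {
  if (object@dz <= 0) return("dz must be > 0")
  if (object@n < 1L) return("n must be >= 1")
  TRUE
})

#' @param z0 position of first element, mm
#' @param dz spacing, mm
#' @param n number of elements
#' @rdname SpatialGrid-class
#' @export
spatialGrid <- function(z0, dz, n) new("SpatialGrid", z0 = z0, dz = dz, n = as.integer(n))

#' Grid element positions
#' @param grid a \linkS4class{SpatialGrid}
#' @return numeric vector of z positions, mm
#' @export
zValues <- function(grid) grid@z0 + (seq_len(grid@n) - 1) * grid@dz

setMethod("show", "SpatialGrid", function(object) {
  cat(sprintf("SpatialGrid: %d elements, dz = %g mm, z in [%g, %g] mm\n",
              object@n, object@dz, object@z0,
              object@z0 + (object@n - 1) * object@dz))
})

## ---------------------------------------------------------------------------
## SweepParams
## ---------------------------------------------------------------------------

#' Acquisition-ordering parameters
#'
#' Describes how slice-centre positions advance over the pulse train.  The
#' \code{"sweep"} scheme advances the centre by delta_z * rs/100 every pulse;
#' the three multi-2D (M2D) schemes hold the centre fixed within a slice and
#' step between slices: \code{"interleaved"} (all slices once per dynamic),
#' \code{"ascending_dynamics"} (all dynamics of a slice contiguously) and
#' \code{"dense_ascending"} (nSlices x nDynamics distinct equally spaced
#' positions covering the same travel as the equivalent sweep).
#'
#' @slot rs sweep rate, percent of the FWHM thickness per TR
#' @slot tr repetition time, ms
#' @slot npe phase encodes (acquired pulses) per slice
#' @slot scheme acquisition ordering
#' @slot nSlices number of slice positions
#' @slot nDynamics number of repeats per position
#' @slot startupPulses dummy pulses before each M2D slice
#' @slot sequence "bssfp" or "spgr" (sets the RF phase schedule and the
#'   half-alpha catalyzation pulse for bSSFP M2D slices)
#' @slot sliceSpacing centre-to-centre spacing for interleaved /
#'   ascending_dynamics schemes, in units of the nominal thickness
#' @export
setClass("SweepParams", representation(rs = "numeric", tr = "numeric",
                                       npe = "integer", scheme = "character",
                                       nSlices = "integer", nDynamics = "integer",
                                       startupPulses = "integer",
                                       sequence = "character",
                                       sliceSpacing = "numeric"))

setValidity("SweepParams", function(object) {
  if (!(object@scheme %in% c("interleaved", "ascending_dynamics",
                             "dense_ascending", "sweep")))
    return(sprintf("unknown scheme '%s'", object@scheme))
  if (object@rs < 0) return("rs must be >= 0")
  if (object@scheme == "sweep" && object@rs <= 0)
    return("scheme 'sweep' requires rs > 0")
  if (object@npe < 1L) return("npe must be >= 1")
  if (object@nSlices < 1L || object@nDynamics < 1L)
    return("nSlices and nDynamics must be >= 1")
  if (object@startupPulses < 0L) return("startupPulses must be >= 0")
  if (!(object@sequence %in% c("bssfp", "spgr")))
    return(sprintf("unknown sequence '%s'", object@sequence))
  TRUE
})

#' @param rs sweep rate, percent of FWHM thickness per TR
#' @param tr repetition time, ms
#' @param npe phase encodes per slice
#' @param scheme acquisition ordering
#' @param nSlices slice positions
#' @param nDynamics repeats
#' @param startupPulses dummy pulses per M2D slice (default 10)
#' @param sequence "bssfp" or "spgr"
#' @param sliceSpacing M2D slice spacing in units of the nominal thickness
#' @rdname SweepParams-class
#' @export
sweepParams <- function(rs, tr, npe, scheme = "sweep", nSlices = 1, nDynamics = 1,
                        startupPulses = 10, sequence = "bssfp", sliceSpacing = 1) {
  new("SweepParams", rs = rs, tr = tr, npe = as.integer(npe), scheme = scheme,
      nSlices = as.integer(nSlices), nDynamics = as.integer(nDynamics),
      startupPulses = as.integer(startupPulses), sequence = sequence,
      sliceSpacing = sliceSpacing)
}

## ---------------------------------------------------------------------------
## FlipMatrix / SignalMatrix
## ---------------------------------------------------------------------------

#' Flip-angle matrix F(z, t)
#'
#' Flip angle (degrees) experienced by each grid element at each pulse, with
#' the shared RF phase schedule, the slice-centre trajectory and acquisition
#' flags (FALSE for startup/dummy pulses).
#'
#' @slot values numeric matrix [grid element, pulse], degrees
#' @slot phases RF phase per pulse, degrees
#' @slot grid the \linkS4class{SpatialGrid}
#' @slot centers slice-centre z per pulse, mm
#' @slot acquired logical per pulse, FALSE for startup pulses
#' @slot deltaZ nominal FWHM slice thickness, mm
#' @slot tr repetition time, ms
#' @slot sequence "bssfp" or "spgr"
#' @export
setClass("FlipMatrix", representation(values = "matrix", phases = "numeric",
                                      grid = "SpatialGrid", centers = "numeric",
                                      acquired = "logical", deltaZ = "numeric",
                                      tr = "numeric", sequence = "character"))

setValidity("FlipMatrix", function(object) {
  np <- ncol(object@values)
  if (nrow(object@values) != object@grid@n)
    return("values must have one row per grid element")
  if (length(object@phases) != np || length(object@centers) != np ||
      length(object@acquired) != np)
    return("phases, centers and acquired must have one entry per pulse")
  TRUE
})

setMethod("show", "FlipMatrix", function(object) {
  cat(sprintf("FlipMatrix (%s): %d grid elements x %d pulses, peak flip %.3g deg\n",
              object@sequence, nrow(object@values), ncol(object@values),
              max(abs(object@values))))
  cat(sprintf("  dz = %g mm, deltaZ = %g mm, centres %.3g..%.3g mm, %d acquired pulses\n",
              object@grid@dz, object@deltaZ, object@centers[1],
              object@centers[length(object@centers)], sum(object@acquired)))
})

#' Signal matrix S(z, t)
#'
#' Complex demodulated transverse signal fraction S/M0 per grid element per
#' pulse.
#'
#' @slot values complex matrix [grid element, pulse]
#' @slot grid the \linkS4class{SpatialGrid}
#' @slot tr repetition time, ms
#' @export
setClass("SignalMatrix", representation(values = "matrix", grid = "SpatialGrid",
                                        tr = "numeric"))

setValidity("SignalMatrix", function(object) {
  if (nrow(object@values) != object@grid@n)
    return("values must have one row per grid element")
  if (!is.complex(object@values)) return("values must be complex")
  TRUE
})

setMethod("show", "SignalMatrix", function(object) {
  cat(sprintf("SignalMatrix: %d grid elements x %d pulses, max |S|/M0 = %.4g\n",
              nrow(object@values), ncol(object@values), max(Mod(object@values))))
})

#' Signal values accessor
#' @param sm a \linkS4class{SignalMatrix}
#' @return complex matrix [grid element, pulse]
#' @export
signalValues <- function(sm) sm@values

#' Flip values accessor
#' @param fm a \linkS4class{FlipMatrix}
#' @return numeric matrix [grid element, pulse], degrees
#' @export
flipValues <- function(fm) fm@values

## ---------------------------------------------------------------------------
## MotionModel
## ---------------------------------------------------------------------------

#' Through-slice tissue motion model
#'
#' Kinds: \code{"none"}; \code{"respiration"} (sinusoidal displacement of
#' amplitude mm at frequency Hz, zero before \code{onsetPulse});
#' \code{"flow"} (constant velocity mm/s, signed relative to the sweep
#' direction); \code{"blips"} (sudden piecewise-constant displacement steps at
#' given pulse indices).
#'
#' @slot kind one of none/respiration/flow/blips
#' @slot amplitude respiration half-range, mm
#' @slot frequency respiration frequency, Hz
#' @slot velocity flow velocity, mm/s
#' @slot blipTimes pulse indices of sudden steps
#' @slot blipSizes step sizes, mm
#' @slot onsetPulse pulse index before which displacement is zero (1-based;
#'   displacement starts at this pulse)
#' @export
setClass("MotionModel", representation(kind = "character", amplitude = "numeric",
                                       frequency = "numeric", velocity = "numeric",
                                       blipTimes = "integer", blipSizes = "numeric",
                                       onsetPulse = "integer"))

setValidity("MotionModel", function(object) {
  if (!(object@kind %in% c("none", "respiration", "flow", "blips")))
    return(sprintf("unknown motion kind '%s'", object@kind))
  if (object@kind == "blips" && length(object@blipTimes) != length(object@blipSizes))
    return("blipTimes and blipSizes must have equal length")
  TRUE
})

#' @param kind motion kind
#' @param amplitude respiration half-range, mm (default 2: +/-2 mm excursion)
#' @param frequency respiration frequency, Hz (default 0.3)
#' @param velocity flow velocity, mm/s
#' @param blipTimes pulse indices of sudden displacement steps
#' @param blipSizes step sizes, mm (default 5 steps doubling from 0.5 mm)
#' @param onsetPulse first pulse with nonzero displacement (default 501: 500
#'   settling TRs precede motion)
#' @rdname MotionModel-class
#' @export
motionModel <- function(kind = c("none", "respiration", "flow", "blips"),
                        amplitude = 2, frequency = 0.3, velocity = 0,
                        blipTimes = integer(0),
                        blipSizes = 0.5 * 2^(seq_along(blipTimes) - 1),
                        onsetPulse = 501) {
  kind <- match.arg(kind)
  new("MotionModel", kind = kind, amplitude = amplitude, frequency = frequency,
      velocity = velocity, blipTimes = as.integer(blipTimes),
      blipSizes = blipSizes, onsetPulse = as.integer(onsetPulse))
}

## ---------------------------------------------------------------------------
## SliceStack
## ---------------------------------------------------------------------------

#' Dense 2D slice stack with per-slice metadata
#'
#' Images are stored [ny, nx, nSlices]; z positions must be strictly
#' increasing for a swept acquisition; timestamps are seconds from the start
#' of the acquisition.  \code{truthPhase} carries the generator's ground-truth
#' respiratory phase (radians) when the stack is synthetic, otherwise it is
#' empty.
#'
#' @slot images numeric array [ny, nx, nSlices]
#' @slot zMm per-slice centre position, mm
#' @slot tS per-slice timestamp, s
#' @slot truthPhase ground-truth respiratory phase, radians (may be empty)
#' @slot meta list of acquisition parameters (must include pixel_mm)
#' @export
setClass("SliceStack", representation(images = "array", zMm = "numeric",
                                      tS = "numeric", truthPhase = "numeric",
                                      meta = "list"))

setValidity("SliceStack", function(object) {
  d <- dim(object@images)
  if (length(d) != 3L) return("images must be a 3D array [ny, nx, nSlices]")
  ns <- d[3]
  if (length(object@zMm) != ns) return("zMm must have one entry per slice")
  if (length(object@tS) != ns) return("tS must have one entry per slice")
  if (length(object@truthPhase) > 0 && length(object@truthPhase) != ns)
    return("truthPhase must be empty or one entry per slice")
  if (any(!is.finite(object@zMm)) || any(!is.finite(object@tS)))
    return("zMm and tS must be finite")
  if (any(diff(object@zMm) <= 0))
    return("zMm must be strictly increasing for a swept stack")
  if (min(object@images) < 0) return("images must be non-negative")
  TRUE
})

setMethod("show", "SliceStack", function(object) {
  d <- dim(object@images)
  cat(sprintf("SliceStack: %d slices of %d x %d, z in [%.2f, %.2f] mm, %.1f s\n",
              d[3], d[1], d[2], object@zMm[1], object@zMm[d[3]],
              object@tS[d[3]] - object@tS[1]))
})

#' Number of slices in a stack
#' @param stack a \linkS4class{SliceStack}
#' @export
nSlices <- function(stack) dim(stack@images)[3]

#' Slice images accessor
#' @param stack a \linkS4class{SliceStack}
#' @return numeric array [ny, nx, nSlices]
#' @export
stackImages <- function(stack) stack@images

## ---------------------------------------------------------------------------
## RespSignal
## ---------------------------------------------------------------------------

#' Respiration surrogate signal
#'
#' Per-slice body area, detrended signal, local statistics and (after
#' binning) state labels.  Excluded slices have label NA.
#'
#' @slot rawArea mask pixel count per slice
#' @slot detrended area minus centred moving average
#' @slot stateLabel integer state 1..nStates, NA for excluded slices
#' @slot excluded logical per slice
#' @slot localMean local mean of the detrended signal
#' @slot localSd local standard deviation of the detrended signal
#' @slot nStates number of respiratory states (0 before binning)
#' @export
setClass("RespSignal", representation(rawArea = "numeric", detrended = "numeric",
                                      stateLabel = "integer", excluded = "logical",
                                      localMean = "numeric", localSd = "numeric",
                                      nStates = "integer"))

setValidity("RespSignal", function(object) {
  n <- length(object@rawArea)
  if (length(object@detrended) != n) return("detrended must match rawArea length")
  if (length(object@stateLabel) != n || length(object@excluded) != n)
    return("stateLabel and excluded must match rawArea length")
  if (any(!is.na(object@stateLabel[object@excluded])))
    return("excluded slices must carry no state label")
  TRUE
})

setMethod("show", "RespSignal", function(object) {
  cat(sprintf("RespSignal: %d slices, %d states, %d excluded\n",
              length(object@rawArea), object@nStates, sum(object@excluded)))
})

#' State labels accessor
#' @param sig a \linkS4class{RespSignal}
#' @return integer vector, NA for excluded slices
#' @export
stateLabels <- function(sig) sig@stateLabel

#' Detrended respiration signal accessor
#' @param sig a \linkS4class{RespSignal}
#' @export
detrendedSignal <- function(sig) sig@detrended

## ---------------------------------------------------------------------------
## Volume4D
## ---------------------------------------------------------------------------

#' Respiration-resolved 4D volume
#'
#' One isotropic 3D volume per respiratory state; voxels outside a state's
#' z hull are NA.
#'
#' @slot values numeric array [ny, nx, nz, nStates], NA where not covered
#' @slot voxelMm isotropic voxel spacing, mm
#' @slot zMm output z grid, mm
#' @slot stateCenters representative detrended respiration value per state
#' @export
setClass("Volume4D", representation(values = "array", voxelMm = "numeric",
                                    zMm = "numeric", stateCenters = "numeric"))

setValidity("Volume4D", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L) return("values must be [ny, nx, nz, nStates]")
  if (length(object@zMm) != d[3]) return("zMm must match the z dimension")
  if (length(object@stateCenters) != d[4])
    return("stateCenters must match the state dimension")
  TRUE
})

setMethod("show", "Volume4D", function(object) {
  d <- dim(object@values)
  cat(sprintf("Volume4D: %d states of %d x %d x %d at %g mm, %.1f%% voxels missing\n",
              d[4], d[1], d[2], d[3], object@voxelMm,
              100 * mean(is.na(object@values))))
})

#' Fraction of missing (uncovered) voxels in a 4D volume
#' @param vol a \linkS4class{Volume4D}
#' @export
missingFraction <- function(vol) mean(is.na(vol@values))

## ---------------------------------------------------------------------------
## PhantomParams
## ---------------------------------------------------------------------------

#' Breathing-phantom generator parameters
#'
#' Defaults emulate a dense swept abdominal acquisition: 550 slices at about
#' 0.44 s per slice with 0.3 Hz sinusoidal respiration of +/-2 mm anterior
#' wall excursion, slice centres advancing by rs/100 * thickness * npe per
#' slice, and additive Gaussian noise at SNR 20 relative to the body
#' intensity.
#'
#' @slot bodySemiaxes ellipse semi-axes (x, y) at the volume centre, mm
#' @slot respAmplitude anterior wall excursion half-range, mm
#' @slot respFreq respiratory frequency, Hz
#' @slot sliceThickness nominal slice thickness, mm
#' @slot rs sweep rate, percent per TR
#' @slot npe phase encodes per slice (sets the per-slice z step)
#' @slot trSlice time per slice, s
#' @slot nSlices number of slices
#' @slot inPlaneMatrix in-plane matrix size, pixels
#' @slot pixelMm in-plane pixel spacing, mm
#' @slot noiseSd additive Gaussian noise SD (body intensity is 1)
#' @slot seed RNG seed
#' @export
setClass("PhantomParams", representation(bodySemiaxes = "numeric",
                                         respAmplitude = "numeric",
                                         respFreq = "numeric",
                                         sliceThickness = "numeric",
                                         rs = "numeric", npe = "integer",
                                         trSlice = "numeric", nSlices = "integer",
                                         inPlaneMatrix = "integer",
                                         pixelMm = "numeric", noiseSd = "numeric",
                                         seed = "integer"))

setValidity("PhantomParams", function(object) {
  if (object@nSlices < 20L) return("need at least 20 slices")
  if (1 / object@respFreq <= 2 * object@trSlice)
    return("respiration period must exceed 2 x trSlice to be resolvable")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (length(object@bodySemiaxes) != 2L) return("bodySemiaxes must be length 2")
  TRUE
})

#' @param bodySemiaxes ellipse semi-axes (x, y), mm
#' @param respAmplitude anterior wall excursion, mm
#' @param respFreq respiratory frequency, Hz
#' @param sliceThickness nominal thickness, mm
#' @param rs sweep rate, percent
#' @param npe phase encodes per slice
#' @param trSlice time per slice, s
#' @param nSlices number of slices
#' @param inPlaneMatrix in-plane matrix size, pixels
#' @param pixelMm pixel spacing, mm
#' @param noiseSd noise SD (body intensity 1)
#' @param seed RNG seed
#' @rdname PhantomParams-class
#' @export
phantomParams <- function(bodySemiaxes = c(60, 45), respAmplitude = 2,
                          respFreq = 0.3, sliceThickness = 4, rs = 0.17,
                          npe = 60, trSlice = 0.44, nSlices = 550,
                          inPlaneMatrix = 128, pixelMm = 1.25,
                          noiseSd = 0.05, seed = 1L) {
  new("PhantomParams", bodySemiaxes = bodySemiaxes, respAmplitude = respAmplitude,
      respFreq = respFreq, sliceThickness = sliceThickness, rs = rs,
      npe = as.integer(npe), trSlice = trSlice, nSlices = as.integer(nSlices),
      inPlaneMatrix = as.integer(inPlaneMatrix), pixelMm = pixelMm,
      noiseSd = noiseSd, seed = as.integer(seed))
}
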
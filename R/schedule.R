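## Sweep scheduling: the scalar relations of slice-select excitation
## (frequency/position, sweep rate, effective thickness), slice-centre
## trajectories for the four acquisition orderings, and construction of the
## flip-angle matrix F(z, t).

#' Slice-select excitation frequency
#'
#' nu(z) = gamma (B0 + Gss z): the RF frequency exciting position z under a
#' slice-select gradient Gss.  Units: gamma in MHz/T, B0 in T, Gss in mT/m,
#' z in mm; the result is in Hz.
#'
#' @param z position, mm
#' @param gss slice-select gradient, mT/m
#' @param b0 main field, T
#' @param gamma gyromagnetic ratio, MHz/T (default 42.577 for protons)
#' @return excitation frequency, Hz
#' @examples
#' excitationFrequency(1, gss = 10) - excitationFrequency(0, gss = 10) # 425.77 Hz
#' @export
excitationFrequency <- function(z, gss, b0 = 3, gamma = 42.577) {
  # gamma[MHz/T] * 1e6 * (B0[T] + Gss[mT/m] * 1e-3 * z[mm] * 1e-3)
  gamma * 1e6 * (b0 + gss * 1e-3 * z * 1e-3)
}

#' Effective swept slice thickness
#'
#' The nominal FWHM thickness plus the distance the profile travels during
#' one slice's phase encodes: delta_z * (1 + rs/100 * npe), equivalent to
#' delta_z + v_ex * npe * TR with v_ex = (rs/100) * delta_z / TR.
#'
#' @param deltaZ nominal FWHM slice thickness, mm
#' @param rs sweep rate, percent of deltaZ per TR
#' @param npe phase encodes per slice
#' @return effective thickness, mm
#' @examples
#' effectiveThickness(3.0, 0.05, 64)   # 3.096 mm
#' effectiveThickness(4.0, 0.17, 60)   # 4.408 mm
#' @export
effectiveThickness <- function(deltaZ, rs, npe) {
  stopifnot(rs >= 0, npe >= 1)
  deltaZ * (1 + (rs / 100) * npe)
}

#' Phase encodes per slice from printed protocol parameters
#'
#' Scanner protocols rarely print the acquired phase-encode count directly.
#' \code{npeFromAcceleration} derives it from the matrix size, partial-Fourier
#' factor and parallel-imaging (SENSE) factor; \code{npeFromDuration} from the
#' total acquisition duration, slice count and TR.
#'
#' @param matrixSize phase-encode matrix size
#' @param partialFourier partial-Fourier factor (e.g. 0.6)
#' @param sense SENSE acceleration factor
#' @return phase encodes per slice (rounded to an integer)
#' @examples
#' npeFromAcceleration(320, 0.6, 3)     # 64
#' npeFromDuration(240, 550, 7.3)       # 60
#' @export
npeFromAcceleration <- function(matrixSize, partialFourier = 1, sense = 1) {
  round(matrixSize * partialFourier / sense)
}

#' @param durationS total acquisition duration, s
#' @param nSlices number of slices
#' @param trMs repetition time, ms
#' @rdname npeFromAcceleration
#' @export
npeFromDuration <- function(durationS, nSlices, trMs) {
  round(durationS / (nSlices * trMs * 1e-3))
}

#' Tissue shared between adjacent swept slices
#'
#' Two consecutive slices of a swept acquisition are offset by the travel
#' during one slice, (rs/100) * deltaZ * npe, while each covers the effective
#' thickness; the shared fraction of excited tissue is the overlap divided by
#' the effective thickness.
#'
#' @inheritParams effectiveThickness
#' @return shared tissue, percent
#' @examples
#' adjacentSliceSharing(3.0, 0.05, 64)  # about 96.9 percent
#' @export
adjacentSliceSharing <- function(deltaZ, rs, npe) {
  travel <- (rs / 100) * deltaZ * npe
  100 * deltaZ / (deltaZ + travel)
}

#' Slice-centre positions per pulse
#'
#' Returns the centre-position trajectory (mm, starting at 0) and per-pulse
#' bookkeeping for an acquisition ordering.  The sweep scheme advances by
#' delta_z * rs/100 every pulse; M2D schemes hold each slice for
#' \code{startupPulses + npe} pulses.  The dense_ascending scheme spaces its
#' nSlices x nDynamics steps to span the same total travel as the equivalent
#' sweep; interleaved and ascending_dynamics space slices by
#' \code{sliceSpacing} nominal thicknesses.
#'
#' @param params a \linkS4class{SweepParams}
#' @param deltaZ nominal FWHM slice thickness, mm
#' @return list with \code{centers} (mm per pulse), \code{acquired} (logical
#'   per pulse), \code{sliceStart} (logical, TRUE at the first pulse of each
#'   slice) and \code{nPulses}
#' @export
centerPositions <- function(params, deltaZ) {
  dzStep <- (params@rs / 100) * deltaZ
  nAcq <- params@nSlices * params@nDynamics * params@npe
  if (params@scheme == "sweep") {
    centers <- (seq_len(nAcq) - 1) * dzStep
    return(list(centers = centers, acquired = rep(TRUE, nAcq),
                sliceStart = c(TRUE, rep(FALSE, nAcq - 1)), nPulses = nAcq))
  }
  # M2D schemes: per-slice blocks of startup + npe pulses
  blockLen <- params@startupPulses + params@npe
  positions <- switch(params@scheme,
    dense_ascending = {
      nSteps <- params@nSlices * params@nDynamics
      travel <- dzStep * (nAcq - 1)          # equal coverage with the sweep
      if (nSteps > 1) (seq_len(nSteps) - 1) * travel / (nSteps - 1) else 0
    },
    ascending_dynamics = {
      pos <- (seq_len(params@nSlices) - 1) * params@sliceSpacing * deltaZ
      # each slice's dynamics are contiguous; the slice position repeats but
      # a new transient only starts when the position changes, so dynamics
      # of one slice form a single block of nDynamics * npe acquired pulses
      pos
    },
    interleaved = {
      pos <- (seq_len(params@nSlices) - 1) * params@sliceSpacing * deltaZ
      rep(pos, times = params@nDynamics)     # all slices once, then repeat
    },
    stop(sprintf("unknown scheme '%s'", params@scheme)))

  perBlockAcq <- switch(params@scheme,
    ascending_dynamics = params@npe * params@nDynamics,
    params@npe)
  centers <- c(); acquired <- c(); sliceStart <- c()
  for (p in positions) {
    nb <- params@startupPulses + perBlockAcq
    centers <- c(centers, rep(p, nb))
    acquired <- c(acquired, rep(c(FALSE, TRUE),
                                c(params@startupPulses, perBlockAcq)))
    sliceStart <- c(sliceStart, TRUE, rep(FALSE, nb - 1))
  }
  if (sum(acquired) != nAcq)
    stop("inconsistent pulse count: nPulses must equal npe * nSlices * nDynamics")
  list(centers = centers, acquired = acquired, sliceStart = sliceStart,
       nPulses = length(centers))
}

#' Choose a simulation grid for a swept acquisition
#'
#' Picks the finest spacing not exceeding deltaZ/80 such that the per-pulse
#' sweep step is an exact integer number of cells, and sizes the grid to the
#' total sweep travel plus an 8 x deltaZ margin plus any motion excursion.
#'
#' @param deltaZ nominal FWHM slice thickness, mm
#' @param rs sweep rate, percent
#' @param nPulses total pulses
#' @param motionMargin largest through-slice displacement magnitude, mm
#' @return a \linkS4class{SpatialGrid}
#' @export
studyGrid <- function(deltaZ, rs, nPulses, motionMargin = 0) {
  target <- deltaZ / 80
  if (rs > 0) {
    step <- (rs / 100) * deltaZ
    dz <- if (step >= target) step / ceiling(step / target) else step
    travel <- step * (nPulses - 1)
  } else {
    dz <- target
    travel <- 0
  }
  extent <- travel + 8 * deltaZ + 2 * motionMargin
  spatialGrid(z0 = 0, dz = dz, n = ceiling(extent / dz) + 1)
}

#' Build the flip-angle matrix F(z, t)
#'
#' Column t is the single-pulse flip profile translated to the slice-centre
#' position of pulse t (an exact integer-cell shift of one evaluated profile).
#' M2D slices are prepended with startup pulses; bSSFP M2D slices start with
#' a half-alpha catalyzation pulse and restart their {0,180} phase
#' alternation, while SPGR uses a continuous quadratic 150-degree RF-spoiling
#' schedule.
#'
#' @param pulse a \linkS4class{PulseSpec}
#' @param params a \linkS4class{SweepParams}
#' @param grid a \linkS4class{SpatialGrid}, or NULL to build one with
#'   \code{studyGrid}
#' @param motionMargin extra margin reserved for through-slice motion, mm
#' @param centerStart z of the first slice centre; defaults to 4 thicknesses
#'   plus the motion margin above the grid origin
#' @return a \linkS4class{FlipMatrix}
#' @export
buildFlipMatrix <- function(pulse, params, grid = NULL, motionMargin = 0,
                            centerStart = NULL) {
  th <- pulse@nominalThickness
  cp <- centerPositions(params, th)
  if (is.null(grid)) {
    # size the grid from the actual centre span (M2D slice fans can exceed
    # the nominal sweep travel)
    span <- max(cp$centers) - min(cp$centers)
    dz <- studyGrid(th, params@rs, cp$nPulses, motionMargin)@dz
    extent <- span + 8 * th + 2 * motionMargin
    grid <- spatialGrid(z0 = 0, dz = dz, n = ceiling(extent / dz) + 1)
  }
  if (is.null(centerStart)) centerStart <- grid@z0 + 4 * th + motionMargin
  centers <- centerStart + cp$centers

  # integer-cell centre offsets (rounded; exact for grids from studyGrid)
  cellOff <- round((centers - grid@z0) / grid@dz)
  if (max(abs(cellOff * grid@dz + grid@z0 - centers)) > grid@dz / 2 + 1e-9)
    stop("sweep step not representable on this grid")
  centers <- grid@z0 + cellOff * grid@dz

  # base profile evaluated once on a compact window around a reference centre
  supCells <- ceiling(2 * th / grid@dz)
  refCell <- supCells                         # reference centre cell index
  refGrid <- spatialGrid(grid@z0, grid@dz, 2 * supCells + 1)
  baseProf <- flipProfile(pulse, refGrid, grid@z0 + refCell * grid@dz)

  np <- cp$nPulses
  vals <- matrix(0, nrow = grid@n, ncol = np)
  for (t in seq_len(np)) {
    lo <- cellOff[t] - supCells + 1L          # 1-based rows of the footprint
    hi <- cellOff[t] + supCells + 1L
    if (lo < 1L || hi > grid@n)
      stop("grid does not accommodate the sweep travel plus margin")
    vals[lo:hi, t] <- baseProf
  }

  # RF phases and catalyzation
  flipsScale <- rep(1, np)
  if (params@sequence == "bssfp") {
    phases <- numeric(np)
    blockStarts <- which(cp$sliceStart)
    bounds <- c(blockStarts, np + 1L)
    for (b in seq_along(blockStarts)) {
      idx <- blockStarts[b]:(bounds[b + 1] - 1L)
      phases[idx] <- rep(c(0, 180), length.out = length(idx))
    }
    if (params@scheme != "sweep" && params@startupPulses > 0L)
      flipsScale[blockStarts] <- 0.5          # half-alpha catalyzation pulse
  } else {
    phases <- defaultPhases(np, "spgr")
  }
  vals <- sweep(vals, 2, flipsScale, "*")

  new("FlipMatrix", values = vals, phases = phases, grid = grid,
      centers = centers, acquired = cp$acquired, deltaZ = th,
      tr = params@tr, sequence = params@sequence)
}
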
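## Slice-profile construction: small-tip Fourier transform of an apodized
## (and optionally one-side truncated) sinc-Gauss RF envelope, rescaled so the
## profile FWHM equals the nominal slice thickness and the peak equals the
## nominal flip angle.

# Dimensionless profile shape for a pulse spec: evaluates the envelope on a
# fine time grid, Fourier transforms it, and returns a function of
# u = (z - center)/thickness normalized to peak 1 and FWHM 1.  Cached per
# (shape, timeBandwidth) since the shape is flip- and thickness-invariant.
profileShapeCache <- new.env(parent = emptyenv())

profileShape <- function(shape, tbw) {
  key <- paste(shape, format(tbw, digits = 12), sep = "|")
  if (!is.null(profileShapeCache[[key]])) return(profileShapeCache[[key]])

  nt <- 1025L
  tt <- seq(-0.5, 0.5, length.out = nt)               # unit pulse duration
  env <- sinc(tbw * tt) * exp(-(2.5 * tt)^2)          # apodized sinc
  if (shape == "sinc_gauss_asymmetric") {
    # one-sided truncation of the trailing envelope, with a short cosine
    # roll-off (vendor short-TE pulses cut the refocusing half smoothly)
    ramp <- rep(1, nt)
    ramp[tt > 0.25] <- 0
    sel <- tt > 0.15 & tt <= 0.25
    ramp[sel] <- 0.5 * (1 + cos(pi * (tt[sel] - 0.15) / 0.1))
    env <- env * ramp
  }
  # small-tip profile = Fourier transform of the envelope; placing the
  # envelope circularly about index 0 keeps a symmetric envelope's spectrum
  # exactly real (no phase-correction artifacts)
  pad <- 32768L
  vec <- numeric(pad)
  vec[((seq_len(nt) - (nt + 1L) %/% 2L) %% pad) + 1L] <- env
  spec <- fft(vec)
  k <- 0:(pad - 1); k[k >= pad / 2] <- k[k >= pad / 2] - pad
  ord <- order(k)
  prof <- if (shape == "sinc_gauss_asymmetric") Mod(spec[ord]) else Re(spec[ord])
  prof <- prof / max(prof)
  u <- k[ord] - k[ord][which.max(prof)]               # recentre on the peak
  fw <- fwhm1d(u, prof)
  u <- u / fw                                          # FWHM = 1 in u units
  # smooth support taper: the profile footprint is compact (zero beyond two
  # thicknesses from the centre) so excitations translate exactly on a grid
  taper <- rep(0, length(u))
  core <- abs(u) <= 1.7
  edge <- abs(u) > 1.7 & abs(u) < 2
  taper[core] <- 1
  taper[edge] <- 0.5 * (1 + cos(pi * (abs(u[edge]) - 1.7) / 0.3))
  fun <- stats::approxfun(u, prof * taper, yleft = 0, yright = 0)
  profileShapeCache[[key]] <- fun
  fun
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# FWHM of a sampled profile by linear interpolation at half of the peak.
fwhm1d <- function(x, y) {
  pk <- which.max(y)
  half <- y[pk] / 2
  iL <- pk
  while (iL > 1 && y[iL] > half) iL <- iL - 1
  iR <- pk
  while (iR < length(y) && y[iR] > half) iR <- iR + 1
  if (y[iL] > half || y[iR] > half) stop("profile does not fall to half maximum")
  xL <- x[iL] + (half - y[iL]) / (y[iL + 1] - y[iL]) * (x[iL + 1] - x[iL])
  xR <- x[iR - 1] + (half - y[iR - 1]) / (y[iR] - y[iR - 1]) * (x[iR] - x[iR - 1])
  xR - xL
}

#' Spatial flip-angle profile of a slice-selective pulse
#'
#' Evaluates the small-tip profile of the pulse on a spatial grid, centred at
#' \code{centerZ}: peak flip equals the nominal flip, profile FWHM equals the
#' nominal thickness (within one grid cell).  Values are clipped to zero
#' beyond two nominal thicknesses from the centre, where the apodized profile
#' has decayed to a negligible level; this gives every excitation a compact,
#' exactly translatable footprint.
#'
#' @param pulse a \linkS4class{PulseSpec}
#' @param grid a \linkS4class{SpatialGrid}; must span at least 4 nominal
#'   thicknesses around \code{centerZ} and resolve the thickness with at
#'   least 8 cells
#' @param centerZ slice centre, mm
#' @return numeric vector of flip angles per grid element, degrees
#' @export
flipProfile <- function(pulse, grid, centerZ) {
  dz <- grid@dz
  th <- pulse@nominalThickness
  if (th / dz < 8) stop("grid too coarse: need at least 8 cells per nominal thickness")
  z <- zValues(grid)
  if (centerZ - 2 * th < z[1] - dz / 2 || centerZ + 2 * th > z[grid@n] + dz / 2)
    stop("grid must span at least 4 nominal thicknesses around centerZ")
  u <- (z - centerZ) / th
  p <- profileShape(pulse@shape, pulse@timeBandwidth)(u)
  p[abs(u) > 2] <- 0
  pulse@nominalFlip * p
}
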
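# Shared small fixtures: tissues and pulse shapes used across test files.

muscleTissue <- function() tissue(1412, 50)      # skeletal muscle at 3T
bloodT <- function() tissue(1550, 275)           # arterial blood
greyT <- function() tissue(1820, 99)             # grey matter

bssfpPulse <- function(flip = 22, th = 4)
  pulseSpec("sinc_gauss_symmetric", nominalFlip = flip, nominalThickness = th)

spgrPulse <- function(flip = 70, th = 3)
  pulseSpec("sinc_gauss_asymmetric", nominalFlip = flip, nominalThickness = th)

# a small test phantom (fast to build and segment)
smallPhantom <- function(nSlices = 120, noiseSd = 0.05, seed = 7,
                         respAmplitude = 2)
  makePhantom(phantomParams(nSlices = nSlices, inPlaneMatrix = 64,
                            pixelMm = 2.5, noiseSd = noiseSd, seed = seed,
                            respAmplitude = respAmplitude))

# FWHM of a sampled curve (independent re-implementation for checking)
measureFwhm <- function(z, p) {
  pk <- which.max(p); h <- max(p) / 2
  iL <- pk; while (p[iL] > h) iL <- iL - 1
  iR <- pk; while (p[iR] > h) iR <- iR + 1
  dz <- z[2] - z[1]
  xR <- z[iR - 1] + (h - p[iR - 1]) / (p[iR] - p[iR - 1]) * dz
  xL <- z[iL] + (h - p[iL]) / (p[iL + 1] - p[iL]) * dz
  xR - xL
}
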
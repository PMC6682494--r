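## Synthetic breathing-abdomen phantom: a dense swept slice stack with
## ground-truth respiratory phase per slice, so the respiration-sorting
## pipeline can be exercised and validated without any acquisition.

#' Generate a breathing slice-stack phantom
#'
#' Each slice images an elliptical "body" cross-section on a regular pixel
#' grid.  Slice i is acquired at z_i = i * (rs/100) * thickness * npe (the
#' travel per slice of a swept acquisition) and t_i = i * trSlice.  The
#' anterior (+y) body wall is displaced by respAmplitude * sin(2 pi f t + phi0),
#' so the segmented body area is a monotone function of sin(phase); the body
#' semi-axes additionally vary slowly (low-order polynomial) along z to give
#' the detrending step realistic anatomical work.  Two bright vessel-like
#' tubes run through the body for qualitative 4D checks.  Gaussian noise of
#' the given SD is added and the result clipped at zero; everything is
#' reproducible from the seed.
#'
#' @param params a \linkS4class{PhantomParams}
#' @return a \linkS4class{SliceStack}; \code{meta} records the generator
#'   parameters and the noise-free ground-truth body area per slice
#'   (\code{truthArea})
#' @export
makePhantom <- function(params = phantomParams()) {
  validObject(params)
  set.seed(params@seed)
  n <- params@nSlices
  m <- params@inPlaneMatrix
  px <- params@pixelMm
  zStep <- (params@rs / 100) * params@sliceThickness * params@npe
  zMm <- (seq_len(n) - 1) * zStep
  tS <- (seq_len(n) - 1) * params@trSlice
  phi0 <- stats::runif(1, 0, 2 * pi)
  phase <- (2 * pi * params@respFreq * tS + phi0) %% (2 * pi)

  fov <- m * px
  xc <- fov / 2; yc <- fov / 2
  x <- (seq_len(m) - 0.5) * px
  y <- (seq_len(m) - 0.5) * px
  X <- matrix(x, m, m, byrow = TRUE)   # [y, x]
  Y <- matrix(y, m, m)

  zRel <- zMm / max(zMm[n], 1) - 0.5
  # slow anatomical variation of the body outline along z
  aZ <- params@bodySemiaxes[1] * (1 - 0.25 * zRel^2 + 0.10 * zRel)
  bZ <- params@bodySemiaxes[2] * (1 - 0.30 * zRel^2 - 0.08 * zRel)

  # vessel tubes: gently curving bright structures inside the body
  v1x <- xc + 12 * sin(2 * pi * zMm / max(zMm[n], 1) * 1.5)
  v1y <- yc - 8 + 6 * cos(2 * pi * zMm / max(zMm[n], 1))
  v2x <- xc - 18 + 5 * sin(2 * pi * zMm / max(zMm[n], 1) * 0.7)
  v2y <- yc + 5
  vr <- 3   # vessel radius, mm

  imgs <- array(0, dim = c(m, m, n))
  truthArea <- numeric(n)
  dResp <- params@respAmplitude * sin(phase)
  for (i in seq_len(n)) {
    bAnt <- bZ[i] + dResp[i]                 # anterior wall moves
    bPost <- bZ[i]
    inBody <- ifelse(Y >= yc,
                     ((X - xc) / aZ[i])^2 + ((Y - yc) / bAnt)^2 <= 1,
                     ((X - xc) / aZ[i])^2 + ((Y - yc) / bPost)^2 <= 1)
    img <- 0.0 + 1.0 * inBody
    img[( (X - v1x[i])^2 + (Y - v1y[i])^2 <= vr^2 ) & inBody] <- 2.0
    img[( (X - v2x[i])^2 + (Y - v2y[i])^2 <= vr^2 ) & inBody] <- 2.0
    truthArea[i] <- pi * aZ[i] * (bAnt + bPost) / 2 / px^2   # pixels
    imgs[, , i] <- img
  }
  if (params@noiseSd > 0) {
    imgs <- imgs + stats::rnorm(length(imgs), 0, params@noiseSd)
    imgs[imgs < 0] <- 0
  }
  meta <- list(pixel_mm = px, tr_slice = params@trSlice,
               slice_thickness = params@sliceThickness, rs = params@rs,
               npe = params@npe, resp_freq = params@respFreq,
               resp_amplitude = params@respAmplitude, seed = params@seed,
               body_semiaxes = params@bodySemiaxes, noise_sd = params@noiseSd,
               truthArea = truthArea,
               bodyCenter = c(xc, yc), aZ = aZ, bZ = bZ)
  new("SliceStack", images = imgs, zMm = zMm, tS = tS,
      truthPhase = phase, meta = meta)
}
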
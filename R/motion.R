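## Through-slice motion: displacement series for respiration, flow and sudden
## blips, and their application to a flip matrix by integer-cell translation
## of each column (tissue-frame convention: the matrix rows index material
## tissue elements, so tissue displaced by d sees the excitation shifted by
## -d in its own frame).

#' Through-slice displacement per pulse
#'
#' Respiration: d(t) = amplitude * sin(2 pi f t) starting at the onset pulse
#' (zero before).  Flow: d(t) = velocity * t.  Blips: cumulative
#' piecewise-constant steps at the given pulse indices.  Time of pulse i is
#' (i - onset) * TR for respiration and (i - 1) * TR for flow.
#'
#' @param model a \linkS4class{MotionModel}
#' @param nPulses number of pulses
#' @param tr repetition time, ms
#' @return numeric vector of displacements, mm
#' @export
displacementSeries <- function(model, nPulses, tr) {
  stopifnot(nPulses >= 1)
  i <- seq_len(nPulses)
  switch(model@kind,
    none = rep(0, nPulses),
    respiration = {
      tSec <- (i - model@onsetPulse) * tr * 1e-3
      d <- model@amplitude * sin(2 * pi * model@frequency * tSec)
      d[i < model@onsetPulse] <- 0
      d
    },
    flow = model@velocity * (i - 1) * tr * 1e-3,
    blips = {
      d <- rep(0, nPulses)
      for (j in seq_along(model@blipTimes))
        d[i >= model@blipTimes[j]] <- d[i >= model@blipTimes[j]] + model@blipSizes[j]
      d
    },
    stop(sprintf("unknown motion kind '%s'", model@kind)))
}

#' Apply a displacement series to a flip matrix
#'
#' Column t of the output is column t of the input sampled at z + d(t):
#' positive displacement moves the tissue in the sweep direction, so in the
#' material frame the excitation pattern appears shifted by -d(t).
#' Displacements are rounded to the nearest integer grid cell; the largest
#' rounding residual is recorded in the \code{"roundingResidualMm"} attribute
#' of the returned object's values.  An error is raised if any shifted
#' excitation footprint would leave the grid.
#'
#' @param fm a \linkS4class{FlipMatrix}
#' @param d displacement per pulse, mm (length = number of pulses)
#' @return a \linkS4class{FlipMatrix} with shifted columns; slice centres are
#'   unchanged (they track the excitation in the laboratory frame)
#' @export
applyMotion <- function(fm, d) {
  np <- ncol(fm@values)
  if (length(d) != np)
    stop("displacement series length must equal the number of pulses")
  dz <- fm@grid@dz
  cells <- round(d / dz)
  resid <- max(abs(d - cells * dz))

  # nonzero footprint of column t spans centre +/- 2 deltaZ; require the
  # shifted footprint to stay on the grid
  sup <- 2 * fm@deltaZ
  zLo <- fm@grid@z0
  zHi <- fm@grid@z0 + (fm@grid@n - 1) * dz
  shiftedLo <- fm@centers - sup - cells * dz  # footprint in material frame
  shiftedHi <- fm@centers + sup - cells * dz
  if (any(shiftedLo < zLo - 1e-9) || any(shiftedHi > zHi + 1e-9))
    stop("displacement exceeds the grid margin")

  vals <- fm@values
  n <- fm@grid@n
  for (t in seq_len(np)) {
    k <- cells[t]
    if (k == 0) next
    col <- vals[, t]
    newCol <- numeric(n)
    # out[i] = in[i + k]  (sample at z + d)
    src <- seq_len(n) + k
    ok <- src >= 1L & src <= n
    newCol[ok] <- col[src[ok]]
    vals[, t] <- newCol
  }
  attr(vals, "roundingResidualMm") <- resid
  out <- fm
  out@values <- vals
  out
}
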
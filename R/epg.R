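## Extended-phase-graph core: RF rotation and relaxation/shift operators on an
## explicit EPGState (reference implementation, used for unit-level reasoning
## and cross-checks), a train simulator backed by the compiled engine, and an
## independent isochromat Bloch simulator used as a numerical oracle.

#' Apply an RF rotation to an EPG state
#'
#' Mixes (F_k, conj(F_-k), Z_k) for every configuration order k with the
#' standard EPG rotation operator for the given flip angle and RF phase.  The
#' operator preserves |F+_k|^2 + |F-_k|^2 + 2|Z_k|^2 for each k (no RF pulse
#' creates magnetization).
#'
#' @param state an \linkS4class{EPGState}
#' @param flip flip angle, degrees
#' @param phase RF phase, degrees
#' @return the rotated \linkS4class{EPGState}
#' @examples
#' s <- rfRotation(equilibriumState(), flip = 90, phase = 0)
#' Mod(s@fplus[1])  # 1: full excitation
#' @export
rfRotation <- function(state, flip, phase = 0) {
  a <- flip * pi / 180
  p <- phase * pi / 180
  if (a == 0) return(state)
  eip <- exp(1i * p)
  ca <- cos(a); sa <- sin(a)
  c2s <- cos(a / 2)^2; s2s <- sin(a / 2)^2
  T11 <- c2s;             T12 <- eip^2 * s2s;      T13 <- -1i * eip * sa
  T21 <- Conj(T12);       T22 <- c2s;              T23 <- 1i * Conj(eip) * sa
  T31 <- -0.5i * Conj(eip) * sa; T32 <- 0.5i * eip * sa; T33 <- ca
  fp <- state@fplus; fm <- state@fminus; zk <- state@zk
  new("EPGState",
      fplus  = T11 * fp + T12 * fm + T13 * zk,
      fminus = T21 * fp + T22 * fm + T23 * zk,
      zk     = T31 * fp + T32 * fm + T33 * zk,
      m0     = state@m0)
}

#' Relaxation (and optional configuration shift) over an interval
#'
#' Scales transverse amplitudes by E2 = exp(-t/T2) and longitudinal ones by
#' E1 = exp(-t/T1) with Z_0 recovering toward m0.  With \code{doShift = TRUE}
#' (spoiled sequences) the transverse states are advanced one configuration
#' order: F_k -> F_{k+1}; the order beyond kmax is discarded.
#'
#' @param state an \linkS4class{EPGState}
#' @param tissue a \linkS4class{Tissue}
#' @param duration interval, ms (must be >= 0)
#' @param doShift apply the unit k-shift of a spoiler gradient
#' @return the evolved \linkS4class{EPGState}
#' @export
relaxAndShift <- function(state, tissue, duration, doShift = FALSE) {
  if (duration < 0) stop("duration must be >= 0")
  e1 <- exp(-duration / tissue@t1)
  e2 <- exp(-duration / tissue@t2)
  fp <- state@fplus * e2
  fm <- state@fminus * e2
  zk <- state@zk * e1
  zk[1] <- zk[1] + state@m0 * (1 - e1)
  if (doShift) {
    n <- length(fp)
    fpNew <- c(if (n >= 2) Conj(fm[2]) else 0 + 0i, fp[-n])
    fmNew <- c(fm[-1], 0 + 0i)
    fmNew[1] <- Conj(fpNew[1])
    fp <- fpNew; fm <- fmNew
  }
  new("EPGState", fplus = fp, fminus = fm, zk = zk, m0 = state@m0)
}

#' Weighted state norm preserved by RF rotations
#'
#' sum_k |F+_k|^2 + |F-_k|^2 + 2 |Z_k|^2, invariant under \code{rfRotation}
#' and non-increasing under relaxation (up to Z_0 recovery toward m0).
#'
#' @param state an \linkS4class{EPGState}
#' @export
stateNorm <- function(state) {
  sum(Mod(state@fplus)^2 + Mod(state@fminus)^2 + 2 * Mod(state@zk)^2)
}

#' Simulate an RF pulse train with the EPG engine
#'
#' Runs the per-TR cycle (RF rotation, demodulated F_0 echo at TE, relaxation
#' over TR, unit k-shift for spoiled sequences) and returns one complex signal
#' sample per pulse: F_0 after excitation, decayed to TE, with the RF phase
#' removed.
#'
#' @param train a \linkS4class{PulseTrain}
#' @param tissue a \linkS4class{Tissue}
#' @param kmax maximum configuration order retained; defaults to the train
#'   length capped at 100 (exact for short trains, bounded memory for long
#'   ones).  \code{kmax = 0} for a spoiled train is the ideal-spoiling limit:
#'   all transverse coherence is discarded each TR.
#' @return complex vector of demodulated signal samples (units of M0 when
#'   m0 = 1)
#' @examples
#' tr <- pulseTrain(22, tr = 6, kind = "bssfp", n = 500)
#' s <- simulateTrain(tr, tissue(1412, 50))
#' Mod(s[500])
#' @export
simulateTrain <- function(train, tissue, kmax = min(length(train@flips), 100L)) {
  shift <- train@kind == "spgr"
  fl <- matrix(train@flips, nrow = 1)
  s <- epg_engine_cpp(fl, train@phases,
                      e1 = exp(-train@tr / tissue@t1),
                      e2 = exp(-train@tr / tissue@t2),
                      e2te = exp(-train@te / tissue@t2),
                      m0 = tissue@m0, shift = shift, kmax = as.integer(kmax))
  as.vector(s)
}

#' Isochromat Bloch simulation of a pulse train (numerical oracle)
#'
#' Independent brute-force route: each isochromat is a 3-vector rotated by the
#' Rodrigues rotation matrix of every RF pulse (axis in the transverse plane
#' at the RF phase angle), relaxed over each TR, and -- for spoiled sequences
#' -- dephased by a per-TR gradient angle spread uniformly over the ensemble.
#' Balanced sequences use a single on-resonance isochromat.  The demodulated
#' mean transverse component reproduces the EPG F_0 signal.
#'
#' @param train a \linkS4class{PulseTrain}
#' @param tissue a \linkS4class{Tissue}
#' @param nSpins ensemble size for spoiled sequences (ignored for balanced)
#' @return complex vector, one demodulated sample per pulse
#' @export
blochTrain <- function(train, tissue, nSpins = 2000) {
  n <- length(train@flips)
  spoiled <- train@kind == "spgr"
  ns <- if (spoiled) nSpins else 1L
  theta <- if (spoiled) 2 * pi * (seq_len(ns) - 0.5) / ns else 0
  e1 <- exp(-train@tr / tissue@t1)
  e2 <- exp(-train@tr / tissue@t2)
  e2te <- exp(-train@te / tissue@t2)
  mx <- rep(0, ns); my <- rep(0, ns); mz <- rep(tissue@m0, ns)
  out <- complex(length.out = n)
  for (j in seq_len(n)) {
    a <- train@flips[j] * pi / 180
    p <- train@phases[j] * pi / 180
    if (a != 0) {
      # rotation about axis (cos p, sin p, 0) by angle a (Rodrigues)
      ux <- cos(p); uy <- sin(p)
      ca <- cos(a); sa <- sin(a); vc <- 1 - ca
      r11 <- ca + ux * ux * vc; r12 <- ux * uy * vc;      r13 <- uy * sa
      r21 <- r12;               r22 <- ca + uy * uy * vc; r23 <- -ux * sa
      r31 <- -uy * sa;          r32 <- ux * sa;           r33 <- ca
      nx <- r11 * mx + r12 * my + r13 * mz
      ny <- r21 * mx + r22 * my + r23 * mz
      nz <- r31 * mx + r32 * my + r33 * mz
      mx <- nx; my <- ny; mz <- nz
    }
    out[j] <- mean(complex(real = mx, imaginary = my)) * e2te * exp(-1i * p)
    # relax over TR, then gradient dephasing for spoiled sequences
    mxy <- complex(real = mx, imaginary = my) * e2
    if (spoiled) mxy <- mxy * exp(1i * theta)
    mx <- Re(mxy); my <- Im(mxy)
    mz <- mz * e1 + tissue@m0 * (1 - e1)
  }
  out
}

#' Closed-form steady-state signals
#'
#' \code{ernstSignal} is the ideally spoiled gradient-echo steady state
#' m0 sin(a) (1 - E1) / (1 - E1 cos(a)); \code{bssfpSignal} the on-resonance
#' balanced steady state m0 sin(a) (1 - E1) / (1 - (E1 - E2) cos(a) - E1 E2).
#' Both are the magnitude immediately after the pulse; multiply by
#' exp(-TE/T2) to compare with echo-time signals.
#'
#' @param flip flip angle, degrees
#' @param tr repetition time, ms
#' @param tissue a \linkS4class{Tissue}
#' @return steady-state transverse magnitude
#' @export
ernstSignal <- function(flip, tr, tissue) {
  a <- flip * pi / 180
  e1 <- exp(-tr / tissue@t1)
  tissue@m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' @rdname ernstSignal
#' @export
bssfpSignal <- function(flip, tr, tissue) {
  a <- flip * pi / 180
  e1 <- exp(-tr / tissue@t1)
  e2 <- exp(-tr / tissue@t2)
  tissue@m0 * sin(a) * (1 - e1) / (1 - (e1 - e2) * cos(a) - e1 * e2)
}
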
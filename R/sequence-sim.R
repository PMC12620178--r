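#' @include AllClasses.R
NULL

#' Sampled echo indices and effective echo times of the dual-echo train
#'
#' The scanner nominally reports `te1`/`te2`, but on one echo train with
#' fixed spacing those times need not both fall on a train echo. The
#' convention here: each image is sampled at the train echo nearest its
#' nominal TE, the train is extended if needed, and the *effective* echo
#' times are what every fit in the package uses.
#'
#' @param params a [TSEParams-class].
#' @return list with `idx1`, `idx2` (echo indices), `te1Eff`, `te2Eff` (ms)
#'   and `nTrain` (number of simulated echoes).
#' @export
tseEchoIndices <- function(params) {
  stopifnot(is(params, "TSEParams"))
  esp <- params@echoSpacing
  idx1 <- max(1L, as.integer(round(params@te1 / esp)))
  idx2 <- max(1L, as.integer(round(params@te2 / esp)))
  if (idx1 == idx2) stop("te1 and te2 map to the same train echo")
  list(idx1 = idx1, idx2 = idx2,
       te1Eff = idx1 * esp, te2Eff = idx2 * esp,
       nTrain = max(params@turboFactor, idx1, idx2))
}

#' Vectorised EPG echo amplitudes (internal)
#'
#' @param t2,t1 ms; `b1` relative. Recycled to a common length.
#' @param params [TSEParams-class].
#' @param nEchoes echoes to simulate.
#' @return matrix `n x nEchoes` of amplitudes.
#' @keywords internal
.epgEchoAmps <- function(t2, t1, b1, params, nEchoes) {
  n <- max(length(t2), length(t1), length(b1))
  .epgEchoesCpp(rep_len(as.numeric(t2), n), rep_len(as.numeric(t1), n),
                rep_len(as.numeric(b1), n), params@echoSpacing,
                as.integer(nEchoes), params@nominalRefocusingDeg,
                params@excitationDeg)
}

#' EPG simulation of a turbo spin echo train
#'
#' Computes all spin-echo amplitudes of the train, including
#' stimulated-echo pathways, with instantaneous pulses whose flip angles
#' are the nominal angles scaled by `b1`. This is the reduced-fidelity
#' stand-in for full Bloch modelling of the vendor RF waveforms: it keeps
#' the stimulated-echo mechanism (the phenomenon under study) while
#' assuming an ideal slice profile.
#'
#' @param t2 transverse relaxation time, ms (> 0).
#' @param t1 longitudinal relaxation time, ms (>= t2); defaults to the
#'   `t1Assumed` of `params`.
#' @param b1 relative transmit field in `[0.1, 2]`.
#' @param params a [TSEParams-class].
#' @param nEchoes number of train echoes (default: the full sampled train).
#' @return An [EchoTrain-class].
#' @examples
#' tr <- epgTseEchoes(80, 1000, 1, TSEParams())
#' @export
epgTseEchoes <- function(t2, t1 = params@t1Assumed, b1 = 1,
                         params = TSEParams(), nEchoes = NULL) {
  stopifnot(length(t2) == 1L, length(b1) == 1L)
  if (t2 <= 0) stop("t2 must be > 0")
  if (t1 < t2) stop("non-physical t2/t1 ordering: need t1 >= t2")
  if (b1 < 0.1 || b1 > 2) stop("b1 must lie in [0.1, 2]")
  if (is.null(nEchoes)) nEchoes <- tseEchoIndices(params)$nTrain
  amps <- .epgEchoAmps(t2, t1, b1, params, nEchoes)[1, ]
  new("EchoTrain", echoTimes = params@echoSpacing * seq_len(nEchoes),
      amplitudes = amps)
}

#' Brute-force isochromat Bloch oracle for the TSE train
#'
#' Independent verification of [epgTseEchoes()]: explicit
#' rotation-relaxation evolution of `nIsochromats` spins whose gradient
#' dephasing uniformly spans one full cycle per crusher period (half echo
#' spacing), averaged at each echo. With a uniform discrete ensemble the
#' average is exact (no aliasing) as long as `nIsochromats` exceeds the
#' number of populated coherence orders, hence the lower bound.
#'
#' @inheritParams epgTseEchoes
#' @param nIsochromats number of isochromats (>= 200).
#' @return An [EchoTrain-class].
#' @export
blochOracle <- function(t2, t1 = params@t1Assumed, b1 = 1,
                        params = TSEParams(), nEchoes = NULL,
                        nIsochromats = 600L) {
  if (nIsochromats < 200L)
    stop("too few isochromats (aliasing risk): need >= 200")
  if (t2 <= 0 || t1 < t2) stop("non-physical t2/t1 ordering")
  if (is.null(nEchoes)) nEchoes <- tseEchoIndices(params)$nTrain
  esp <- params@echoSpacing
  th <- 2 * pi * (seq_len(nIsochromats) - 1) / nIsochromats
  e2 <- exp(-esp / 2 / t2); e1 <- exp(-esp / 2 / t1)
  rotx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  roty <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  cth <- cos(th); sth <- sin(th)
  prec <- function(M) {  # half-interval free precession + relaxation
    Mx <- M[1, ] * cth - M[2, ] * sth
    My <- M[1, ] * sth + M[2, ] * cth
    rbind(Mx * e2, My * e2, M[3, ] * e1 + (1 - e1))
  }
  M <- rbind(0, 0, rep(1, nIsochromats))
  M <- rotx(params@excitationDeg * pi / 180 * b1) %*% M
  Ry <- roty(params@nominalRefocusingDeg * pi / 180 * b1)
  amps <- numeric(nEchoes)
  for (e in seq_len(nEchoes)) {
    M <- prec(M); M <- Ry %*% M; M <- prec(M)
    amps[e] <- Mod(mean(M[1, ]) + 1i * mean(M[2, ]))
  }
  new("EchoTrain", echoTimes = esp * seq_len(nEchoes), amplitudes = amps)
}

#' Echo times of a MEGE acquisition
#'
#' @param params a [MEGEParams-class].
#' @return numeric vector of echo times, ms.
#' @export
megeEchoTimes <- function(params = MEGEParams()) {
  params@teFirst + params@echoSpacing * (seq_len(params@nEchoes) - 1)
}

#' Mono-exponential complex MEGE signal model
#'
#' `S(TE) = s0 * exp(-r2star * TE) * exp(i * 2 * pi * deltaF * TE)` at the
#' echo times of `params` (the model the R2* fit assumes).
#'
#' @param s0 initial magnitude (>= 0).
#' @param r2star effective transverse rate, Hz.
#' @param deltaF frequency shift, Hz.
#' @param params a [MEGEParams-class].
#' @return complex vector, one value per echo.
#' @examples
#' Mod(megeSignal(1, 20, 0)[1])  # exp(-20 Hz * 5 ms)
#' @export
megeSignal <- function(s0, r2star, deltaF, params = MEGEParams()) {
  if (s0 < 0) stop("s0 must be >= 0")
  te <- megeEchoTimes(params) / 1000  # s
  s0 * exp(-r2star * te) * exp(2i * pi * deltaF * te)
}
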
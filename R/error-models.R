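#' @include AllClasses.R relaxometry.R
NULL

#' Globally scale an R2 map
#'
#' Voxelwise multiplication by `factor`; the unit and mask are preserved.
#' Linear: `scaleR2Map(scaleR2Map(m, a), b)` equals `scaleR2Map(m, a * b)`.
#'
#' @param r2 a [ScalarVolume-class].
#' @param factor positive scale factor.
#' @return A [ScalarVolume-class].
#' @export
scaleR2Map <- function(r2, factor) {
  stopifnot(is(r2, "ScalarVolume"))
  if (!is.finite(factor) || factor <= 0) stop("factor must be > 0")
  ScalarVolume(r2@data * factor, voxelSize = r2@voxelSize, unit = r2@unit,
               mask = r2@mask)
}

#' The global R2 error series: 0.75 to 1.25 in 1 percent steps
#'
#' The identity factor 1.00 is excluded, yielding exactly 50 altered maps
#' (errors from -25 to +25 percent of the true value).
#'
#' @return numeric vector of 50 scale factors.
#' @export
enumerateErrorSeries <- function() {
  f <- round(seq(0.75, 1.25, by = 0.01), 2)
  f[f != 1]
}

#' Approximate R2 from R2* alone
#'
#' The acquisition-shortcut estimate used when no spin-echo data exist:
#' `R2 = 0.48 * R2*`, equivalently `R2' = 0.52 * R2*`. By construction
#' `R2 + R2'` reproduces `R2*` exactly and the downstream clipping in
#' [computeR2Prime()] can never trigger.
#'
#' @param r2star a [ScalarVolume-class] in Hz.
#' @param coefficient the R2 fraction of R2* (default 0.48).
#' @return A [ScalarVolume-class] of approximated R2 in Hz.
#' @export
r2FromR2Star <- function(r2star, coefficient = 0.48) {
  stopifnot(is(r2star, "ScalarVolume"))
  if (r2star@unit != "Hz") stop("r2star must be in Hz")
  ScalarVolume(r2star@data * coefficient, voxelSize = r2star@voxelSize,
               unit = "Hz", mask = r2star@mask)
}

#' Exponential-fit R2 as an error condition
#'
#' Delegates to [fitR2Exponential()]; exists so the sweep driver treats
#' the three R2 corruption schemes (global scaling, exponential fit,
#' R2*-based approximation) through one interface.
#'
#' @inheritParams fitR2Exponential
#' @return identical to the [fitR2Exponential()] output.
#' @export
exponentialSubstitute <- function(echo1, echo2, params = TSEParams(),
                                  noiseFloor = 0) {
  fitR2Exponential(echo1, echo2, params, noiseFloor)
}
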
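#' @include chisep-package.R
NULL

.volumeUnits <- c("Hz", "ppb", "ppm", "relative", "dimensionless")

#' ScalarVolume: a 3D scalar field with voxel geometry and a unit tag
#'
#' Carrier for all volumetric maps in the pipeline (R2, R2*, R2', B1+,
#' frequency shift, susceptibility components). Values inside the optional
#' mask must be finite; the unit tag is one of `"Hz"`, `"ppb"`, `"ppm"`,
#' `"relative"`, `"dimensionless"`.
#'
#' @slot data 3D numeric array.
#' @slot voxelSize numeric length-3, voxel edge lengths in mm (all > 0).
#' @slot unit character unit tag.
#' @slot mask `NULL` or a logical array congruent with `data`.
#' @exportClass ScalarVolume
setClass("ScalarVolume",
  representation(data = "array", voxelSize = "numeric", unit = "character",
                 mask = "ANY"),
  prototype(voxelSize = c(1, 1, 1), unit = "dimensionless", mask = NULL))

setValidity("ScalarVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3D array")
  if (any(d < 1L)) return("all three dimensions must be >= 1")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0)) return("voxel sizes must be positive")
  if (length(object@unit) != 1L || !object@unit %in% .volumeUnits)
    return(sprintf("unit must be one of: %s", paste(.volumeUnits, collapse = ", ")))
  if (!is.null(object@mask)) {
    if (!is.logical(object@mask) || !identical(dim(object@mask), d))
      return("mask must be a logical array congruent with data")
    if (any(!is.finite(object@data[object@mask])))
      return("values inside mask must be finite")
  } else if (any(!is.finite(object@data))) {
    return("unmasked volume must be finite everywhere")
  }
  TRUE
})

#' Construct a ScalarVolume
#'
#' @param data 3D numeric array.
#' @param voxelSize voxel edge lengths in mm.
#' @param unit unit tag.
#' @param mask optional logical array.
#' @return A [ScalarVolume-class] object.
#' @examples
#' v <- ScalarVolume(array(0, c(8, 8, 8)), c(1, 1, 2), "Hz")
#' @export
ScalarVolume <- function(data, voxelSize = c(1, 1, 1), unit = "dimensionless",
                         mask = NULL) {
  if (is.null(dim(data))) stop("data must be a 3D array")
  new("ScalarVolume", data = data, voxelSize = as.numeric(voxelSize),
      unit = unit, mask = mask)
}

#' AcquisitionGeometry: grid, B0 direction and imaging frequency
#'
#' @slot matrixSize integer length-3 grid size.
#' @slot voxelSize numeric length-3 voxel size in mm.
#' @slot b0Direction unit 3-vector of the main field direction.
#' @slot imagingFrequency Larmor frequency in Hz (> 0).
#' @exportClass AcquisitionGeometry
setClass("AcquisitionGeometry",
  representation(matrixSize = "integer", voxelSize = "numeric",
                 b0Direction = "numeric", imagingFrequency = "numeric"))

setValidity("AcquisitionGeometry", function(object) {
  if (length(object@matrixSize) != 3L || any(object@matrixSize < 1L))
    return("matrixSize must be 3 positive integers")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive numbers")
  if (length(object@b0Direction) != 3L ||
      abs(sqrt(sum(object@b0Direction^2)) - 1) > 1e-9)
    return("b0Direction must have unit norm (tolerance 1e-9)")
  if (length(object@imagingFrequency) != 1L || object@imagingFrequency <= 0)
    return("imagingFrequency must be > 0")
  TRUE
})

#' Construct an AcquisitionGeometry
#'
#' @param matrixSize grid size (3 integers).
#' @param voxelSize voxel size in mm.
#' @param b0Direction main-field unit vector (same axes as the array).
#' @param imagingFrequency Larmor frequency in Hz (default 3 T proton).
#' @return An [AcquisitionGeometry-class] object.
#' @export
AcquisitionGeometry <- function(matrixSize, voxelSize = c(1, 1, 1),
                                b0Direction = c(0, 0, 1),
                                imagingFrequency = 127.74e6) {
  new("AcquisitionGeometry", matrixSize = as.integer(matrixSize),
      voxelSize = as.numeric(voxelSize),
      b0Direction = as.numeric(b0Direction),
      imagingFrequency = imagingFrequency)
}

#' TSEParams: dual-echo turbo spin echo sequence parameters
#'
#' Times in ms, angles in degrees. The two images are sampled at the train
#' echoes whose times are nearest `te1` and `te2`; with the default
#' `echoSpacing = te1` those are echo 1 (10 ms) and echo 9 (90 ms), and both
#' effective echo times are recorded by [tseEchoIndices()].
#'
#' @slot tr repetition time, ms.
#' @slot te1,te2 nominal echo times of the two images, ms.
#' @slot turboFactor echoes per excitation per image.
#' @slot echoSpacing inter-echo spacing, ms.
#' @slot nominalRefocusingDeg nominal refocusing flip angle (0, 180].
#' @slot excitationDeg excitation flip angle, degrees.
#' @slot t1Assumed longitudinal relaxation time assumed during the train, ms.
#' @exportClass TSEParams
setClass("TSEParams",
  representation(tr = "numeric", te1 = "numeric", te2 = "numeric",
                 turboFactor = "integer", echoSpacing = "numeric",
                 nominalRefocusingDeg = "numeric", excitationDeg = "numeric",
                 t1Assumed = "numeric"))

setValidity("TSEParams", function(object) {
  if (object@nominalRefocusingDeg <= 0 || object@nominalRefocusingDeg > 180)
    return("nominalRefocusingDeg must lie in (0, 180]")
  if (object@echoSpacing <= 0) return("echoSpacing must be > 0")
  if (object@te1 <= 0 || object@te2 <= object@te1)
    return("need 0 < te1 < te2")
  k1 <- round(object@te1 / object@echoSpacing)
  k2 <- round(object@te2 / object@echoSpacing)
  if (k1 < 1 || k2 < 1 || k1 == k2)
    return("te1 and te2 must map to distinct echo-train indices k >= 1")
  TRUE
})

#' Construct TSEParams
#'
#' Defaults follow the dual-echo protocol driving this analysis:
#' TR 2500 ms, TE 10/93 ms, turbo factor 8, 165 degree refocusing.
#'
#' @param tr,te1,te2,turboFactor,echoSpacing,nominalRefocusingDeg,excitationDeg,t1Assumed
#'   see slot documentation in [TSEParams-class].
#' @return A [TSEParams-class] object.
#' @export
TSEParams <- function(tr = 2500, te1 = 10, te2 = 93, turboFactor = 8L,
                      echoSpacing = te1, nominalRefocusingDeg = 165,
                      excitationDeg = 90, t1Assumed = 1000) {
  new("TSEParams", tr = tr, te1 = te1, te2 = te2,
      turboFactor = as.integer(turboFactor), echoSpacing = echoSpacing,
      nominalRefocusingDeg = nominalRefocusingDeg,
      excitationDeg = excitationDeg, t1Assumed = t1Assumed)
}

#' MEGEParams: multi-echo gradient echo sequence parameters
#'
#' @slot tr repetition time, ms.
#' @slot teFirst first echo time, ms.
#' @slot echoSpacing inter-echo spacing, ms.
#' @slot nEchoes number of echoes (>= 2).
#' @slot flipDeg excitation flip angle, degrees.
#' @exportClass MEGEParams
setClass("MEGEParams",
  representation(tr = "numeric", teFirst = "numeric", echoSpacing = "numeric",
                 nEchoes = "integer", flipDeg = "numeric"))

setValidity("MEGEParams", function(object) {
  if (object@nEchoes < 2L) return("nEchoes must be >= 2")
  if (object@echoSpacing <= 0 || object@teFirst <= 0)
    return("echo times must be strictly increasing and positive")
  TRUE
})

#' Construct MEGEParams
#'
#' Defaults: TE1 5.0 ms, spacing 7.1 ms, 6 echoes, 18 degree flip.
#'
#' @param tr,teFirst,echoSpacing,nEchoes,flipDeg see [MEGEParams-class].
#' @return A [MEGEParams-class] object.
#' @export
MEGEParams <- function(tr = 47, teFirst = 5.0, echoSpacing = 7.1,
                       nEchoes = 6L, flipDeg = 18) {
  new("MEGEParams", tr = tr, teFirst = teFirst, echoSpacing = echoSpacing,
      nEchoes = as.integer(nEchoes), flipDeg = flipDeg)
}

#' EchoTrain: echo times and amplitudes of a simulated spin-echo train
#'
#' Amplitudes are normalised to unit initial magnetisation.
#'
#' @slot echoTimes numeric, ms.
#' @slot amplitudes numeric, same length.
#' @exportClass EchoTrain
setClass("EchoTrain",
  representation(echoTimes = "numeric", amplitudes = "numeric"))

setValidity("EchoTrain", function(object) {
  if (length(object@echoTimes) != length(object@amplitudes))
    return("echoTimes and amplitudes must have the same length")
  TRUE
})

#' ROISet: integer label volume plus name-to-code lookup
#'
#' Labels partition the grid (every voxel has exactly one label); code 0 is
#' air/outside. Paired deep gray matter structures carry distinct left and
#' right codes.
#'
#' @slot labels 3D integer array.
#' @slot roiNames named integer vector mapping ROI name to label code.
#' @exportClass ROISet
setClass("ROISet",
  representation(labels = "array", roiNames = "integer"))

setValidity("ROISet", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
  if (is.null(names(object@roiNames))) return("roiNames must be named")
  if (anyDuplicated(object@roiNames)) return("label codes must be unique")
  if (any(!unique(as.integer(object@labels)) %in% c(0L, object@roiNames)))
    return("label volume contains codes absent from roiNames")
  TRUE
})

#' PhantomTruth: ground-truth bundle for one synthetic subject
#'
#' Holds non-negative paramagnetic/diamagnetic susceptibility magnitudes
#' (ppb), tissue R2 and self-consistent R2* (Hz), the relative transmit
#' field B1+, the dipole-derived frequency shift (Hz), ROI labels, the true
#' relaxometric constant and the acquisition geometry.
#'
#' @slot chiPara,chiDia [ScalarVolume-class], ppb, >= 0.
#' @slot r2,r2star [ScalarVolume-class], Hz.
#' @slot b1 [ScalarVolume-class], relative.
#' @slot deltaF [ScalarVolume-class], Hz.
#' @slot rois [ROISet-class].
#' @slot drTrue relaxometric constant used to build R2*, Hz/ppm.
#' @slot geometry [AcquisitionGeometry-class].
#' @slot config the phantom configuration list used to build the object.
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(chiPara = "ScalarVolume", chiDia = "ScalarVolume",
                 r2 = "ScalarVolume", r2star = "ScalarVolume",
                 b1 = "ScalarVolume", deltaF = "ScalarVolume",
                 rois = "ROISet", drTrue = "numeric",
                 geometry = "AcquisitionGeometry", config = "list"))

setValidity("PhantomTruth", function(object) {
  msk <- object@chiPara@mask
  inb <- if (is.null(msk)) TRUE else msk
  if (any(object@chiPara@data < 0) || any(object@chiDia@data < 0))
    return("chiPara and chiDia must be non-negative everywhere")
  if (any((object@r2star@data - object@r2@data)[inb] < -1e-9))
    return("r2star must be >= r2 at every brain voxel")
  if (isTRUE(object@config$selfConsistent)) {
    lhs <- object@r2star@data - object@r2@data
    rhs <- object@drTrue * (object@chiPara@data + object@chiDia@data) / 1000
    if (max(abs((lhs - rhs)[inb])) > 1e-9)
      return("self-consistency r2star - r2 = drTrue*(chiPara+chiDia)/1000 violated")
  }
  TRUE
})

#' DictionaryGrid: (T2 x B1) grid of simulated dual-echo TSE amplitudes
#'
#' Signals are EPG echo amplitudes at the two sampled train echoes,
#' normalised so the first echo has unit amplitude (only the echo ratio is
#' identifiable from two magnitude images).
#'
#' @slot t2Values T2 grid, ms (sorted).
#' @slot b1Values relative B1 grid (sorted).
#' @slot echo1,echo2 amplitude matrices, `length(t2Values)` x `length(b1Values)`.
#' @slot params the [TSEParams-class] used for simulation.
#' @exportClass DictionaryGrid
setClass("DictionaryGrid",
  representation(t2Values = "numeric", b1Values = "numeric",
                 echo1 = "matrix", echo2 = "matrix", params = "TSEParams"))

setValidity("DictionaryGrid", function(object) {
  dmn <- c(length(object@t2Values), length(object@b1Values))
  if (!identical(dim(object@echo1), dmn) || !identical(dim(object@echo2), dmn))
    return("signal matrices must be t2 x b1")
  if (is.unsorted(object@t2Values) || is.unsorted(object@b1Values))
    return("grids must be sorted increasing")
  # amplitudes must be physical; pairwise echo1 >= echo2 is deliberately
  # NOT required: at long T2 and reduced effective refocusing angles the
  # stimulated-echo/transient enhancement of late echoes legitimately
  # pushes the sampled ratio above one, and the fit flags such voxels
  if (any(!is.finite(object@echo1)) || !all(object@echo2 > 0))
    return("expected finite amplitudes with amplitude2 > 0")
  TRUE
})

#' RelaxometricConstant: slope linking R2' (Hz) to |chi| (ppm)
#'
#' @slot dr the constant, Hz/ppm (> 0).
#' @slot source `"default"` or `"regressed"`.
#' @slot diagnostics list with regression diagnostics (intercept, slope
#'   standard error, r.squared, the six points) when regressed.
#' @exportClass RelaxometricConstant
setClass("RelaxometricConstant",
  representation(dr = "numeric", source = "character", diagnostics = "list"),
  prototype(diagnostics = list()))

setValidity("RelaxometricConstant", function(object) {
  if (length(object@dr) != 1L || !is.finite(object@dr) || object@dr <= 0)
    return("dr must be a single positive number")
  if (!object@source %in% c("default", "regressed"))
    return("source must be 'default' or 'regressed'")
  TRUE
})

#' Default relaxometric constant (137 Hz/ppm)
#'
#' The fixed value shipped with the reference source-separation pipeline,
#' used for every subject when regression is not requested.
#'
#' @param dr value in Hz/ppm.
#' @return A [RelaxometricConstant-class] with source `"default"`.
#' @export
drDefault <- function(dr = 137) {
  new("RelaxometricConstant", dr = dr, source = "default")
}

#' SeparationResult: non-negative component maps plus solver diagnostics
#'
#' @slot chiPara,chiDia non-negative component magnitudes, ppb.
#' @slot chiTotal `chiPara - chiDia`, ppb (exact elementwise identity).
#' @slot drUsed the [RelaxometricConstant-class] used.
#' @slot iterations iterations performed.
#' @slot converged logical, tolerance reached before the iteration cap.
#' @slot residuals list: RMS of the relaxation and field data residuals (Hz)
#'   and the final cost.
#' @exportClass SeparationResult
setClass("SeparationResult",
  representation(chiPara = "ScalarVolume", chiDia = "ScalarVolume",
                 chiTotal = "ScalarVolume", drUsed = "RelaxometricConstant",
                 iterations = "integer", converged = "logical",
                 residuals = "list"))

setValidity("SeparationResult", function(object) {
  if (any(object@chiPara@data < 0) || any(object@chiDia@data < 0))
    return("component maps must be non-negative everywhere")
  if (max(abs(object@chiTotal@data -
              (object@chiPara@data - object@chiDia@data))) > 0)
    return("chiTotal must equal chiPara - chiDia exactly")
  TRUE
})

#' MPEReport: per-ROI, per-map mean percentage errors with paired tests
#'
#' @slot data data.frame with one row per (ROI, map, condition):
#'   `baseline_mean`, `mean`, `sd`, `diff`, `mpe_percent`, `p_value`, `n`.
#' @slot nReplicates replicates ("subjects") entering the paired tests.
#' @exportClass MPEReport
setClass("MPEReport",
  representation(data = "data.frame", nReplicates = "integer"))

setValidity("MPEReport", function(object) {
  need <- c("roi", "map", "condition", "baseline_mean", "mean", "sd",
            "diff", "mpe_percent", "p_value", "n")
  if (!all(need %in% names(object@data)))
    return(sprintf("report must have columns: %s", paste(need, collapse = ", ")))
  p <- object@data$p_value
  if (any(!is.na(p) & (p < 0 | p > 1))) return("p values must lie in [0, 1]")
  TRUE
})
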
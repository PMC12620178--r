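#' @include AllClasses.R
NULL

#' Accessors for ScalarVolume and pipeline containers
#'
#' `volData`, `voxelSize`, `volUnit`, `volMask` read the corresponding
#' slots of a [ScalarVolume-class]; `drValue` reads the Hz/ppm value of a
#' [RelaxometricConstant-class]; `roiLabels`/`roiNames` read a
#' [ROISet-class]; `reportTable` extracts the data.frame of an
#' [MPEReport-class].
#'
#' @param x the object.
#' @return The slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("volUnit", function(x) standardGeneric("volUnit"))
#' @rdname accessors
#' @export
setGeneric("volMask", function(x) standardGeneric("volMask"))
#' @rdname accessors
#' @export
setGeneric("drValue", function(x) standardGeneric("drValue"))
#' @rdname accessors
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
#' @rdname accessors
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))
#' @rdname accessors
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @rdname accessors
setMethod("volData", "ScalarVolume", function(x) x@data)
#' @rdname accessors
setMethod("voxelSize", "ScalarVolume", function(x) x@voxelSize)
#' @rdname accessors
setMethod("volUnit", "ScalarVolume", function(x) x@unit)
#' @rdname accessors
setMethod("volMask", "ScalarVolume", function(x) x@mask)
#' @rdname accessors
setMethod("drValue", "RelaxometricConstant", function(x) x@dr)
#' @rdname accessors
setMethod("roiLabels", "ROISet", function(x) x@labels)
#' @rdname accessors
setMethod("roiNames", "ROISet", function(x) x@roiNames)
#' @rdname accessors
setMethod("roiLabels", "PhantomTruth", function(x) x@rois@labels)
#' @rdname accessors
setMethod("roiNames", "PhantomTruth", function(x) x@rois@roiNames)
#' @rdname accessors
setMethod("reportTable", "MPEReport", function(x) x@data)

setMethod("show", "ScalarVolume", function(object) {
  d <- dim(object@data)
  rng <- range(if (is.null(object@mask)) object@data
               else object@data[object@mask])
  cat(sprintf("ScalarVolume %dx%dx%d voxels (%.2gx%.2gx%.2g mm), unit=%s\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3], object@unit))
  cat(sprintf("  range%s: [%.4g, %.4g]%s\n",
              if (is.null(object@mask)) "" else " (in mask)",
              rng[1], rng[2],
              if (is.null(object@mask)) ""
              else sprintf(", mask voxels: %d", sum(object@mask))))
})

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@r2@data)
  cat(sprintf("PhantomTruth %dx%dx%d, drTrue = %g Hz/ppm, %d ROIs\n",
              d[1], d[2], d[3], object@drTrue, length(object@rois@roiNames)))
  cat("  maps: chiPara, chiDia [ppb], r2, r2star, deltaF [Hz], b1 [relative]\n")
})

setMethod("show", "DictionaryGrid", function(object) {
  cat(sprintf(
    "DictionaryGrid: %d T2 values [%g, %g] ms x %d B1 values [%g, %g]\n",
    length(object@t2Values), min(object@t2Values), max(object@t2Values),
    length(object@b1Values), min(object@b1Values), max(object@b1Values)))
})

setMethod("show", "RelaxometricConstant", function(object) {
  cat(sprintf("RelaxometricConstant: %.4g Hz/ppm (%s)\n",
              object@dr, object@source))
})

setMethod("show", "SeparationResult", function(object) {
  cat(sprintf(
    "SeparationResult: %d iterations (%s), Dr = %.4g Hz/ppm (%s)\n",
    object@iterations, if (object@converged) "converged" else "iteration cap",
    object@drUsed@dr, object@drUsed@source))
  cat(sprintf("  residual RMS: relaxation %.4g Hz, field %.4g Hz\n",
              object@residuals$relaxRms, object@residuals$fieldRms))
})

setMethod("show", "MPEReport", function(object) {
  cat(sprintf("MPEReport: %d rows, %d replicates\n",
              nrow(object@data), object@nReplicates))
})

setMethod("show", "EchoTrain", function(object) {
  cat("EchoTrain:\n")
  print(data.frame(te_ms = object@echoTimes, amplitude = object@amplitudes))
})
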
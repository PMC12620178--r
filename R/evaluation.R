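#' @include AllClasses.R
NULL

#' Voxelwise difference map (altered minus baseline)
#'
#' @param altered,baseline congruent [ScalarVolume-class] maps with the
#'   same unit.
#' @return A [ScalarVolume-class].
#' @export
differenceMap <- function(altered, baseline) {
  if (!identical(dim(altered@data), dim(baseline@data)))
    stop("volumes are not congruent")
  if (altered@unit != baseline@unit) stop("unit mismatch")
  ScalarVolume(altered@data - baseline@data, voxelSize = altered@voxelSize,
               unit = altered@unit, mask = altered@mask)
}

#' CSF-contamination exclusion mask
#'
#' Keeps voxels with `R2 >= 2.5` Hz (T2 <= 400 ms) and `R2* >= 5` Hz
#' (T2* <= 200 ms); slower-relaxing voxels suggest partial CSF voluming
#' and are excluded. Computed once on the baseline maps and reused for
#' every error condition, so ROI voxel sets stay fixed across conditions.
#'
#' @param r2,r2star congruent [ScalarVolume-class] maps, Hz.
#' @param r2Min,r2starMin thresholds in Hz.
#' @return logical array.
#' @export
exclusionMask <- function(r2, r2star, r2Min = 2.5, r2starMin = 5) {
  if (!identical(dim(r2@data), dim(r2star@data)))
    stop("volumes are not congruent")
  keep <- r2@data >= r2Min & r2star@data >= r2starMin
  base <- r2@mask
  if (!is.null(base)) keep <- keep & base
  keep
}

#' Per-ROI means of a volume
#'
#' @param vol a [ScalarVolume-class].
#' @param rois a [ROISet-class].
#' @param mask logical inclusion mask (e.g. from [exclusionMask()]).
#' @param which ROI names to evaluate (default: all).
#' @return named numeric vector, one mean per ROI present.
#' @export
roiMeans <- function(vol, rois, mask = NULL, which = names(rois@roiNames)) {
  if (is.null(mask)) mask <- array(TRUE, dim(vol@data))
  out <- vapply(which, function(nm) {
    sel <- rois@labels == rois@roiNames[[nm]] & mask
    if (!any(sel)) return(NA_real_)
    mean(vol@data[sel])
  }, numeric(1))
  out
}

#' Per-ROI mean percentage error
#'
#' `100 * (mean_altered - mean_baseline) / mean_baseline` over the
#' included voxels of each ROI; `NaN`-safe: a zero baseline mean reports
#' `NA` (undefined), an empty ROI after exclusion raises an error.
#'
#' @param altered,baseline congruent [ScalarVolume-class] maps.
#' @param rois a [ROISet-class].
#' @param mask logical inclusion mask.
#' @param which ROI names to evaluate (default: all).
#' @return named numeric vector of MPE percentages.
#' @export
roiMpe <- function(altered, baseline, rois, mask = NULL,
                   which = names(rois@roiNames)) {
  if (is.null(mask)) mask <- array(TRUE, dim(altered@data))
  out <- vapply(which, function(nm) {
    sel <- rois@labels == rois@roiNames[[nm]] & mask
    if (!any(sel)) stop("ROI empty after exclusion: ", nm)
    mb <- mean(baseline@data[sel])
    if (mb == 0) return(NA_real_)
    100 * (mean(altered@data[sel]) - mb) / mb
  }, numeric(1))
  out
}

#' Two-sided paired t test on replicate ROI means
#'
#' Null hypothesis: the mean of the paired differences (altered minus
#' baseline) is zero. Degenerate zero-variance differences with a nonzero
#' mean report a p value at the machine minimum with `degenerate = TRUE`.
#'
#' @param valuesAltered,valuesBaseline equal-length paired samples
#'   (one value per replicate), n >= 2.
#' @return list with `t`, `df`, `p_value`, `degenerate`.
#' @export
pairedTest <- function(valuesAltered, valuesBaseline) {
  if (length(valuesAltered) != length(valuesBaseline))
    stop("paired samples must have equal length")
  n <- length(valuesAltered)
  if (n < 2) stop("need at least 2 paired observations")
  dif <- valuesAltered - valuesBaseline
  if (sd(dif) == 0) {
    if (mean(dif) == 0) return(list(t = 0, df = n - 1, p_value = 1,
                                    degenerate = FALSE))
    return(list(t = sign(mean(dif)) * Inf, df = n - 1,
                p_value = .Machine$double.xmin, degenerate = TRUE))
  }
  ht <- t.test(valuesAltered, valuesBaseline, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, degenerate = FALSE)
}

#' Source-rich ROIs of a phantom
#'
#' ROIs whose baseline total susceptibility magnitude is large enough for
#' a percentage error on chiTotal to be meaningful; by default those with
#' `|chiPara - chiDia| >= 10` ppb in the configured means (the iron-rich
#' deep gray structures and the myelin-rich callosal regions, excluding
#' the near-balanced thalamus).
#'
#' @param config phantom configuration (see [defaultPhantomConfig()]).
#' @param minAbsChiTotal threshold in ppb.
#' @return character vector of ROI base names.
#' @export
sourceRichRois <- function(config = defaultPhantomConfig(),
                           minAbsChiTotal = 10) {
  nm <- names(config$chiParaMeans)
  tot <- config$chiParaMeans - config$chiDiaMeans[nm]
  keep <- nm[abs(tot) >= minAbsChiTotal &
             !nm %in% c("wm_background", "cortical_gm", "csf")]
  keep
}

#' Analysis ROI names of a phantom
#'
#' The structures the error analysis reports on: the four paired deep
#' gray matter structures (left/right separately) and the three corpus
#' callosum regions -- excluding the background tissue classes and CSF.
#'
#' @param rois a [ROISet-class] or [PhantomTruth-class].
#' @return character vector of ROI names.
#' @export
analysisRois <- function(rois) {
  nm <- if (is(rois, "PhantomTruth")) names(rois@rois@roiNames)
        else names(rois@roiNames)
  setdiff(nm, c("csf", "wm_background", "cortical_gm"))
}
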
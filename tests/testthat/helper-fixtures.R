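# shared fixtures: a reduced phantom and run configuration used by the
# module tests so that the suite stays fast; the acceptance tests use the
# full default study conditions

smokePhantomConfig <- function() {
  cfg <- defaultPhantomConfig(matrixSize = c(32L, 32L, 32L),
                              voxelSize = c(2, 2, 3))
  cfg
}

smokeRunConfig <- function(seed = 1L) {
  cfg <- defaultRunConfig(seed = seed)
  cfg$phantom <- smokePhantomConfig()
  cfg$dictionary <- list(t2From = 10, t2To = 2000, t2By = 5,
                         b1From = 0.4, b1To = 1.6, b1By = 0.02)
  cfg$nReplicates <- 3L
  cfg
}

# small synthetic ROI set: six cubes with distinct L/R labels for the
# three regression structures, embedded in a 12x12x6 grid
syntheticRegressionRois <- function() {
  labels <- array(0L, c(12, 12, 6))
  nm <- c("caudate_L", "caudate_R", "globus_pallidus_L",
          "globus_pallidus_R", "putamen_L", "putamen_R")
  codes <- seq_along(nm)
  ox <- c(1, 7, 1, 7, 1, 7); oy <- c(1, 1, 5, 5, 9, 9)
  for (i in seq_along(nm))
    labels[ox[i]:(ox[i] + 2), oy[i]:(oy[i] + 2), 2:4] <- codes[i]
  new("ROISet", labels = labels, roiNames = setNames(as.integer(codes), nm))
}

# volumes with prescribed per-ROI constants on the synthetic ROI set
roiConstantVolume <- function(rois, values, unit) {
  arr <- array(0, dim(rois@labels))
  for (nm in names(rois@roiNames))
    arr[rois@labels == rois@roiNames[[nm]]] <- values[[nm]]
  ScalarVolume(arr, unit = unit)
}
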
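#' @include AllClasses.R dipole.R sequence-sim.R
NULL

#' Default phantom configuration
#'
#' Nested-ellipsoid brain phantom on a 64 x 64 x 48 grid at 1 x 1 x 2 mm
#' (a scaled-down whole-head matrix). Per-ROI paramagnetic/diamagnetic
#' susceptibility means (ppb) follow the unaltered default-constant
#' component values of the reference cohort; white-matter background,
#' cortical gray matter and CSF values are plausibility choices. Tissue R2
#' values are chosen so the whole-brain mean (CSF included) is about
#' 11.7 Hz. The true relaxometric constant defaults to 142 Hz/ppm and R2*
#' is derived self-consistently: `R2* = R2 + drTrue * (chiPara + chiDia)`.
#'
#' Structure centres/semi-axes are in mm relative to the grid centre
#' (x lateral, y anterior-posterior, z inferior-superior). The B1+ field is
#' a smooth quadratic polynomial of the normalised brain radius with a
#' small lateral tilt, spanning roughly `[b1Edge, b1Centre]`.
#'
#' @param matrixSize grid size.
#' @param voxelSize voxel size, mm.
#' @return configuration list for [generatePhantom()].
#' @export
defaultPhantomConfig <- function(matrixSize = c(64L, 64L, 48L),
                                 voxelSize = c(1, 1, 2)) {
  structures <- data.frame(
    name = c("caudate_L", "caudate_R", "globus_pallidus_L",
             "globus_pallidus_R", "putamen_L", "putamen_R",
             "thalamus_L", "thalamus_R", "splenium", "body_cc", "genu_cc",
             "csf_L", "csf_R"),
    cx = c(-11, 11, -10, 10, -18, 18, -9, 9, 0, 0, 0, -5.5, 5.5),
    cy = c(13, 13, 2, 2, 3, 3, -9, -9, -17, 2, 20, 2, 2),
    cz = c(7, 7, -3, -3, 0, 0, 2, 2, 6, 14, 5, 7, 7),
    ax = c(3.5, 3.5, 3, 3, 4.5, 4.5, 4.5, 4.5, 4, 4, 4, 2.5, 2.5),
    ay = c(6, 6, 4.5, 4.5, 8, 8, 6.5, 6.5, 4, 9, 3, 9, 9),
    az = c(5, 5, 4, 4, 6, 6, 5, 5, 6, 3, 6, 5, 5),
    stringsAsFactors = FALSE)
  chiPara <- c(caudate = 48.9, globus_pallidus = 132.0, putamen = 46.7,
               thalamus = 26.7, splenium = 23.5, body_cc = 15.5,
               genu_cc = 22.5, wm_background = 20, cortical_gm = 35,
               csf = 0)
  chiDia <- c(caudate = 14.6, globus_pallidus = 18.6, putamen = 17.1,
              thalamus = 23.9, splenium = 35.9, body_cc = 30.6,
              genu_cc = 30.3, wm_background = 28, cortical_gm = 18,
              csf = 0)
  # DGM R2 reflects the in-vivo iron-R2 association (pallidum highest)
  r2 <- c(caudate = 14.5, globus_pallidus = 19.5, putamen = 15.5,
          thalamus = 13.5, splenium = 14, body_cc = 14, genu_cc = 14,
          wm_background = 12.8, cortical_gm = 10.0, csf = 0.4)
  list(
    matrixSize = as.integer(matrixSize), voxelSize = as.numeric(voxelSize),
    b0Direction = c(0, 0, 1), imagingFrequency = 127.74e6,
    brainSemiAxes = c(29, 28, 42),     # mm
    gmShellFraction = 0.85,            # interior fraction below cortical GM
    structures = structures,
    chiParaMeans = chiPara, chiDiaMeans = chiDia, r2Means = r2,
    chiTextureFrac = 0.10,             # within-ROI Gaussian texture, sd/mean
    r2TextureFrac = 0.03,
    b1Centre = 1.05, b1Edge = 0.75, b1TiltX = 0.02,
    drTrue = 142, selfConsistent = TRUE,
    tseNoiseSd = 0.01, megeNoiseSd = 0.01,   # SNR ~ 100 at unit signal
    nReplicates = 11L)
}

#' Default end-to-end run configuration
#'
#' Phantom configuration plus sequence parameters, error-sweep settings,
#' solver settings and the base seed; [writeConfigEcho()] serialises it
#' next to every run's outputs.
#'
#' @param seed base seed; replicate k uses `seed + 1000 * k`.
#' @return configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(phantom = defaultPhantomConfig(),
       tse = list(tr = 2500, te1 = 10, te2 = 93, turboFactor = 8L,
                  nominalRefocusingDeg = 165, t1Assumed = 1000),
       mege = list(tr = 47, teFirst = 5.0, echoSpacing = 7.1, nEchoes = 6L,
                   flipDeg = 18),
       errors = list(factors = enumerateErrorSeries(),
                     r2starCoefficient = 0.48),
       solver = list(lambda = 1, maxIters = 200, tol = 1e-6,
                     qsmThreshold = 0.19),
       drModes = c("default", "regressed"),
       nReplicates = 11L,
       seed = as.integer(seed))
}

# ellipsoid membership: coords list(X, Y, Z) in mm, centre/semi mm
.insideEllipsoid <- function(co, centre, semi) {
  ((co$X - centre[1]) / semi[1])^2 + ((co$Y - centre[2]) / semi[2])^2 +
    ((co$Z - centre[3]) / semi[3])^2 <= 1
}

.structureClass <- function(name) sub("_[LR]$", "", name)

#' Generate a ground-truth phantom
#'
#' Builds the ROI label volume (air, CSF, white-matter background,
#' cortical gray matter shell, left/right deep gray structures, three
#' corpus callosum regions), draws within-ROI Gaussian texture around the
#' configured susceptibility and R2 means (clamped at zero: both component
#' maps are magnitudes), lays down the smooth B1+ polynomial, derives R2*
#' from the self-consistency rule and computes the frequency shift as the
#' forward dipole field of `chiPara - chiDia`.
#'
#' @param config list from [defaultPhantomConfig()].
#' @param seed integer seed for the texture draws.
#' @return A [PhantomTruth-class].
#' @export
generatePhantom <- function(config = defaultPhantomConfig(), seed = 1L) {
  n <- config$matrixSize
  if (any(n < 32L)) stop("grid must be at least 32^3")
  vs <- config$voxelSize
  geometry <- AcquisitionGeometry(n, vs, config$b0Direction,
                                  config$imagingFrequency)
  # physical coordinates (mm), grid centre at origin
  cx <- (seq_len(n[1]) - (n[1] + 1) / 2) * vs[1]
  cy <- (seq_len(n[2]) - (n[2] + 1) / 2) * vs[2]
  cz <- (seq_len(n[3]) - (n[3] + 1) / 2) * vs[3]
  co <- list(X = array(cx, n),
             Y = array(rep(cy, each = n[1]), n),
             Z = array(rep(cz, each = n[1] * n[2]), n))
  rho2 <- (co$X / config$brainSemiAxes[1])^2 +
    (co$Y / config$brainSemiAxes[2])^2 + (co$Z / config$brainSemiAxes[3])^2

  structNames <- config$structures$name
  tissueNames <- c("csf", "wm_background", "cortical_gm",
                   structNames[!grepl("^csf", structNames)])
  roiNames <- setNames(seq_along(tissueNames), tissueNames)

  labels <- array(0L, n)
  labels[rho2 <= 1] <- roiNames[["cortical_gm"]]
  labels[rho2 <= config$gmShellFraction^2] <- roiNames[["wm_background"]]
  for (i in seq_len(nrow(config$structures))) {
    s <- config$structures[i, ]
    code <- if (grepl("^csf", s$name)) roiNames[["csf"]] else roiNames[[s$name]]
    inside <- .insideEllipsoid(co, c(s$cx, s$cy, s$cz), c(s$ax, s$ay, s$az))
    if (any(rho2[inside] > config$gmShellFraction^2))
      stop("overlapping ROI geometry: ", s$name,
           " extends beyond the white-matter compartment")
    clash <- inside & !labels %in% c(roiNames[["wm_background"]])
    if (any(clash & inside))
      stop("overlapping ROI geometry: ", s$name,
           " intersects a previously placed structure")
    labels[inside] <- code
  }
  rois <- new("ROISet", labels = labels, roiNames = roiNames)

  # per-voxel means from the per-class tables
  classOf <- vapply(tissueNames, .structureClass, "")
  fill <- function(means, texFrac) {
    out <- array(0, n)
    for (nm in tissueNames) {
      idx <- labels == roiNames[[nm]]
      out[idx] <- means[[classOf[[nm]]]]
    }
    if (texFrac > 0) {
      tex <- array(rnorm(prod(n)), n) * texFrac * out
      out <- pmax(out + tex, 0)
    }
    out[labels == 0L] <- 0
    out
  }
  set.seed(seed)
  chiPara <- fill(config$chiParaMeans, config$chiTextureFrac)
  chiDia <- fill(config$chiDiaMeans, config$chiTextureFrac)
  r2 <- fill(config$r2Means, config$r2TextureFrac)
  r2[labels != 0L] <- pmax(r2[labels != 0L], 0.1)

  # smooth transmit field: quadratic in the normalised brain radius + tilt
  b1 <- config$b1Centre - (config$b1Centre - config$b1Edge) * pmin(rho2, 1.5) +
    config$b1TiltX * co$X / max(abs(cx))
  if (min(b1) < 0.4 || max(b1) > 1.6)
    stop("B1 range outside dictionary support [0.4, 1.6]")

  mask <- labels != 0L
  r2star <- if (isTRUE(config$selfConsistent)) {
    r2 + config$drTrue * (chiPara + chiDia) / 1000
  } else r2

  sv <- function(x, unit, masked = TRUE)
    ScalarVolume(x, voxelSize = vs, unit = unit,
                 mask = if (masked) mask else NULL)
  kernel <- dipoleKernel(geometry)
  deltaF <- forwardField(sv((chiPara - chiDia) / 1000, "ppm"), kernel)

  new("PhantomTruth",
      chiPara = sv(chiPara, "ppb"), chiDia = sv(chiDia, "ppb"),
      r2 = sv(r2, "Hz"), r2star = sv(r2star, "Hz"),
      b1 = sv(b1, "relative", masked = FALSE), deltaF = deltaF,
      rois = rois, drTrue = config$drTrue, geometry = geometry,
      config = config)
}

#' Simulate the dual-echo TSE magnitude images of a phantom
#'
#' Runs the EPG train per brain voxel with effective refocusing angle
#' `nominal x B1(r)` (clamped at 180 degrees with a message when B1
#' pushes past it), samples the two train echoes given by
#' [tseEchoIndices()] and adds Gaussian noise to the magnitudes.
#'
#' @param truth a [PhantomTruth-class].
#' @param params a [TSEParams-class].
#' @param noiseSd magnitude noise standard deviation (signal is 1 at TE=0).
#' @param seed integer seed.
#' @return list with `echo1`, `echo2` ([ScalarVolume-class]) and the
#'   effective echo times `te1Eff`, `te2Eff` (ms).
#' @export
simulateTse <- function(truth, params = TSEParams(),
                        noiseSd = truth@config$tseNoiseSd, seed = 1L) {
  stopifnot(is(truth, "PhantomTruth"))
  if (noiseSd < 0) stop("negative noise_sd")
  idx <- tseEchoIndices(params)
  msk <- truth@r2@mask
  r2v <- truth@r2@data[msk]
  t2 <- 1000 / pmax(r2v, 1e-3)
  t2 <- pmin(t2, 1e5)
  b1 <- truth@b1@data[msk]
  maxB1 <- 180 / params@nominalRefocusingDeg
  nClamp <- sum(b1 > maxB1)
  if (nClamp > 0) {
    message("simulateTse: effective refocusing clamped to 180 degrees at ",
            nClamp, " voxels")
    b1 <- pmin(b1, maxB1)
  }
  amps <- .epgEchoAmps(t2, pmax(params@t1Assumed, t2), b1, params,
                       idx$nTrain)
  n <- dim(truth@r2@data)
  e1 <- array(0, n); e2 <- array(0, n)
  e1[msk] <- amps[, idx$idx1]
  e2[msk] <- amps[, idx$idx2]
  if (noiseSd > 0) {
    set.seed(seed)
    e1 <- e1 + array(rnorm(prod(n), sd = noiseSd), n)
    e2 <- e2 + array(rnorm(prod(n), sd = noiseSd), n)
  }
  vs <- truth@r2@voxelSize
  list(echo1 = ScalarVolume(e1, vs, "dimensionless"),
       echo2 = ScalarVolume(e2, vs, "dimensionless"),
       te1Eff = idx$te1Eff, te2Eff = idx$te2Eff)
}

#' Simulate the complex multi-echo gradient echo signal of a phantom
#'
#' `S(TE) = S0 exp(-R2* TE) exp(i 2 pi deltaF TE)` per voxel at the echo
#' times of `params`, plus independent complex Gaussian noise (standard
#' deviation `noiseSd` per real/imaginary channel).
#'
#' @param truth a [PhantomTruth-class].
#' @param params a [MEGEParams-class].
#' @param noiseSd per-channel noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return list with `signal` (4D complex array, last dimension = echo),
#'   `echoTimes` (ms) and `params`.
#' @export
simulateMege <- function(truth, params = MEGEParams(),
                         noiseSd = truth@config$megeNoiseSd, seed = 1L) {
  stopifnot(is(truth, "PhantomTruth"))
  if (noiseSd < 0) stop("negative noise_sd")
  te <- megeEchoTimes(params) / 1000  # s
  n <- dim(truth@r2star@data)
  msk <- truth@r2star@mask
  s0 <- array(0, n); s0[msk] <- 1
  sig <- array(0 + 0i, c(n, params@nEchoes))
  for (e in seq_along(te)) {
    sig[, , , e] <- s0 * exp(-truth@r2star@data * te[e]) *
      exp(2i * pi * truth@deltaF@data * te[e])
  }
  if (noiseSd > 0) {
    set.seed(seed)
    ntot <- length(sig)
    sig <- sig + array(complex(real = rnorm(ntot, sd = noiseSd),
                               imaginary = rnorm(ntot, sd = noiseSd)),
                       dim(sig))
  }
  list(signal = sig, echoTimes = megeEchoTimes(params), params = params)
}
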
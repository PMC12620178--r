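#' @include AllClasses.R dipole.R
NULL

#' Estimate the relaxometric constant by ROI regression
#'
#' Ordinary least-squares slope of mean R2' (Hz) against mean absolute
#' susceptibility (ppm) over the six (structure, side) points formed by
#' the left/right caudate, globus pallidus and putamen — the iron-rich
#' deep gray structures where the R2'-susceptibility relation is
#' strongest. The intercept is left free. Scaling all R2' values by `s`
#' scales the slope by exactly `s` (least-squares linearity).
#'
#' @param qsm [ScalarVolume-class] of total susceptibility, ppb.
#' @param r2prime [ScalarVolume-class], Hz.
#' @param rois a [ROISet-class] containing the three structures with
#'   distinct `_L`/`_R` labels.
#' @param mask optional logical array restricting the ROI means.
#' @param structures structure base names entering the regression.
#' @return A [RelaxometricConstant-class] with source `"regressed"` and
#'   regression diagnostics (intercept, slope SE, r.squared, points).
#' @export
estimateDr <- function(qsm, r2prime, rois, mask = NULL,
                       structures = c("caudate", "globus_pallidus",
                                      "putamen")) {
  stopifnot(is(rois, "ROISet"))
  want <- as.vector(outer(structures, c("_L", "_R"), paste0))
  missing <- setdiff(want, names(rois@roiNames))
  if (length(missing))
    stop("rois must contain distinct L/R labels for: ",
         paste(structures, collapse = ", "))
  if (is.null(mask)) mask <- array(TRUE, dim(qsm@data))
  xs <- numeric(0); ys <- numeric(0)
  for (w in want) {
    sel <- rois@labels == rois@roiNames[[w]] & mask
    if (!any(sel)) next
    xs <- c(xs, mean(abs(qsm@data[sel])) / 1000)  # ppb -> ppm
    ys <- c(ys, mean(r2prime@data[sel]))
  }
  if (length(xs) < 3) stop("fewer than 3 usable regression points")
  if (stats::var(xs) == 0) stop("zero variance in |chi| across ROIs")
  fit <- lm(ys ~ xs)
  sm <- suppressWarnings(summary(fit))  # collinear inputs are legitimate
  dr <- unname(coef(fit)[2])
  if (!is.finite(dr) || dr <= 0)
    stop("regressed Dr is non-positive; inputs are inconsistent")
  new("RelaxometricConstant", dr = dr, source = "regressed",
      diagnostics = list(intercept = unname(coef(fit)[1]),
                         slopeSe = sm$coefficients[2, 2],
                         r.squared = sm$r.squared,
                         points = data.frame(roi = want[seq_along(xs)],
                                             absChiPpm = xs, r2prime = ys)))
}

#' Closed-form per-voxel source decomposition (test oracle)
#'
#' When the data at a voxel are exactly consistent, the model
#' `R2' = Dr (chiPara + chiDia)` together with
#' `chiTotal = chiPara - chiDia` inverts in closed form:
#' `chiPara = (R2'/Dr + chiTotal)/2`, `chiDia = (R2'/Dr - chiTotal)/2`.
#' A negative component is clamped to zero with the other set to the
#' remaining non-negative constraint, and flagged as an inconsistent
#' voxel. Serves as the independent oracle for the iterative solver.
#'
#' @param r2prime numeric (Hz), any shape.
#' @param chiTotal numeric (ppm), same shape.
#' @param dr relaxometric constant, Hz/ppm (> 0).
#' @return list of `chiPara`, `chiDia` (ppm, same shape) and logical
#'   `inconsistent`.
#' @examples
#' closedFormDecomposition(13.7, 0.06, 137)  # (0.08, 0.02) ppm
#' @export
closedFormDecomposition <- function(r2prime, chiTotal, dr) {
  if (dr <= 0) stop("dr must be > 0")
  s <- r2prime / dr
  p <- (s + chiTotal) / 2
  d <- (s - chiTotal) / 2
  inconsistent <- (p < 0) | (d < 0)
  pc <- pmax(p, 0); dc <- pmax(d, 0)
  # keep the binding constraint: where one component was clamped, assign
  # the other the larger of the two remaining one-sided solutions
  dc[p < 0] <- pmax(pmax(s, -chiTotal)[p < 0], 0)
  pc[d < 0] <- pmax(pmax(s, chiTotal)[d < 0], 0)
  list(chiPara = pc, chiDia = dc, inconsistent = inconsistent)
}

# grad^T grad with forward differences and Neumann boundaries:
# (out)_k = (x_k - x_{k-1}) - (x_{k+1} - x_k) summed over axes
.gradTGrad <- function(x) .gradTGradCpp(x, dim(x))

#' Non-negative iterative susceptibility source separation
#'
#' Minimises, over non-negative component magnitudes (ppm, supported on
#' the mask),
#' \deqn{\|w_r (D_r(\chi_p+\chi_d) - R_2')\|^2 +
#'       \|w_f (f_0 10^{-6} D * (\chi_p-\chi_d) - \Delta f)\|^2 +
#'       \lambda (\|\nabla\chi_p\|^2 + \|\nabla\chi_d\|^2)}
#' by projected conjugate gradients: exact line search on the quadratic,
#' projection onto the non-negative orthant each iteration, direction
#' restart whenever the projection clips. Initialisation at zero
#' (deterministic, seed-free). Stops when the relative cost change drops
#' below `tol` or at `maxIters`; a sustained cost increase raises an
#' error with diagnostics.
#'
#' @param r2prime [ScalarVolume-class], Hz.
#' @param deltaF [ScalarVolume-class], tissue frequency shift, Hz.
#' @param dr a [RelaxometricConstant-class] (same constant for both
#'   components).
#' @param geometry an [AcquisitionGeometry-class].
#' @param mask logical array of brain voxels.
#' @param lambda gradient-regularisation weight (Hz^2/ppm^2 scale).
#' @param wr,wf optional weight volumes for the relaxation/field data
#'   terms (default: uniform inside the mask). Pass e.g. an SNR map from
#'   the MEGE magnitude for noise-adaptive weighting.
#' @param maxIters iteration cap.
#' @param tol relative cost-change tolerance.
#' @param chiInit optional [ScalarVolume-class] of total susceptibility in
#'   ppb (typically the closed-form QSM): the solver then starts from its
#'   per-voxel closed-form decomposition instead of zero. Deterministic
#'   either way; the warm start mainly speeds up the ill-conditioned
#'   dipole-cone modes of the component difference.
#' @return A [SeparationResult-class] (component maps in ppb).
#' @export
chiSeparate <- function(r2prime, deltaF, dr, geometry, mask,
                        lambda = 1, wr = NULL, wf = NULL,
                        maxIters = 200L, tol = 1e-6, chiInit = NULL) {
  stopifnot(is(dr, "RelaxometricConstant"),
            identical(dim(r2prime@data), dim(deltaF@data)))
  if (!identical(dim(r2prime@data), as.integer(geometry@matrixSize)) &&
      !identical(dim(r2prime@data), geometry@matrixSize))
    stop("volumes do not match the geometry grid")
  drv <- dr@dr
  f0s <- geometry@imagingFrequency * 1e-6   # Hz per ppm
  kernel <- dipoleKernel(geometry)
  m <- mask
  if (!any(m)) stop("empty mask")
  Wr <- if (is.null(wr)) 1 else wr@data
  Wf <- if (is.null(wf)) 1 else wf@data
  yr <- r2prime@data * m
  yf <- deltaF@data * m
  wr2 <- if (is.null(wr)) m * 1 else (Wr^2) * m
  wf2 <- if (is.null(wf)) m * 1 else (Wf^2) * m

  fieldOp <- function(x) f0s * .kernelConvolve(x, kernel)

  # H applied to (p, d); returns list plus cached linear pieces so the
  # accepted iterate can be updated without re-applying the operators
  applyH <- function(p, d) {
    rel <- drv * (p + d)
    fld <- fieldOp(p - d)
    a <- drv * (wr2 * rel)
    b <- fieldOp(wf2 * (fld * m))
    gp <- 2 * (a + b) + 2 * lambda * .gradTGrad(p)
    gd <- 2 * (a - b) + 2 * lambda * .gradTGrad(d)
    list(gp = gp * m, gd = gd * m, rel = rel, fld = fld)
  }
  # right-hand side c = A^T y; cost C(x) = x.Hx/2 - c.x + const0
  bfld <- fieldOp(wf2 * yf)
  cp <- (2 * (drv * wr2 * yr + bfld)) * m
  cd <- (2 * (drv * wr2 * yr - bfld)) * m
  const0 <- sum(wr2 * yr^2) + sum(wf2 * yf^2)
  costOf <- function(p, d, H)
    0.5 * (sum(p * H$gp) + sum(d * H$gd)) - (sum(p * cp) + sum(d * cd)) +
      const0

  # Preconditioner: in sum/difference coordinates (s, t) = (p+d, p-d) the
  # two data terms decouple: the relaxation term acts on s (well
  # conditioned) and the dipole term on t, whose normal operator is
  # (nearly) diagonal in k-space. Approximate inverses per block; the
  # cone ridge only affects convergence speed, never the fixed point.
  n3 <- dim(yr)
  lapSym <- 0
  for (ax in 1:3) {
    w <- 2 * (1 - cos(2 * pi * (seq_len(n3[ax]) - 1) / n3[ax]))
    lapSym <- lapSym + switch(ax, array(w, n3),
                              array(rep(w, each = n3[1]), n3),
                              array(rep(w, each = n3[1] * n3[2]), n3))
  }
  ridge <- 2 * f0s^2 * 1e-4
  ctk <- 2 * f0s^2 * kernel@kvalues^2 + lambda * lapSym + ridge
  hs <- 2 * drv^2 + lambda * 12
  precond <- function(g) {
    gs <- (g$gp + g$gd) / 2
    gt <- (g$gp - g$gd) / 2
    zs <- gs / hs
    zt <- Re(.ifft3(.fft3(gt) / ctk)) / length(gt)
    list(gp = (zs + zt) * m, gd = (zs - zt) * m)
  }

  if (is.null(chiInit)) {
    p <- array(0, dim(yr)); d <- array(0, dim(yr))
  } else {
    stopifnot(is(chiInit, "ScalarVolume"))
    if (chiInit@unit != "ppb") stop("chiInit must be in ppb")
    cf <- closedFormDecomposition(yr, chiInit@data / 1000 * m, drv)
    p <- cf$chiPara * m; d <- cf$chiDia * m
  }
  H <- applyH(p, d)
  gdot <- function(a, b) sum(a$gp * b$gp) + sum(a$gd * b$gd)
  g <- list(gp = H$gp - cp, gd = H$gd - cd)
  z <- precond(g)
  dir <- list(gp = -z$gp, gd = -z$gd)
  cost <- costOf(p, d, H)
  iters <- 0L; converged <- FALSE; nIncrease <- 0L
  gOld <- g; zOld <- z
  while (iters < maxIters) {
    iters <- iters + 1L
    Hd <- applyH(dir$gp, dir$gd)
    denom <- gdot(dir, Hd)
    if (denom <= 0) break
    alpha <- -gdot(g, dir) / denom
    pNew <- p + alpha * dir$gp
    dNew <- d + alpha * dir$gd
    clipped <- any(pNew < 0) || any(dNew < 0)
    pNew <- pmax(pNew, 0) * m
    dNew <- pmax(dNew, 0) * m
    HNew <- if (clipped) applyH(pNew, dNew) else
      list(gp = H$gp + alpha * Hd$gp, gd = H$gd + alpha * Hd$gd,
           rel = H$rel + alpha * Hd$rel, fld = H$fld + alpha * Hd$fld)
    costNew <- costOf(pNew, dNew, HNew)
    if (costNew > cost + 1e-12 * abs(cost)) {
      # projected-arc backtracking along the search direction
      step <- alpha
      repeat {
        step <- step / 2
        pNew <- pmax(p + step * dir$gp, 0) * m
        dNew <- pmax(d + step * dir$gd, 0) * m
        HNew <- applyH(pNew, dNew)
        costNew <- costOf(pNew, dNew, HNew)
        if (costNew <= cost || abs(step) < 1e-15 * abs(alpha)) break
      }
      clipped <- TRUE
      if (costNew > cost) {
        nIncrease <- nIncrease + 1L
        if (nIncrease >= 5L)
          stop(sprintf(
            "separation diverged: cost rose over %d iterations (cost %.6g)",
            nIncrease, costNew))
        pNew <- p; dNew <- d; HNew <- H; costNew <- cost
      } else nIncrease <- 0L
    }
    p <- pNew; d <- dNew; H <- HNew
    gNew <- list(gp = H$gp - cp, gd = H$gd - cd)
    zNew <- precond(gNew)
    if (clipped) {
      dir <- list(gp = -zNew$gp, gd = -zNew$gd)  # restart after projection
    } else {
      beta <- max(0, gdot(zNew, list(gp = gNew$gp - gOld$gp,
                                     gd = gNew$gd - gOld$gd)) /
                    max(gdot(zOld, gOld), .Machine$double.eps))
      dir <- list(gp = -zNew$gp + beta * dir$gp,
                  gd = -zNew$gd + beta * dir$gd)
    }
    gOld <- gNew; g <- gNew; zOld <- zNew; z <- zNew
    costPrev <- cost; cost <- costNew
    if (abs(costPrev - cost) < tol * max(abs(costPrev), 1e-300)) {
      converged <- TRUE
      break
    }
  }
  nvox <- sum(m)
  relRms <- sqrt(sum((m * (drv * (p + d)) - yr)^2) / nvox)
  fldRms <- sqrt(sum((m * H$fld - yf)^2) / nvox)
  vs <- r2prime@voxelSize
  sv <- function(x) ScalarVolume(x, voxelSize = vs, unit = "ppb", mask = m)
  pb <- p * 1000; db <- d * 1000   # ppm -> ppb
  new("SeparationResult",
      chiPara = sv(pb), chiDia = sv(db), chiTotal = sv(pb - db),
      drUsed = dr, iterations = iters, converged = converged,
      residuals = list(relaxRms = relRms, fieldRms = fldRms,
                       finalCost = cost, initialCost = const0))
}
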
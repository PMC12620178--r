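test_that("dipole kernel takes its closed-form extreme values", {
  g <- AcquisitionGeometry(c(8, 8, 8), c(1, 1, 1), c(0, 0, 1))
  D <- dipoleKernel(g)@kvalues
  expect_equal(D[1, 1, 2], -2 / 3)   # k along B0
  expect_equal(D[2, 1, 1], 1 / 3)    # k perpendicular to B0
  expect_equal(D[1, 2, 1], 1 / 3)
  expect_equal(D[1, 1, 1], 0)        # DC convention
  expect_true(min(D) >= -2 / 3 - 1e-12 && max(D) <= 1 / 3 + 1e-12)
  expect_error(dipoleKernel(AcquisitionGeometry(c(0, 8, 8))))
})

test_that("forward field of a sphere matches the analytic dipole solution", {
  n <- c(64L, 64L, 64L)
  g <- AcquisitionGeometry(n, c(1, 1, 1), c(0, 0, 1))
  kern <- dipoleKernel(g)
  ctr <- (n + 1) / 2
  co <- list(X = array((seq_len(n[1]) - ctr[1]), n),
             Y = array(rep(seq_len(n[2]) - ctr[2], each = n[1]), n),
             Z = array(rep(seq_len(n[3]) - ctr[3], each = n[1] * n[2]), n))
  R <- 6; chi0 <- 0.1   # ppm
  r <- sqrt(co$X^2 + co$Y^2 + co$Z^2)
  chi <- array(0, n); chi[r <= R] <- chi0
  f0 <- 127.74e6
  df <- forwardField(ScalarVolume(chi, unit = "ppm"), kern, f0)
  # analytic external field of a uniformly susceptible sphere with
  # moment m = chi B0 V / mu0: df/f0 = (chi/3) (R/r)^3 (3 cos^2 theta - 1)
  shell <- r > R + 2 & r < 16
  cos2 <- (co$Z[shell] / r[shell])^2
  ana <- f0 * 1e-6 * (chi0 / 3) * (R / r[shell])^3 * (3 * cos2 - 1)
  scale <- max(abs(ana))
  expect_lt(max(abs(volData(df)[shell] - ana)) / scale, 0.05)
})

test_that("forward field vanishes for empty and uniform sources", {
  g <- AcquisitionGeometry(c(16, 16, 16))
  kern <- dipoleKernel(g)
  z <- forwardField(ScalarVolume(array(0, c(16, 16, 16)), unit = "ppm"), kern)
  expect_true(all(volData(z) == 0))
  u <- forwardField(ScalarVolume(array(0.3, c(16, 16, 16)), unit = "ppm"),
                    kern)
  expect_lt(max(abs(volData(u))), 1e-12)
  expect_error(forwardField(ScalarVolume(array(0, c(8, 8, 8)), unit = "ppm"),
                            kern), "geometry mismatch")
  expect_error(forwardField(ScalarVolume(array(0, c(16, 16, 16)),
                                         unit = "ppb"), kern), "ppm")
})

test_that("closed-form QSM is brain-referenced and inverts the forward model", {
  ph <- generatePhantom(smokePhantomConfig(), seed = 12)
  kern <- dipoleKernel(ph@geometry)
  msk <- volMask(ph@r2)
  q <- qsmClosedForm(ph@deltaF, kern, mask = msk)
  expect_lt(abs(mean(volData(q)[msk])), 1e-9)      # brain-average reference
  z <- qsmClosedForm(ScalarVolume(array(0, dim(msk)), unit = "Hz"),
                     kern, mask = msk)
  expect_true(all(volData(z) == 0))
  expect_error(qsmClosedForm(ph@deltaF, kern, mask = array(FALSE, dim(msk))),
               "empty mask")
  expect_error(qsmClosedForm(ph@deltaF, kern, mask = msk, threshold = 0.5),
               "threshold")
  # round trip recovers deep gray ROI-mean contrasts
  truthTot <- ScalarVolume(volData(ph@chiPara) - volData(ph@chiDia),
                           voxelSize = voxelSize(ph@r2), unit = "ppb",
                           mask = msk)
  ref <- mean(volData(truthTot)[msk])
  for (roi in c("caudate_L", "globus_pallidus_L", "putamen_L")) {
    tru <- roiMeans(truthTot, ph@rois)[[roi]] - ref
    est <- roiMeans(q, ph@rois)[[roi]]
    expect_lt(abs(est - tru) / abs(tru), 0.20)
  }
  # the iterative refinement tightens the same contrasts
  qi <- qsmIterative(ph@deltaF, kern, mask = msk)
  for (roi in c("caudate_L", "globus_pallidus_L", "putamen_L")) {
    tru <- roiMeans(truthTot, ph@rois)[[roi]] - ref
    est <- roiMeans(qi, ph@rois)[[roi]]
    expect_lt(abs(est - tru) / abs(tru), 0.05)
  }
})

test_that("relaxometric-constant regression is exact on collinear points", {
  rois <- syntheticRegressionRois()
  # six points exactly on a slope-137 line through the origin
  absChiPpm <- c(0.03, 0.035, 0.11, 0.115, 0.028, 0.032)
  vals <- setNames(as.list(absChiPpm * 1000), names(rois@roiNames))
  qsm <- roiConstantVolume(rois, vals, "ppb")
  r2p <- roiConstantVolume(rois,
                           setNames(as.list(absChiPpm * 137),
                                    names(rois@roiNames)), "Hz")
  dr <- estimateDr(qsm, r2p, rois)
  expect_equal(drValue(dr), 137, tolerance = 1e-9)
  expect_equal(dr@diagnostics$intercept, 0, tolerance = 1e-9)
  expect_identical(dr@source, "regressed")
  # least-squares linearity: scaling R2' scales the slope exactly
  r2pScaled <- scaleR2Map(r2p, 1.2)
  expect_equal(drValue(estimateDr(qsm, r2pScaled, rois)), 137 * 1.2,
               tolerance = 1e-9)
  # default mode bypasses regression
  expect_equal(drValue(drDefault()), 137)
  expect_identical(drDefault()@source, "default")
})

test_that("degenerate regression inputs are rejected", {
  rois <- syntheticRegressionRois()
  vals <- setNames(as.list(rep(50, 6)), names(rois@roiNames))
  qsm <- roiConstantVolume(rois, vals, "ppb")
  r2p <- roiConstantVolume(rois, vals, "Hz")
  expect_error(estimateDr(qsm, r2p, rois), "zero variance")
  few <- new("ROISet", labels = array(0L, c(4, 4, 4)),
             roiNames = c(caudate_L = 1L))
  expect_error(estimateDr(qsm, r2p, few), "L/R labels")
})

test_that("closed-form decomposition inverts consistent voxels and clamps", {
  cf <- closedFormDecomposition(13.7, 0.06, 137)
  expect_equal(cf$chiPara, 0.08)
  expect_equal(cf$chiDia, 0.02)
  expect_false(cf$inconsistent)
  sym <- closedFormDecomposition(13.7, 0, 137)   # symmetric split
  expect_equal(sym$chiPara, 0.05)
  expect_equal(sym$chiDia, 0.05)
  edge <- closedFormDecomposition(0, 0.05, 137)  # negative dia clamps
  expect_equal(edge$chiPara, 0.05)
  expect_equal(edge$chiDia, 0)
  expect_true(edge$inconsistent)
  expect_error(closedFormDecomposition(1, 0, -3), "dr")
})

test_that("separation returns exact zeros for zero data", {
  cfg <- smokePhantomConfig()
  ph <- generatePhantom(cfg, seed = 3)
  msk <- volMask(ph@r2)
  zero <- ScalarVolume(array(0, dim(msk)), voxelSize = voxelSize(ph@r2),
                       unit = "Hz", mask = msk)
  sep <- chiSeparate(zero, zero, drDefault(), ph@geometry, msk)
  expect_true(all(volData(sep@chiPara) == 0))
  expect_true(all(volData(sep@chiDia) == 0))
})

test_that("separation recovers ground truth on a consistent phantom", {
  ph <- generatePhantom(smokePhantomConfig(), seed = 3)
  r2p <- computeR2Prime(ph@r2star, ph@r2)
  q <- qsmIterative(ph@deltaF, dipoleKernel(ph@geometry),
                    mask = volMask(ph@r2))
  sep <- chiSeparate(r2p, ph@deltaF, drDefault(ph@drTrue), ph@geometry,
                     volMask(ph@r2), chiInit = q)
  # structural invariants hold on every run
  expect_true(all(volData(sep@chiPara) >= 0))
  expect_true(all(volData(sep@chiDia) >= 0))
  expect_identical(volData(sep@chiTotal),
                   volData(sep@chiPara) - volData(sep@chiDia))
  # ROI means agree with the per-voxel closed-form oracle given truth
  rois <- analysisRois(ph)
  oracle <- closedFormDecomposition(
    volData(r2p), (volData(ph@chiPara) - volData(ph@chiDia)) / 1000,
    ph@drTrue)
  oraclePara <- ScalarVolume(oracle$chiPara * 1000,
                             voxelSize = voxelSize(ph@r2), unit = "ppb")
  op <- roiMeans(oraclePara, ph@rois, which = rois)
  sp <- roiMeans(sep@chiPara, ph@rois, which = rois)
  expect_true(all(abs(sp - op) / op < 0.10))
})

test_that("scaling R2-prime moves the component sum, not the total", {
  ph <- generatePhantom(smokePhantomConfig(), seed = 3)
  msk <- volMask(ph@r2)
  r2p <- computeR2Prime(ph@r2star, ph@r2)
  q <- qsmIterative(ph@deltaF, dipoleKernel(ph@geometry), mask = msk)
  dr <- drDefault(ph@drTrue)
  sep0 <- chiSeparate(r2p, ph@deltaF, dr, ph@geometry, msk, chiInit = q)
  sep1 <- chiSeparate(scaleR2Map(r2p, 1.25), ph@deltaF, dr, ph@geometry,
                      msk, chiInit = q)
  rois <- sourceRichRois(ph@config)
  roiSel <- intersect(analysisRois(ph),
                      as.vector(outer(rois, c("", "_L", "_R"), paste0)))
  tot0 <- roiMeans(sep0@chiTotal, ph@rois, which = roiSel)
  tot1 <- roiMeans(sep1@chiTotal, ph@rois, which = roiSel)
  expect_true(all(abs(tot1 - tot0) / abs(tot0) < 0.05))
  sum0 <- roiMeans(ScalarVolume(volData(sep0@chiPara) + volData(sep0@chiDia),
                                unit = "ppb"), ph@rois, which = roiSel)
  sum1 <- roiMeans(ScalarVolume(volData(sep1@chiPara) + volData(sep1@chiDia),
                                unit = "ppb"), ph@rois, which = roiSel)
  expect_true(all(sum1 > sum0))
})
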
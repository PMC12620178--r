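test_that("phantom ground truth is self-consistent and labelled", {
  cfg <- smokePhantomConfig()
  ph <- generatePhantom(cfg, seed = 2)
  msk <- volMask(ph@r2)
  # r2star - r2 = drTrue * (chiPara + chiDia) / 1000 at every brain voxel
  lhs <- volData(ph@r2star) - volData(ph@r2)
  rhs <- ph@drTrue * (volData(ph@chiPara) + volData(ph@chiDia)) / 1000
  expect_lt(max(abs((lhs - rhs)[msk])), 1e-9)
  expect_true(all(volData(ph@chiPara) >= 0))
  expect_true(all(volData(ph@chiDia) >= 0))
  # labels partition the grid
  expect_true(all(roiLabels(ph) %in% c(0L, roiNames(ph))))
  # paired structures have distinct L/R codes
  expect_false(roiNames(ph)[["caudate_L"]] == roiNames(ph)[["caudate_R"]])
})

test_that("zero texture reproduces configured ROI means exactly", {
  cfg <- smokePhantomConfig()
  cfg$chiTextureFrac <- 0; cfg$r2TextureFrac <- 0
  ph <- generatePhantom(cfg, seed = 9)
  m <- roiMeans(ph@chiPara, ph@rois)
  expect_equal(m[["globus_pallidus_L"]], 132.0)   # configured pallidal mean
  expect_equal(m[["caudate_R"]], 48.9)
  d <- roiMeans(ph@chiDia, ph@rois)
  expect_equal(d[["splenium"]], 35.9)
  # every voxel equals the mean (degenerate noise)
  sel <- roiLabels(ph) == roiNames(ph)[["splenium"]]
  expect_true(all(volData(ph@chiDia)[sel] == 35.9))
})

test_that("textured ROI means approach configured means", {
  cfg <- smokePhantomConfig()
  ph <- generatePhantom(cfg, seed = 4)
  m <- roiMeans(ph@chiPara, ph@rois)
  expect_equal(m[["globus_pallidus_L"]], 132.0, tolerance = 0.05)
  expect_equal(roiMeans(ph@chiDia, ph@rois)[["splenium"]], 35.9,
               tolerance = 0.05)
})

test_that("frequency shift is a zero-mean dipole field", {
  ph <- generatePhantom(smokePhantomConfig(), seed = 2)
  expect_lt(abs(mean(volData(ph@deltaF))), 1e-10)
})

test_that("invalid phantom geometry is rejected", {
  cfg <- smokePhantomConfig()
  cfg$structures$cx[cfg$structures$name == "caudate_L"] <- -10  # onto pallidum
  cfg$structures$cy[cfg$structures$name == "caudate_L"] <- 2
  cfg$structures$cz[cfg$structures$name == "caudate_L"] <- -3
  expect_error(generatePhantom(cfg, seed = 1), "overlapping ROI geometry")
  cfg2 <- smokePhantomConfig()
  cfg2$b1Centre <- 1.9
  expect_error(generatePhantom(cfg2, seed = 1), "dictionary support")
  cfg3 <- smokePhantomConfig(); cfg3$matrixSize <- c(16L, 16L, 16L)
  expect_error(generatePhantom(cfg3, seed = 1), "at least 32")
})

test_that("TSE simulation reaches the ideal CPMG limit at 180 degrees", {
  cfg <- smokePhantomConfig()
  cfg$b1Centre <- 1; cfg$b1Edge <- 1; cfg$b1TiltX <- 0
  cfg$chiTextureFrac <- 0; cfg$r2TextureFrac <- 0
  ph <- generatePhantom(cfg, seed = 1)
  tp <- TSEParams(nominalRefocusingDeg = 180)
  tse <- simulateTse(ph, tp, noiseSd = 0, seed = 1)
  sel <- roiLabels(ph) == roiNames(ph)[["splenium"]]  # T2 = 1000/14 ms
  ratio <- volData(tse$echo2)[sel] / volData(tse$echo1)[sel]
  expect_equal(ratio,
               rep(exp(-(tse$te2Eff - tse$te1Eff) * 14 / 1000), sum(sel)),
               tolerance = 1e-9)
})

test_that("TSE simulation matches the EPG engine voxelwise at 165 deg", {
  cfg <- smokePhantomConfig()
  cfg$chiTextureFrac <- 0; cfg$r2TextureFrac <- 0
  ph <- generatePhantom(cfg, seed = 1)
  tp <- TSEParams()
  tse <- simulateTse(ph, tp, noiseSd = 0, seed = 1)
  i <- which(roiLabels(ph) == roiNames(ph)[["thalamus_L"]])[1]
  b1v <- volData(ph@b1)[i]; t2v <- 1000 / volData(ph@r2)[i]
  oracle <- blochOracle(t2v, max(1000, t2v), b1v, tp)
  idx <- tseEchoIndices(tp)
  expect_equal(volData(tse$echo1)[i], oracle@amplitudes[idx$idx1],
               tolerance = 1e-9)
  expect_equal(volData(tse$echo2)[i], oracle@amplitudes[idx$idx2],
               tolerance = 1e-9)
})

test_that("excessive transmit field is clamped with a message", {
  cfg <- smokePhantomConfig()
  cfg$b1Centre <- 1.15   # 165 * 1.15 > 180
  ph <- generatePhantom(cfg, seed = 1)
  expect_message(simulateTse(ph, TSEParams(), noiseSd = 0, seed = 1),
                 "clamped")
})

test_that("MEGE noise model is complex Gaussian per channel", {
  ph <- generatePhantom(smokePhantomConfig(), seed = 2)
  mg <- simulateMege(ph, MEGEParams(), noiseSd = 0.05, seed = 3)
  out <- !volMask(ph@r2star)
  noise <- mg$signal[, , , 1][out]   # pure noise outside the head
  expect_equal(sd(Re(noise)), 0.05, tolerance = 0.05)
  expect_equal(sd(Im(noise)), 0.05, tolerance = 0.05)
  expect_error(simulateMege(ph, MEGEParams(), noiseSd = -1, seed = 1),
               "negative")
})
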
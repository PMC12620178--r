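test_that("reference dictionary grids have the documented resolution", {
  t2 <- defaultT2Grid(); b1 <- defaultB1Grid()
  expect_equal(length(t2), 19901)           # 10..2000 ms in 0.1 ms steps
  expect_equal(length(b1), 241)             # 0.4..1.6 in 0.005 steps
  expect_equal(range(t2), c(10, 2000))
  expect_equal(range(b1), c(0.4, 1.6))
})

test_that("dictionary build is deterministic and matches the EPG engine", {
  tp <- TSEParams()
  d1 <- buildDictionary(tp, t2Grid = 80, b1Grid = 1)
  d2 <- buildDictionary(tp, t2Grid = 80, b1Grid = 1)
  expect_identical(d1@echo2, d2@echo2)
  idx <- tseEchoIndices(tp)
  tr <- epgTseEchoes(80, 1000, 1, tp)
  expect_equal(d1@echo2[1, 1],
               tr@amplitudes[idx$idx2] / tr@amplitudes[idx$idx1],
               tolerance = 1e-12)
  expect_error(buildDictionary(tp, t2Grid = c(10, 3000)), "2000")
  expect_error(buildDictionary(tp, t2Grid = numeric(0)), "empty")
})

test_that("dictionary fit recovers T2 within one grid step (self-consistency)", {
  tp <- TSEParams()
  t2Grid <- seq(20, 400, by = 0.5)
  b1Grid <- seq(0.7, 1.3, by = 0.01)
  dict <- buildDictionary(tp, t2Grid, b1Grid)
  idx <- tseEchoIndices(tp)
  set.seed(31)
  t2True <- runif(20, 25, 380)
  b1True <- sample(b1Grid, 20, replace = TRUE)
  amps <- t(vapply(seq_along(t2True), function(i)
    epgTseEchoes(t2True[i], 1000, b1True[i], tp)@amplitudes[c(idx$idx1, idx$idx2)],
    numeric(2)))
  dims <- c(20L, 1L, 1L)
  e1 <- ScalarVolume(array(amps[, 1], dims))
  e2 <- ScalarVolume(array(amps[, 2], dims))
  b1v <- ScalarVolume(array(b1True, dims), unit = "relative")
  r2 <- fitR2Dictionary(e1, e2, b1v, dict, noiseFloor = 1e-9)
  t2hat <- 1000 / volData(r2)[, 1, 1]
  expect_true(all(abs(t2hat - t2True) <= 0.5 + 1e-9))  # one grid step
})

test_that("non-decaying ratios pin the fit at the boundary with a flag", {
  tp <- TSEParams()
  dict <- buildDictionary(tp, seq(50, 150, by = 1), 1)
  dims <- c(1L, 1L, 1L)
  r2 <- fitR2Dictionary(ScalarVolume(array(1, dims)),
                        ScalarVolume(array(1.2, dims)),   # ratio > 1
                        ScalarVolume(array(1, dims), unit = "relative"),
                        dict, noiseFloor = 1e-9)
  expect_equal(volData(r2)[1, 1, 1], 1000 / 150)  # longest T2, smallest R2
  expect_gte(attr(r2, "boundary"), 1)
})

test_that("forcing a wrong B1 slice biases the dictionary fit", {
  tp <- TSEParams()
  dict <- buildDictionary(tp, seq(20, 400, by = 0.1),
                          seq(0.7, 1.3, by = 0.005))
  idx <- tseEchoIndices(tp)
  tr <- epgTseEchoes(80, 1000, 0.8, tp)   # truth simulated at B1 = 0.8
  dims <- c(1L, 1L, 1L)
  e1 <- ScalarVolume(array(tr@amplitudes[idx$idx1], dims))
  e2 <- ScalarVolume(array(tr@amplitudes[idx$idx2], dims))
  fitAt <- function(b1) {
    v <- fitR2Dictionary(e1, e2, ScalarVolume(array(b1, dims),
                                              unit = "relative"),
                         dict, noiseFloor = 1e-9)
    volData(v)[1, 1, 1]
  }
  expect_equal(fitAt(0.8), 12.5, tolerance = 0.05)
  # bias magnitude from the independent Bloch oracle: the ratio measured at
  # B1=0.8 read off the B1=1.0 dictionary slice must land on the T2 whose
  # oracle ratio at B1=1 matches the B1=0.8 oracle ratio of T2=80
  ratioTrue <- tr@amplitudes[idx$idx2] / tr@amplitudes[idx$idx1]
  t2grid <- seq(20, 400, by = 0.1)
  oracleRatio <- function(t2) {
    a <- blochOracle(t2, 1000, 1, tp)@amplitudes
    a[idx$idx2] / a[idx$idx1]
  }
  lo <- 20; hi <- 400
  for (i in 1:40) {   # bisection on the monotone oracle ratio
    mid <- (lo + hi) / 2
    if (oracleRatio(mid) < ratioTrue) lo <- mid else hi <- mid
  }
  expect_equal(fitAt(1.0), 1000 / mid, tolerance = 0.02 * 1000 / mid)
})

test_that("two-point exponential fit follows its closed form", {
  tp <- TSEParams(te1 = 83, te2 = 166, echoSpacing = 83, turboFactor = 2L)
  dims <- c(1L, 1L, 1L)
  e1 <- ScalarVolume(array(100, dims))
  e2 <- ScalarVolume(array(36.788, dims))
  r2 <- fitR2Exponential(e1, e2, tp)
  expect_equal(volData(r2)[1, 1, 1], 12.048, tolerance = 1e-3)
  # equal echoes give zero rate; inverted decay clips at zero
  expect_equal(volData(fitR2Exponential(e1, e1, tp))[1, 1, 1], 0)
  e3 <- ScalarVolume(array(120, dims))
  expect_equal(volData(fitR2Exponential(e1, e3, tp))[1, 1, 1], 0)
})

test_that("exponential fit is depressed by stimulated-echo contamination", {
  tp <- TSEParams()
  idx <- tseEchoIndices(tp)
  dte <- (idx$te2Eff - idx$te1Eff) / 1000
  biasAt <- function(t2, b1) {
    a <- epgTseEchoes(t2, 1000, b1, tp)@amplitudes
    fit <- log(a[idx$idx1] / a[idx$idx2]) / dte
    fit - 1000 / t2
  }
  # away from the CPMG condition (effective angle well below 180 deg) the
  # naive fit underestimates R2 for all tissue-like T2
  for (t2 in c(50, 80, 150, 300))
    for (b1 in c(0.7, 0.8, 0.9))
      expect_lt(biasAt(t2, b1), 0)
  # contamination grows as the effective angle departs the CPMG condition
  expect_lt(biasAt(80, 0.7), biasAt(80, 0.85))
  expect_lt(biasAt(80, 0.85), biasAt(80, 0.95))
})

test_that("exponential fit sits below the dictionary fit on reduced-angle data", {
  tp <- TSEParams()
  dict <- buildDictionary(tp, seq(20, 500, by = 0.2),
                          seq(0.6, 1.1, by = 0.005))
  idx <- tseEchoIndices(tp)
  cases <- expand.grid(t2 = c(50, 80, 150, 300), b1 = c(0.7, 0.8, 0.9))
  dims <- c(nrow(cases), 1L, 1L)
  amps <- t(vapply(seq_len(nrow(cases)), function(i)
    epgTseEchoes(cases$t2[i], 1000, cases$b1[i], tp)@amplitudes[c(idx$idx1, idx$idx2)],
    numeric(2)))
  e1 <- ScalarVolume(array(amps[, 1], dims))
  e2 <- ScalarVolume(array(amps[, 2], dims))
  b1v <- ScalarVolume(array(cases$b1, dims), unit = "relative")
  rDict <- volData(fitR2Dictionary(e1, e2, b1v, dict, noiseFloor = 1e-9))
  rExp <- volData(fitR2Exponential(e1, e2, tp))
  expect_true(all(rExp <= rDict + 1e-9))
})

test_that("ARLO recovers noiseless decay rates and the constant limit", {
  mp <- MEGEParams()
  te <- megeEchoTimes(mp) / 1000
  dims <- c(2L, 1L, 1L)
  mag <- array(0, c(dims, 6))
  mag[1, 1, 1, ] <- exp(-20 * te)
  mag[2, 1, 1, ] <- 0.7             # constant magnitude
  r2s <- fitR2Star(mag, mp)
  expect_equal(volData(r2s)[1, 1, 1], 20, tolerance = 0.1)
  expect_equal(volData(r2s)[2, 1, 1], 0, tolerance = 1e-9)
  # log-linear fallback agrees within 2% on noiseless decays
  r2l <- fitR2Star(mag, mp, method = "loglinear")
  expect_equal(volData(r2l)[1, 1, 1], volData(r2s)[1, 1, 1],
               tolerance = 0.02)
  expect_error(fitR2Star(mag[, , , 1:2, drop = FALSE],
                         MEGEParams(nEchoes = 2L)), "3 echoes")
  expect_error(fitR2Star(mag, MEGEParams(nEchoes = 5L)), "match")
})

test_that("ARLO matches a nonlinear least-squares oracle on noisy decays", {
  mp <- MEGEParams()
  te <- megeEchoTimes(mp) / 1000
  set.seed(17)
  n <- 60; r2true <- 25; snr <- 50
  y <- t(replicate(n, exp(-r2true * te) + rnorm(6, sd = 1 / snr)))
  arlo <- volData(fitR2Star(array(abs(y), c(n, 1, 1, 6)), mp))[, 1, 1]
  nlsFit <- vapply(seq_len(n), function(i) {
    df <- data.frame(t = te, s = abs(y[i, ]))
    fit <- try(nls(s ~ a * exp(-r * t), df, start = list(a = 1, r = 20)),
               silent = TRUE)
    if (inherits(fit, "try-error")) NA_real_ else coef(fit)[["r"]]
  }, numeric(1))
  disp <- sd(nlsFit, na.rm = TRUE)
  expect_lt(abs(mean(arlo) - r2true), disp)  # bias within oracle dispersion
  expect_lt(sd(arlo), 2 * disp)
})

test_that("R2-prime construction clips negatives and preserves identities", {
  dims <- c(3L, 1L, 1L)
  r2s <- ScalarVolume(array(c(30, 10, 25), dims), unit = "Hz")
  r2 <- ScalarVolume(array(c(12, 12, 0), dims), unit = "Hz")
  rp <- computeR2Prime(r2s, r2)
  expect_equal(volData(rp)[, 1, 1], c(18, 0, 25))   # clip at zero; identity
  expect_true(all(volData(rp) >= 0))
  expect_error(computeR2Prime(ScalarVolume(array(1, dims), unit = "ppb"),
                              r2), "unit")
})

test_that("R2/R2* ratio behaves and exceeds 0.6 over most of the phantom", {
  dims <- c(2L, 1L, 1L)
  r2 <- ScalarVolume(array(c(12, 20), dims), unit = "Hz")
  r2s <- ScalarVolume(array(c(20, 20), dims), unit = "Hz")
  expect_equal(volData(r2OverR2Star(r2, r2s))[, 1, 1], c(0.6, 1))
  ph <- generatePhantom(smokePhantomConfig(), seed = 6)
  rat <- r2OverR2Star(ph@r2, ph@r2star, volMask(ph@r2))
  expect_gte(median(volData(rat)[volMask(ph@r2)]), 0.6)
})
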
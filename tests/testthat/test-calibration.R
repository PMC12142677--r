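# Drift-time to CCS conversion: default linear chain and multipass chain.

test_that("bins-to-ms and EDC correction follow the instrument formulas", {
  expect_equal(binsToMs(100, 60), 6)
  expect_equal(binsToMs(0, 123), 0)
  expect_equal(binsToMs(55, 64), 3.52)
  expect_equal(edcCorrect(10, 0.1, 400), 8)
  expect_equal(edcCorrect(7.3, 0, 900), 7.3)
  expect_equal(edcCorrect(6, 0.05, 556.2771), 6 - 0.05 * sqrt(556.2771))
  expect_error(edcCorrect(1, 1, 900), "non-positive")
})

test_that("linear calibration recovers exact coefficients and rejects degenerate input", {
  m <- fitLinearCalibration(c(1, 2), c(10, 20))
  expect_equal(calSlope(m), 10)
  expect_equal(calIntercept(m), 0, tolerance = 1e-12)
  tc <- seq(2, 9, length.out = 12)
  m2 <- fitLinearCalibration(tc, 412.3 * tc + 31.7)
  expect_equal(calSlope(m2), 412.3, tolerance = 1e-9)
  expect_equal(calIntercept(m2), 31.7, tolerance = 1e-8)
  expect_error(fitLinearCalibration(1, 2), "at least 2")
  expect_error(fitLinearCalibration(c(3, 3), c(1, 2)), "identical")
})

test_that("noisy linear calibration recovers the slope within 3 SE almost always", {
  set.seed(11)
  truth <- c(m = 380, b = 40)
  hits <- replicate(400, {
    tc <- seq(2, 10, length.out = 8)
    y <- truth["m"] * tc + truth["b"] + rnorm(8, 0, 5)
    fit <- lm(y ~ tc)
    abs(coef(fit)[2] - truth["m"]) <= 3 * summary(fit)$coefficients[2, 2]
  })
  expect_gte(mean(hits), 0.97)
})

test_that("corrected CCS conversion and its inverse round-trip", {
  expect_equal(correctedToCcs(150, 1, 1), 150)
  expect_equal(correctedToCcs(150, 1, 26.5988), 150 * sqrt(1 / 26.5988))
  set.seed(5)
  for (i in 1:20) {
    x <- runif(1, 50, 400); z <- sample(1:3, 1); mu <- runif(1, 10, 30)
    expect_equal(ccsToCorrected(correctedToCcs(x, z, mu), z, mu), x,
                 tolerance = 1e-12)
  }
})

test_that("the full default chain round-trips a known CCS through drift bins", {
  lin <- fitLinearCalibration(c(2, 4, 6, 8), c(800, 1600, 2400, 3200),
                              edcCoefficient = 1.41, pusherPeriod = 64)
  for (ccs in c(180, 250, 320)) {
    bins <- ccsToBins(lin, ccs, mz = 760.6, z = 1)
    expect_equal(defaultCcs(lin, bins, mz = 760.6, z = 1), ccs,
                 tolerance = 1e-9)
  }
  bins2 <- ccsToBins(lin, 300, mz = 450.3, z = 2)
  expect_equal(defaultCcs(lin, bins2, mz = 450.3, z = 2), 300, tolerance = 1e-9)
})

test_that("Gaussian peak fitting recovers apexes and rejects flat signal", {
  t <- seq(15, 25, length.out = 101)
  y <- 3 * exp(-(t - 20)^2 / (2 * 0.5^2))
  fit <- fitGaussianPeak(t, y)
  expect_equal(fit$apex, 20, tolerance = 1e-6)
  expect_equal(fit$width, 0.5, tolerance = 1e-6)
  expect_error(fitGaussianPeak(t, rep(1, length(t))), "flat")
  expect_error(fitGaussianPeak(1:3, c(1, 2, 1)), "at least 5")
  # 5% additive noise: apex recovered well within sigma/5 in >= 95% of runs
  set.seed(21)
  ok <- replicate(200, {
    yn <- y + rnorm(length(t), 0, 0.05 * max(y))
    abs(fitGaussianPeak(t, yn)$apex - 20) < 0.5 / 5
  })
  expect_gte(mean(ok), 0.95)
})

test_that("perturbed-drift regression recovers t_pp and the velocity ratio exactly", {
  st <- passSettings()
  tpp <- 20; vr <- 1.05
  tnd <- st$ts + st$n * tpp - vr * st$ts
  fit <- fitTpp(st$n, st$ts, tnd)
  expect_equal(perturbedDriftTime(fit), tpp, tolerance = 1e-10)
  expect_equal(velocityRatio(fit), vr, tolerance = 1e-10)
  expect_error(fitTpp(1, 15, 40), "at least 2")
  expect_error(fitTpp(c(1, 2), c(10, 20), c(30, 40)), "underdetermined")
})

test_that("power-law calibration is exact on generated data and monotone for B > 0", {
  tpp <- c(5, 8, 12, 17, 23)
  A <- 370; B <- 0.55
  pl <- fitPowerLaw(tpp, A * tpp^B)
  expect_equal(unname(powerLawCoef(pl)), c(A, B), tolerance = 1e-10)
  # B = 1 reduces to proportionality through the log-space origin
  pl1 <- fitPowerLaw(tpp, 42 * tpp)
  expect_equal(powerLawCoef(pl1)[["B"]], 1, tolerance = 1e-10)
  # monotonicity in t_pp
  grid <- seq(2, 30, length.out = 50)
  pred <- multipassCcs(pl, grid, z = 1, mIon = 700)
  expect_true(all(diff(pred) > 0))
  expect_error(fitPowerLaw(c(-1, 2), c(3, 4)), "positive")
})

test_that("percent CCS error matches direct computation", {
  expect_equal(ccsPercentError(202, 200), 1)
  expect_equal(ccsPercentError(200, 200), 0)
  expect_equal(mean(ccsPercentError(c(201, 198), c(200, 200))), 0.75)
  expect_equal(ccsPercentError(198, 200, signed = TRUE), -1)
})
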
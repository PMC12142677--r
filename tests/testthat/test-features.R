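# Feature-table alignment, isotope/charge linking, differential statistics.

test_that("alignment is idempotent on duplicated runs and splits distant features", {
  run <- data.frame(mz = c(400.1, 500.2, 600.3), drift = c(20, 60, 100),
                    intensity = c(10, 20, 30))
  tab <- alignFeatures(list(a = run, b = run))
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$nMembers == 2))
  two <- data.frame(mz = c(500.00, 500.05), drift = c(50, 50),
                    intensity = c(5, 5))
  expect_identical(nrow(alignFeatures(list(two))), 2L)
})

test_that("alignment conserves features and recovers the simulated ground truth", {
  nRecovered <- sapply(1:10, function(s) {
    st <- simulateFeatureStudy(nFeatures = 50, nPerGroup = 2, effectFraction = 0,
                               isotopeFraction = 0, doublyChargedPairs = 0,
                               mzJitterSd = 0.005, driftJitterSd = 0.4, seed = s)
    tab <- alignFeatures(st$runs[1:3])
    expect_identical(sum(tab$nMembers), nrow(st$truth) * 3L)
    nrow(tab)
  })
  expect_gte(mean(nRecovered == 50), 0.9)
})

test_that("isotope flagging matches constructed pairs and stays acyclic", {
  tab <- data.frame(mz = c(500.000, 501.0034, 502.0067, 700.0),
                    drift = c(50, 50, 50, 90),
                    intensity = c(100, 30, 9, 50))
  fl <- flagIsotopes(tab)
  expect_identical(fl$flag, c("analyte", "isotope", "isotope", "analyte"))
  expect_identical(fl$parent, c(NA_integer_, 1L, 2L, NA_integer_))
  # drift-separated pair is not flagged
  apart <- data.frame(mz = c(500.000, 501.0034), drift = c(50, 55),
                      intensity = c(100, 30))
  expect_true(all(flagIsotopes(apart)$flag == "analyte"))
  # parent links are acyclic and no chain exceeds the configured depth
  chain <- data.frame(mz = 500 + (0:4) * 1.003355, drift = 50,
                      intensity = 100 * 0.5^(0:4))
  fl2 <- flagIsotopes(chain, maxDepth = 2)
  depthOf <- function(i) {
    d <- 0
    while (!is.na(fl2$parent[i])) { i <- fl2$parent[i]; d <- d + 1 }
    d
  }
  expect_lte(max(vapply(seq_len(nrow(fl2)), depthOf, numeric(1))), 2)
})

test_that("isotope flagging on simulated studies is sensitive and specific", {
  sens <- fp <- numeric(20)
  for (s in 1:20) {
    st <- simulateFeatureStudy(nFeatures = 60, isotopeFraction = 0.25,
                               doublyChargedPairs = 0, effectFraction = 0,
                               seed = s)
    tab <- st$truth[c("mz", "drift", "z")]
    tab$intensity <- rowMeans(st$intensities)
    fl <- flagIsotopes(tab)
    isIso <- st$truth$kind == "isotope"
    sens[s] <- mean(fl$flag[isIso] == "isotope")
    fp[s] <- mean(fl$flag[!isIso] == "isotope")
  }
  expect_gte(mean(sens), 0.95)
  expect_lte(mean(fp), 0.02)
})

test_that("doubly charged partners are linked by the half-mass-plus-proton relation", {
  res <- linkMultiplyCharged(529.3989, 265.2030)
  expect_true(res$linked)
  expect_equal(round(res$residualPpm, 1), -1.4)
  expect_false(linkMultiplyCharged(529.3989, 270.0)$linked)
  exact <- (700 + 1.00782503207) / 2
  expect_equal(linkMultiplyCharged(700, exact)$residualPpm, 0)
  st <- simulateFeatureStudy(nFeatures = 20, doublyChargedPairs = 2,
                             isotopeFraction = 0, seed = 6)
  dc <- st$truth[st$truth$kind == "doubly_charged", ]
  for (i in seq_len(nrow(dc))) {
    expect_true(linkMultiplyCharged(st$truth$mz[dc$pair[i]], dc$mz[i])$linked)
  }
})

test_that("spatial correlation behaves on identical, inverted and noisy images", {
  img <- matrix(runif(100), 10)
  expect_equal(spatialCorrelation(img, img), 1)
  expect_equal(spatialCorrelation(img, -img), -1)
  expect_error(spatialCorrelation(img, matrix(1, 10, 10)), "constant")
  expect_error(spatialCorrelation(img, matrix(0.5, 5, 5)), "different")
  set.seed(9)
  pattern <- outer(sin(seq(0, pi, length.out = 30)),
                   cos(seq(0, pi, length.out = 30)))
  n1 <- pattern + rnorm(900, 0, sd(pattern) / sqrt(10))
  n2 <- pattern + rnorm(900, 0, sd(pattern) / sqrt(10))
  expect_gt(spatialCorrelation(n1, n2), 0.9)
})

test_that("differential filter applies fold-change and p-value cutoffs", {
  x <- data.frame(c1 = c(10, 10), c2 = c(11, 10.5), c3 = c(9, 9.4), c4 = c(10, 10.2),
                  t1 = c(10, 1), t2 = c(10.5, 1.1), t3 = c(9.6, 0.95), t4 = c(10.1, 1.0))
  g <- setNames(rep(c("control", "tumor"), each = 4), names(x))
  res <- differentialFilter(x, g)
  expect_false(res$stats$kept[1])   # FC = 1
  expect_true(res$stats$kept[2])    # 10x shift, tiny variance
  expect_equal(res$stats$fc[2], 10, tolerance = 0.15)
  expect_error(differentialFilter(x[, c(1, 2, 5)],
               setNames(c("control", "control", "tumor"), names(x)[c(1, 2, 5)])),
               ">= 2 samples")
})

test_that("differential filter is invariant to global rescaling and monotone in thresholds", {
  st <- simulateFeatureStudy(nFeatures = 120, effectFraction = 0.2, seed = 13)
  tab <- as.data.frame(st$intensities)
  g <- setNames(st$samples$group, st$samples$sample)
  r1 <- differentialFilter(tab, g)
  r2 <- differentialFilter(tab * 1e3, g)
  expect_equal(r1$stats$p, r2$stats$p, tolerance = 1e-12)
  expect_identical(r1$stats$kept, r2$stats$kept)
  # relaxing either threshold never drops a kept feature
  rLoose <- differentialFilter(tab, g, fcThreshold = 1.2, pThreshold = 0.2)
  expect_true(all(!r1$stats$kept | rLoose$stats$kept))
})

test_that("planted strong effects are recovered and volcano classes split correctly", {
  st <- simulateFeatureStudy(nFeatures = 100, effectFraction = 0.1,
                             effectSize = 10, intensitySdLog = 0.1, seed = 17)
  tab <- as.data.frame(st$intensities)
  g <- setNames(st$samples$group, st$samples$sample)
  res <- differentialFilter(tab, g)
  expect_true(all(res$stats$kept[st$truth$effect]))
  v <- volcanoData(res$stats)
  expect_true(all(v$class[st$truth$effect & st$truth$fc > 1] == "up"))
  expect_identical(volcanoData(data.frame(fc = 1, p = 1))$class, "ns")
  expect_identical(volcanoData(data.frame(fc = 8.3, p = 0.009))$class, "up")
  expect_identical(volcanoData(data.frame(fc = 4, p = 0.2))$class, "ns")
})

test_that("background removal excludes listed m/z within tolerance", {
  tab <- data.frame(mz = c(400.0000, 400.0080, 500.0), intensity = 1:3)
  out <- removeBackground(tab, exclusionMz = 400.0, ppmTol = 10)
  expect_identical(out$mz, c(400.0080, 500.0))
  flagged <- removeBackground(tab, 400.0, ppmTol = 10, drop = FALSE)
  expect_identical(flagged$flag, c("background", "analyte", "analyte"))
})
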
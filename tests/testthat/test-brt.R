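test_that("deviance statistics follow the loss definitions", {
  expect_equal(devianceStat(c(3, 7), c(3, 7), "poisson"), 0)
  expect_equal(devianceStat(c(1, 2), c(1, 2), "gaussian"), 0)
  expect_equal(devianceStat(c(0, 2), c(1, 1), "gaussian"), 1)
  expect_equal(devianceStat(c(1, 2), c(1, 1), "poisson"),
               (2 * (2 * log(2) - 1)) / 2, tolerance = 1e-12)
  expect_error(devianceStat(c(1, 2), c(0, 1), "poisson"), "positive")
  expect_equal(devianceExplained(3.976, 1.578), 60.3, tolerance = 0.05)
})

test_that("boosting on a constant response stays at the baseline", {
  set.seed(1)
  X <- as.data.frame(matrix(rnorm(200), 40, 5))
  y <- rep(5, 40)
  m <- fitBRT(X, y, brtConfig("gaussian", learningRate = 0.1), nTrees = 50,
              seed = 3)
  expect_equal(predict(m, X), rep(5, 40), tolerance = 1e-8)
  mp <- fitBRT(X, y, brtConfig("poisson", learningRate = 0.1), nTrees = 50,
               seed = 3)
  expect_equal(predict(mp, X), rep(5, 40), tolerance = 1e-6)
})

test_that("training deviance is non-increasing over stages", {
  set.seed(2)
  X <- as.data.frame(matrix(rnorm(600), 100, 6))
  y <- X[[1]] - 2 * X[[2]] + rnorm(100, 0, 0.3)
  cfg <- brtConfig("gaussian", learningRate = 0.05)
  m <- fitBRT(X, y, cfg, nTrees = 300, seed = 5)
  devAt <- vapply(c(25, 50, 100, 200, 300), function(k)
    devianceStat(y, predict(m, X, nTrees = k), "gaussian"), numeric(1))
  expect_true(all(diff(devAt) <= 1e-9))
})

test_that("a simple linear signal is learned out of sample", {
  set.seed(3)
  n <- 200
  X <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  y <- 2 * X[[1]] + rnorm(n, 0, 0.5)
  train <- 1:150
  m <- fitBRT(X[train, ], y[train], brtConfig("gaussian", learningRate = 0.02),
              nTrees = 800, seed = 7)
  mseHeld <- mean((y[-train] - predict(m, X[-train, ]))^2)
  expect_lt(mseHeld, var(y[-train]))
})

test_that("fits are deterministic in the seed", {
  set.seed(4)
  X <- as.data.frame(matrix(rnorm(300), 60, 5))
  y <- rpois(60, exp(0.5 + 0.4 * X[[2]]))
  cfg <- brtConfig("poisson", learningRate = 0.05)
  m1 <- fitBRT(X, y, cfg, nTrees = 120, seed = 11)
  m2 <- fitBRT(X, y, cfg, nTrees = 120, seed = 11)
  expect_identical(m1@trees, m2@trees)
  expect_identical(m1@varImprovement, m2@varImprovement)
  expect_error(fitBRT(X, y - 1, cfg, nTrees = 10), "non-negative")
})

test_that("relative influence is a percentage split over used predictors", {
  set.seed(5)
  n <- 150
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  X$unused <- 0  # constant column can never be split on
  y <- 3 * X[[1]] + rnorm(n, 0, 0.2)
  m <- fitBRT(X, y, brtConfig("gaussian", learningRate = 0.05), nTrees = 300,
              seed = 13)
  infl <- relativeInfluence(m)
  expect_equal(sum(infl$influence), 100, tolerance = 1e-6)
  expect_true(all(infl$influence >= 0))
  expect_equal(infl$variable[1], "V1")
  expect_equal(infl$influence[infl$variable == "unused"], 0)
  cats <- setNames(c("a", "a", "b", "b", "b", "b", "c"), names(X))
  withCat <- relativeInfluence(m, cats)
  expect_equal(sum(attr(withCat, "categoryInfluence")), 100,
               tolerance = 1e-6)
})

test_that("cross-validation selects trees and reports the evaluation", {
  set.seed(6)
  n <- 120
  X <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  y <- X[[1]]  # perfect predictor, no noise
  sel <- suppressWarnings(selectNTreesCV(
    X, y, brtConfig("gaussian", learningRate = 0.05), maxTrees = 1500,
    seed = 17))
  expect_gt(sel$evaluation$cvDevianceExplained, 85)
  expect_gt(sel$evaluation$cvCorrelation, 0.9)
  expect_equal(sel$evaluation$trainingDevianceExplained,
               devianceExplained(sel$evaluation$meanNullDeviance,
                                 devianceStat(y, predict(sel$model, X),
                                              "gaussian")),
               tolerance = 1e-8)
  expect_true(sel$nTrees %% 50 == 0 || sel$nTrees == 1500)
  # the under-1000-trees advisory fires with a fast learning rate
  expect_warning(selectNTreesCV(X, y,
                                brtConfig("gaussian", learningRate = 0.5),
                                maxTrees = 200, seed = 18),
                 "lowering the learning rate")
})

test_that("predictor assembly follows the model-variant rules", {
  set.seed(7)
  t <- data.frame(site_id = paste0("s", 1:12),
                  catchment_size = runif(12, 3, 900),
                  elevation = runif(12, 100, 400),
                  landuse_agriculture = runif(12, 0, 100),
                  landuse_forest = runif(12, 0, 100),
                  chem_chloride = runif(12, 10, 200),
                  x = runif(12, 0, 1e5), y = runif(12, 0, 1e5),
                  drainage = rep(c("north", "south"), 6))
  Xall <- assemblePredictors(t, section = "all")
  expect_true("catchment_size" %in% names(Xall))
  Xhead <- assemblePredictors(t, section = "headwaters")
  expect_false("catchment_size" %in% names(Xhead))
  expect_false(any(c("x", "y", "site_id", "drainage") %in% names(Xhead)))

  pc <- pcoaVectors(geographicDistances(t))
  Xsp <- assemblePredictors(t, pcoa = pc, section = "all")
  expect_equal(ncol(Xsp), ncol(Xall) + 2)
  expect_true(all(c("PCo1", "PCo2") %in% names(Xsp)))
  cats <- attr(Xsp, "categories")
  expect_equal(unname(cats[c("catchment_size", "landuse_forest",
                             "chem_chloride", "PCo1")]),
               c("physical", "land use", "chemical", "spatial"))
  Xd <- assemblePredictors(t, section = "all", includeDrainage = TRUE)
  expect_s3_class(Xd$drainage, "factor")
})
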
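test_that("embedded absences match the exhaustive gap-scan oracle", {
  expect_equal(countEmbeddedAbsences(
    IncidenceMatrix(matrix(c(1, 0, 1), 3, 1)), mode = "columns"), 1)
  expect_equal(countEmbeddedAbsences(IncidenceMatrix(matrix(1, 4, 3))), 0)
  b <- matrix(0, 5, 5)
  for (j in 1:5) b[j, j] <- 1
  for (j in 1:4) b[j + 1, j] <- 1
  expect_equal(countEmbeddedAbsences(IncidenceMatrix(b)), 0)  # banded
  for (seed in 1:20) {
    X <- randomIncidence(10, 8, seed = 200 + seed)
    m <- IncidenceMatrix(X)
    expect_equal(countEmbeddedAbsences(m), oracleAbs(X))
    expect_equal(countEmbeddedAbsences(m, mode = "columns"),
                 oracleAbs(X, mode = "columns"))
  }
  # empty input is rejected (at construction already)
  expect_error(countEmbeddedAbsences(IncidenceMatrix(matrix(numeric(0),
                                                            0, 0))))
})

test_that("range filling is column-wise, idempotent and minimal", {
  m <- IncidenceMatrix(matrix(c(1, 0, 1), 3, 1))
  expect_equal(unname(as.matrix(fillRanges(m))), matrix(1, 3, 1))
  coherent <- IncidenceMatrix(matrix(c(0, 1, 1, 1, 1, 0), 3, 2))
  expect_identical(as.matrix(fillRanges(coherent)), as.matrix(coherent))
  for (seed in 1:10) {
    X <- randomIncidence(9, 6, seed = 300 + seed)
    f <- fillRanges(IncidenceMatrix(X))
    expect_identical(as.matrix(f), oracleFill(X))
    expect_identical(as.matrix(fillRanges(f)), as.matrix(f))
    expect_equal(countEmbeddedAbsences(f, mode = "columns"), 0)
    expect_true(all(as.matrix(f) >= X))  # presences never removed
  }
})

test_that("replacements match the quadruple-loop oracle", {
  nested <- IncidenceMatrix(cbind(c(1, 1, 1, 1), c(1, 1, 1, 0),
                                  c(1, 1, 0, 0), c(1, 0, 0, 0)))
  expect_equal(countReplacements(nested), 0)
  checker <- IncidenceMatrix(rbind(c(1, 0), c(0, 1)))
  expect_equal(countReplacements(checker), 1)
  for (seed in 1:8) {
    X <- oracleFill(randomIncidence(8, 6, seed = 400 + seed))
    expect_equal(countReplacements(IncidenceMatrix(X)), oracleRe(X))
  }
})

test_that("z tests reproduce every printed coherence and turnover z", {
  for (row in printedEMSRows()) {
    co <- zTest(row$abs[1], list(mean = row$abs[2], sd = row$abs[3]),
                "embedded_absences")
    expect_equal(co@z, row$z_abs, tolerance = 0.01)
    tu <- zTest(row$re[1], list(mean = row$re[2], sd = row$re[3]),
                "replacements")
    expect_equal(tu@z, row$z_re, tolerance = 0.011)
  }
  exact <- zTest(100, list(mean = 100, sd = 5))
  expect_equal(exact@z, 0)
  expect_equal(exact@p, 1)
  expect_error(zTest(5, rep(3, 10)), "SD")
  emp <- zTest(10, c(12, 14, 16, 18))
  expect_equal(emp@z, (15 - 10) / sd(c(12, 14, 16, 18)))
})

test_that("boundary counts match the index-scan oracle", {
  one <- IncidenceMatrix(matrix(1, 5, 1))
  expect_equal(boundaryCounts(one), c(1, 0, 0, 0, 1))
  same <- IncidenceMatrix(matrix(c(0, 1, 1, 0), 4, 3))
  expect_equal(boundaryCounts(same), c(0, 3, 3, 0))
  for (seed in 1:10) {
    X <- randomIncidence(8, 6, seed = 500 + seed)
    n <- boundaryCounts(IncidenceMatrix(X))
    expect_equal(n, oracleBoundaries(X))
    expect_equal(sum(n), 2 * ncol(X))
  }
  # excluding edge-touching boundaries drops the margins
  edge <- IncidenceMatrix(cbind(c(1, 1, 0), c(0, 1, 1)))
  expect_equal(sum(boundaryCounts(edge, excludeEdges = TRUE)), 2)
})

test_that("Morisita's index matches the direct formula", {
  allAtOne <- c(8, 0, 0, 0)
  r <- morisitaClumping(allAtOne)
  expect_equal(r@morisita, 4)  # maximal clumping: MI = T
  expect_equal(morisitaClumping(rep(1, 6))@morisita, 0)
  for (seed in 1:10) {
    set.seed(600 + seed)
    n <- rpois(7, 3) + c(1, rep(0, 6))
    got <- morisitaClumping(n)
    expect_equal(got@morisita, oracleMorisita(n))
    expN <- sum(n) / 7
    expect_equal(got@chi2, sum((n - expN)^2 / expN))
    expect_identical(got@df, 6L)
  }
  expect_error(morisitaClumping(c(1, 0, 0)), "two boundaries")
})

test_that("the taxonomy yields exactly 14 reachable labels", {
  sig <- 0.001
  ns <- 0.5
  mk <- function(stat, z, p) {
    obs <- 100
    new("EMSTestResult", statisticName = stat, observed = obs,
        nullMean = obs + z * 10, nullSD = 10, z = z, p = p, nNull = 100L)
  }
  labels <- character(0)
  for (cohSig in c(TRUE, FALSE)) for (cohPos in c(TRUE, FALSE))
    for (turnSig in c(TRUE, FALSE)) for (turnPos in c(TRUE, FALSE))
      for (clumpCase in c("clumped", "indistinct", "hyperdispersed")) {
        coh <- mk("embedded_absences", if (cohPos) 3 else -3,
                  if (cohSig) sig else ns)
        turn <- mk("replacements", if (turnPos) -3 else 3,
                   if (turnSig) sig else ns)
        clump <- switch(clumpCase,
          clumped = clumpingFromSummary(2.5, sig),
          indistinct = clumpingFromSummary(1.1, ns),
          hyperdispersed = clumpingFromSummary(0.4, sig))
        labels <- c(labels, classifyStructure(coh, turn, clump, 0.05))
      }
  expect_setequal(unique(labels), structureLabels())
  expect_length(structureLabels(), 14)
})

test_that("taxonomy rules are applied as stated", {
  sig <- 1e-4
  coh_pos <- zTest(100, list(mean = 150, sd = 10), "embedded_absences")
  coh_neg <- zTest(200, list(mean = 150, sd = 10), "embedded_absences")
  coh_ns <- zTest(149, list(mean = 150, sd = 10), "embedded_absences")
  turn_neg <- zTest(500, list(mean = 900, sd = 50), "replacements")  # nested
  clump_pos <- clumpingFromSummary(2.9, sig)
  expect_equal(classifyStructure(coh_ns, NULL, NULL), "Random")
  expect_equal(classifyStructure(coh_neg, NULL, NULL), "Checkerboard")
  expect_equal(classifyStructure(coh_pos, turn_neg, clump_pos),
               "Nested - clumped species loss")
})

test_that("printed component outcomes reproduce the printed labels", {
  for (row in printedEMSRows()) {
    coh <- zTest(row$abs[1], list(mean = row$abs[2], sd = row$abs[3]),
                 "embedded_absences")
    turn <- zTest(row$re[1], list(mean = row$re[2], sd = row$re[3]),
                  "replacements")
    clump <- clumpingFromSummary(row$mi, row$mi_p)
    expect_equal(classifyStructure(coh, turn, clump, 0.05), row$label)
  }
})

test_that("EMS statistics are invariant to reversing the ordering", {
  for (seed in 1:5) {
    X <- randomIncidence(10, 8, seed = 700 + seed)
    m <- IncidenceMatrix(X)
    ra <- reciprocalAveraging(m)
    om <- as.matrix(orderMatrix(m, ra, axis = 1))
    variants <- list(om, om[nrow(om):1, ], om[, ncol(om):1],
                     om[nrow(om):1, ncol(om):1])
    absVals <- vapply(variants, function(v)
      countEmbeddedAbsences(IncidenceMatrix(v)), numeric(1))
    reVals <- vapply(variants, function(v)
      countReplacements(fillRanges(IncidenceMatrix(v))), numeric(1))
    expect_equal(max(absVals) - min(absVals), 0)
    expect_equal(max(reVals) - min(reVals), 0)
  }
})

test_that("evaluateAxis classifies a clean compartmented metacommunity", {
  cfg <- syntheticConfig("clementsian", nSites = 30, nTaxa = 24,
                         noiseEps = 0, seed = 77)
  sim <- simulateMetacommunity(cfg)
  m <- dropEmptySites(filterRareTaxa(sim$incidence))
  cl <- evaluateAxis(m, axis = 1, nSim = 100, seed = 42)
  expect_s4_class(cl, "StructureClassification")
  expect_equal(cl@label, "Clementsian")
  expect_gt(cl@coherence@z, 2)
  expect_lt(cl@turnover@z, -2)
  expect_gt(cl@clumping@morisita, 1)
  # a shared ensemble gives identical results to an internally generated one
  ens <- generateR1(m, 100, seed = 42)
  cl2 <- evaluateAxis(m, axis = 1, ensemble = ens)
  expect_equal(cl2@label, cl@label)
  expect_equal(cl2@coherence@z, cl@coherence@z)
})

test_that("the EMS table mirrors the standard report layout", {
  cfg <- syntheticConfig("clementsian", nSites = 24, nTaxa = 18,
                         noiseEps = 0, seed = 5)
  sim <- simulateMetacommunity(cfg)
  m <- dropEmptySites(filterRareTaxa(sim$incidence))
  ens <- generateR1(m, 60, seed = 2)
  cls <- lapply(1:2, function(ax) evaluateAxis(m, axis = ax, ensemble = ens))
  tab <- emsTable(cls, labels = c("all", "all"))
  expect_named(tab, c("set", "axis", "Abs", "Abs_mean", "Abs_SD", "Abs_z",
                      "Abs_p", "Re", "Re_mean", "Re_SD", "Re_z", "Re_p",
                      "MI", "MI_p", "structure"))
  expect_equal(nrow(tab), 2)
})
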
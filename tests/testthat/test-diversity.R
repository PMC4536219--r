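abund <- function(X) {
  dimnames(X) <- list(paste0("s", seq_len(nrow(X))),
                      paste0("t", seq_len(ncol(X))))
  AbundanceMatrix(X)
}

test_that("richness counts occupied taxa per site", {
  a <- abund(rbind(c(3, 0, 1), c(0, 0, 0), c(2, 2, 2)))
  expect_equal(unname(richness(a)), c(2, 0, 3))
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rpois(40, 1), 8, 5)
    expect_equal(unname(richness(abund(X))),
                 apply(X, 1, function(v) sum(v > 0)))
  }
})

test_that("rarefied richness follows the hypergeometric expectation", {
  # a site with exactly n individuals keeps its observed richness
  a <- abund(rbind(c(60, 40), c(50, 50)))
  rr <- rarefiedRichness(a, n = 100)
  expect_equal(as.vector(rr), c(2, 2))
  # single taxon: always 1
  expect_equal(as.vector(rarefiedRichness(abund(matrix(500, 1, 1)), 100)), 1)
  # two equal taxa, n = 1 draws exactly one taxon
  expect_equal(as.vector(rarefiedRichness(abund(matrix(c(50, 50), 1, 2)), 1)),
               1)
  # matches a 10,000-draw subsampling simulation
  counts <- c(120, 40, 25, 10, 3, 2)
  got <- as.vector(rarefiedRichness(abund(matrix(counts, 1)), 100))
  expect_equal(got, oracleRarefy(counts, 100), tolerance = 0.05)
  # small sites are flagged and fall back to observed richness
  small <- abund(matrix(c(5, 3, 0, 2), 2, 2))
  expect_warning(rs <- rarefiedRichness(small, n = 100), "flagged")
  expect_equal(as.vector(rs), c(1, 2))
  expect_true(all(attr(rs, "flagged")))
  # monotone non-decreasing in n
  vals <- vapply(c(5, 20, 50, 100, 150),
                 function(n) as.vector(rarefiedRichness(
                   abund(matrix(counts, 1)), n)), numeric(1))
  expect_true(all(diff(vals) >= -1e-9))
  expect_error(rarefiedRichness(a, n = 0), "positive")
})

test_that("Simpson's index matches its formula", {
  expect_equal(unname(simpsonIndex(abund(matrix(17, 1, 1)))), 0)
  expect_equal(unname(simpsonIndex(abund(matrix(c(50, 50), 1, 2)))), 0.5)
  for (seed in 1:5) {
    set.seed(seed)
    v <- rpois(6, 5) + 1
    p <- v / sum(v)
    expect_equal(unname(simpsonIndex(abund(matrix(v, 1)))), 1 - sum(p^2))
  }
  withEmpty <- abund(rbind(c(1, 1), c(0, 0)))
  expect_warning(s <- simpsonIndex(withEmpty), "undefined")
  expect_true(is.na(s[2]))
})

test_that("Bray-Curtis behaves at its extremes", {
  same <- abund(rbind(c(3, 1, 0), c(3, 1, 0)))
  expect_equal(as.numeric(brayCurtis(same)), 0)
  disjoint <- abund(rbind(c(5, 0), c(0, 7)))
  expect_equal(as.numeric(brayCurtis(disjoint)), 1)
  half <- abund(rbind(c(1, 1, 0), c(0, 1, 1)))
  expect_equal(as.numeric(brayCurtis(half)), 0.5)
  expect_error(brayCurtis(abund(rbind(c(1, 1), c(0, 0)))), "empty")
})

test_that("beta dispersion measures distance to group centroid", {
  # identical sites within a group sit on their centroid
  X <- rbind(c(5, 1, 0), c(5, 1, 0), c(0, 2, 8), c(0, 2, 8))
  bd <- betaDispersion(brayCurtis(abund(X)), c("a", "a", "b", "b"))
  expect_equal(unname(bd$distances), rep(0, 4), tolerance = 1e-10)

  # with Euclidean distances, equals distance to the arithmetic centroid
  set.seed(31)
  pts <- matrix(rnorm(24), 12, 2)
  grp <- rep(c("g1", "g2"), each = 6)
  bd2 <- betaDispersion(dist(pts), grp)
  manual <- vapply(1:12, function(i) {
    ctr <- colMeans(pts[grp == grp[i], , drop = FALSE])
    sqrt(sum((pts[i, ] - ctr)^2))
  }, numeric(1))
  expect_equal(unname(bd2$distances), manual, tolerance = 1e-8)

  # permuting site order leaves per-site distances unchanged
  set.seed(32)
  perm <- sample(12)
  bd3 <- betaDispersion(dist(pts[perm, ]), grp[perm])
  expect_equal(unname(bd3$distances), manual[perm], tolerance = 1e-8)

  expect_error(betaDispersion(dist(pts), c("a", rep("b", 11))), "two sites")
})

test_that("one-way ANOVA with Tukey letters matches hand computation", {
  # hand-worked three-group ANOVA table
  vals <- c(6, 8, 4, 5, 3, 4, 8, 12, 9, 11, 6, 8, 13, 9, 11, 8, 7, 12)
  grp <- rep(c("g1", "g2", "g3"), each = 6)
  k <- 3; N <- 18
  means <- tapply(vals, grp, mean)
  ssb <- sum(6 * (means - mean(vals))^2)
  ssw <- sum((vals - means[grp])^2)
  Fhand <- (ssb / (k - 1)) / (ssw / (N - k))
  got <- anovaTukey(vals, grp)
  expect_equal(got$F, Fhand, tolerance = 1e-6)
  expect_equal(c(got$df1, got$df2), c(2, 15))

  # two groups: F equals the squared pooled-variance t statistic
  v2 <- c(1.2, 2.3, 1.8, 2.9, 4.1, 3.3, 5.0, 4.2)
  g2 <- rep(c("a", "b"), each = 4)
  tt <- t.test(v2 ~ g2, var.equal = TRUE)
  got2 <- anovaTukey(v2, g2)
  expect_equal(got2$F, unname(tt$statistic)^2, tolerance = 1e-8)

  # identical groups: F ~ 0, no pair separated, all letters shared
  v3 <- rep(c(1, 2, 3), 3)
  g3 <- rep(c("a", "b", "c"), each = 3)
  got3 <- anovaTukey(v3, g3)
  expect_lt(got3$F, 1e-10)
  expect_true(all(got3$tukey$p_adj > 0.99))
  expect_equal(unname(got3$letters), rep("a", 3))

  # well-separated groups get distinct letters
  set.seed(51)
  v4 <- c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1), rnorm(5, 20, 0.1))
  g4 <- rep(c("a", "b", "c"), each = 5)
  expect_equal(length(unique(anovaTukey(v4, g4)$letters)), 3)
  expect_error(anovaTukey(rep(1, 6), rep(c("a", "b"), 3)), "variance")
})

test_that("diversity summary assembles the per-site table", {
  set.seed(41)
  X <- matrix(rpois(60, 8), 10, 6)
  X[1, ] <- c(200, 100, 50, 10, 5, 1)
  a <- abund(X)
  sec <- factor(rep(c("headwaters", "large"), 5))
  names(sec) <- siteIDs(a)
  tab <- suppressWarnings(diversitySummary(a, sec))
  expect_named(tab, c("site_id", "richness", "rarefied_richness",
                      "rarefied_flagged", "simpson", "section"))
  expect_true(all(tab$rarefied_richness <= tab$richness + 1e-9))
  expect_true(all(tab$simpson >= 0 & tab$simpson < 1))
})
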
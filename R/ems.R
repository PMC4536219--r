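## Elements of Metacommunity Structure: coherence (embedded absences),
## species turnover (replacements), boundary clumping (Morisita), z tests
## against the r1 null ensemble, and the 14-label structure taxonomy.

## -- bare-matrix kernels (also used in the per-null hot loop) ----------------

## first/last presence index per column of a binary matrix (0 rows excluded
## by callers); max.col on 0/1 columns returns the first maximum = first 1.
.colRange <- function(X) {
  tX <- t(X)
  first <- max.col(tX, ties.method = "first")
  last <- nrow(X) + 1L - max.col(tX[, rev(seq_len(nrow(X))), drop = FALSE],
                                 ties.method = "first")
  cs <- colSums(X)
  first[cs == 0] <- NA_integer_
  last[cs == 0] <- NA_integer_
  list(first = first, last = last, size = cs)
}

.absCore <- function(X, mode = "both") {
  cr <- .colRange(X)
  colAbs <- sum(cr$last - cr$first + 1 - cr$size, na.rm = TRUE)
  if (mode == "columns") return(colAbs)
  rr <- .colRange(t(X))
  colAbs + sum(rr$last - rr$first + 1 - rr$size, na.rm = TRUE)
}

.fillCore <- function(X) {
  cr <- .colRange(X)
  n <- nrow(X)
  k <- ncol(X)
  idx <- matrix(seq_len(n), n, k)
  lo <- matrix(cr$first, n, k, byrow = TRUE)
  hi <- matrix(cr$last, n, k, byrow = TRUE)
  out <- 1 * (idx >= lo & idx <= hi)
  out[is.na(out)] <- 0
  dimnames(out) <- dimnames(X)
  out
}

.reCore <- function(A) {
  C <- crossprod(A)                  # co-occurrence counts
  n <- colSums(A)
  only <- matrix(n, length(n), length(n)) - C   # [i, j] = sites with i only
  sum(only * t(only)) / 2
}

.boundaryCore <- function(X, excludeEdges = FALSE) {
  cr <- .colRange(X)
  n <- nrow(X)
  f <- cr$first[!is.na(cr$first)]
  l <- cr$last[!is.na(cr$last)]
  if (excludeEdges) {
    f <- f[f > 1L]
    l <- l[l < n]
  }
  tabulate(f, nbins = n) + tabulate(l, nbins = n)
}

## -- exported operations -----------------------------------------------------

#' Count embedded absences (the coherence statistic)
#'
#' An embedded absence is a zero lying strictly inside a taxon's range (the
#' span between its first and last presence down the ordered sites) or,
#' symmetrically, inside a site's range across the ordered taxa. Fewer
#' embedded absences than the null expectation means coherent structure; more
#' means checkerboard.
#'
#' @param m an ordered [IncidenceMatrix-class] (see [orderMatrix()]).
#' @param mode count gaps in both taxon and site ranges (`"both"`, default)
#'   or in taxon columns only.
#' @return integer count.
#' @examples
#' m <- IncidenceMatrix(rbind(c(1, 1), c(0, 1), c(1, 1)))
#' countEmbeddedAbsences(m)  # the column gap at site 2
#' @export
countEmbeddedAbsences <- function(m, mode = c("both", "columns")) {
  stopifnot(is(m, "IncidenceMatrix"))
  mode <- match.arg(mode)
  if (nSites(m) == 0 || nTaxa(m) == 0) stop("empty matrix")
  .absCore(m@mat, mode)
}

#' Fill taxon ranges
#'
#' Makes every taxon's column continuous between its first and last presence
#' (embedded absences become 1); presences are never removed. Turnover and
#' boundary clumping are defined on these range-filled matrices.
#'
#' @param m an ordered [IncidenceMatrix-class].
#' @return the range-filled [IncidenceMatrix-class].
#' @export
fillRanges <- function(m) {
  stopifnot(is(m, "IncidenceMatrix"))
  IncidenceMatrix(.fillCore(m@mat))
}

#' Count species replacements (the turnover statistic)
#'
#' For every unordered pair of taxa, the number of sites holding only the
#' first times the number holding only the second, summed over pairs: how
#' often one species replaces another between sites. Computed on range-filled
#' matrices; nested matrices give 0.
#'
#' @param m a range-filled [IncidenceMatrix-class] (see [fillRanges()]).
#' @return numeric count.
#' @export
countReplacements <- function(m) {
  stopifnot(is(m, "IncidenceMatrix"))
  .reCore(m@mat)
}

#' Range-boundary counts per site position
#'
#' The number of taxon range edges (first and last presences) falling at each
#' ordered site position. Every taxon contributes exactly two edges, so the
#' counts sum to twice the number of (non-empty) taxa, unless edges touching
#' the matrix margins are excluded.
#'
#' @param m a range-filled, ordered [IncidenceMatrix-class].
#' @param excludeEdges drop boundaries at the first/last site position.
#' @return integer vector of length `nSites(m)`.
#' @export
boundaryCounts <- function(m, excludeEdges = FALSE) {
  stopifnot(is(m, "IncidenceMatrix"))
  .boundaryCore(m@mat, excludeEdges)
}

#' Morisita's index of boundary clumping
#'
#' `MI = T * sum(n_i (n_i - 1)) / (N (N - 1))` for boundary counts `n_i` over
#' `T` site positions with `N = sum(n_i)`. MI significantly above 1 means
#' clumped range boundaries, significantly below 1 evenly spaced
#' (hyperdispersed) boundaries. Significance is a chi-square goodness-of-fit
#' of the counts against the uniform expectation `N/T` with `T - 1` degrees
#' of freedom; the p value is two-sided (equal tail: twice the smaller of the
#' upper and lower tail areas), since clumping inflates the statistic and
#' hyperdispersion deflates it. Both the statistic and the df convention are
#' documented choices of this implementation.
#'
#' @param n integer vector of boundary counts (see [boundaryCounts()]).
#' @return a [ClumpingResult-class].
#' @export
morisitaClumping <- function(n) {
  n <- as.numeric(n)
  N <- sum(n)
  T <- length(n)
  if (N < 2) stop("need at least two boundaries")
  mi <- T * sum(n * (n - 1)) / (N * (N - 1))
  exp <- N / T
  chi2 <- sum((n - exp)^2 / exp)
  df <- T - 1L
  p <- min(1, 2 * min(stats::pchisq(chi2, df, lower.tail = FALSE),
                      stats::pchisq(chi2, df, lower.tail = TRUE)))
  new("ClumpingResult", morisita = mi, chi2 = chi2, df = as.integer(df),
      p = p, counts = n)
}

#' z test of an EMS statistic against its null distribution
#'
#' `z = (null mean - observed) / null SD`, with a two-tailed normal-theory p.
#' For embedded absences, significantly positive z (fewer gaps than null)
#' means positive coherence and significantly negative z means checkerboard;
#' for replacements, significantly negative z (more replacements than null)
#' means positive turnover and significantly positive z means nestedness.
#'
#' @param observed observed statistic.
#' @param nullStats numeric vector of the statistic over the null ensemble
#'   (length >= 2), or a list with `mean` and `sd` (and optionally `n`) when
#'   only summary moments are available.
#' @param statisticName "embedded_absences" or "replacements".
#' @return an [EMSTestResult-class].
#' @examples
#' zTest(24774, list(mean = 29843.7, sd = 769.4))  # z = 6.59
#' @export
zTest <- function(observed, nullStats,
                  statisticName = c("embedded_absences", "replacements")) {
  statisticName <- match.arg(statisticName)
  if (is.list(nullStats)) {
    mu <- nullStats$mean
    sd <- nullStats$sd
    n <- if (is.null(nullStats$n)) NA_integer_ else as.integer(nullStats$n)
  } else {
    if (length(nullStats) < 2) stop("need >= 2 null statistics")
    mu <- mean(nullStats)
    sd <- stats::sd(nullStats)
    n <- length(nullStats)
  }
  if (!is.finite(sd) || sd <= 0) stop("null SD must be positive")
  z <- (mu - observed) / sd
  p <- 2 * stats::pnorm(-abs(z))
  new("EMSTestResult", statisticName = statisticName,
      observed = as.numeric(observed), nullMean = mu, nullSD = sd,
      z = z, p = p, nNull = n)
}

#' The 14 idealised/quasi metacommunity structure labels
#'
#' @return character vector of the full label set.
#' @export
structureLabels <- function() c(
  "Checkerboard", "Random",
  "Evenly spaced", "Gleasonian", "Clementsian",
  "Nested - hyperdispersed species loss", "Nested - random species loss",
  "Nested - clumped species loss",
  "Quasi-evenly spaced", "Quasi-Gleasonian", "Quasi-Clementsian",
  "Quasi-nested - hyperdispersed species loss",
  "Quasi-nested - random species loss",
  "Quasi-nested - clumped species loss")

#' Classify the three EMS component results into a structure label
#'
#' Deterministic taxonomy: non-significant coherence is Random and
#' significantly negative coherence (more embedded absences than null) is
#' Checkerboard; otherwise turnover splits the coherent structures. For
#' significant positive turnover, boundary clumping significantly below 1,
#' non-significant, or significantly above 1 gives evenly spaced, Gleasonian
#' or Clementsian; significant negative turnover gives the nested analogues
#' (hyperdispersed / random / clumped species loss). Non-significant turnover
#' yields the quasi variant of the family indicated by the direction of its
#' deviation from the null mean (observed equal to the mean counts as the
#' nested direction).
#'
#' @param coh coherence [EMSTestResult-class] (embedded absences).
#' @param turn turnover [EMSTestResult-class] (replacements); may be NULL
#'   only when coherence already decides the label.
#' @param clump [ClumpingResult-class]; as `turn`.
#' @param alpha two-tailed significance level (default 0.05).
#' @return a structure label from [structureLabels()].
#' @export
classifyStructure <- function(coh, turn, clump, alpha = 0.05) {
  stopifnot(is(coh, "EMSTestResult"))
  if (coh@statisticName != "embedded_absences")
    stop("coherence result must be an embedded-absence test")
  if (coh@p >= alpha) return("Random")
  if (coh@z < 0) return("Checkerboard")
  stopifnot(is(turn, "EMSTestResult"), is(clump, "ClumpingResult"))
  if (turn@statisticName != "replacements")
    stop("turnover result must be a replacement test")
  positive <- turn@z < 0  # observed replacements above the null mean
  clumpCat <- if (clump@p < alpha) {
    if (clump@morisita > 1) "clumped" else "hyperdispersed"
  } else "indistinct"
  if (turn@p < alpha) {
    if (positive)
      switch(clumpCat, clumped = "Clementsian", indistinct = "Gleasonian",
             hyperdispersed = "Evenly spaced")
    else
      switch(clumpCat,
             clumped = "Nested - clumped species loss",
             indistinct = "Nested - random species loss",
             hyperdispersed = "Nested - hyperdispersed species loss")
  } else {
    if (positive)
      switch(clumpCat, clumped = "Quasi-Clementsian",
             indistinct = "Quasi-Gleasonian",
             hyperdispersed = "Quasi-evenly spaced")
    else
      switch(clumpCat,
             clumped = "Quasi-nested - clumped species loss",
             indistinct = "Quasi-nested - random species loss",
             hyperdispersed = "Quasi-nested - hyperdispersed species loss")
  }
}

#' Run the full EMS analysis for one ordination axis
#'
#' Ordinates the matrix by reciprocal averaging, tests coherence (embedded
#' absences), then — if coherence is significantly positive — fills ranges
#' and tests turnover (replacements) and boundary clumping, and classifies
#' the result into the 14-structure taxonomy. All statistics are judged
#' against the same "r1" null ensemble; by default each null matrix is
#' re-ordinated by its own reciprocal averaging before its statistics are
#' measured (`reordinate = FALSE` scores nulls on the empirical ordering
#' instead). Null matrices that lose taxa entirely have those all-zero
#' columns dropped before ordination (they contribute nothing to either
#' statistic).
#'
#' @param m a filtered, non-degenerate [IncidenceMatrix-class] (see
#'   [filterRareTaxa()] and [dropEmptySites()]).
#' @param axis ordination axis, 1 or 2.
#' @param nSim null matrices (default 1000).
#' @param seed integer seed for the null ensemble.
#' @param alpha significance level (default 0.05).
#' @param mode embedded-absence counting mode, see
#'   [countEmbeddedAbsences()].
#' @param reordinate re-ordinate each null matrix (default) or reuse the
#'   empirical ordering.
#' @param ensemble optionally, a precomputed [NullEnsemble-class] for `m`
#'   (so both axes can share one ensemble); `nSim`/`seed` are then ignored.
#' @return a [StructureClassification-class].
#' @export
evaluateAxis <- function(m, axis = 1, nSim = 1000, seed, alpha = 0.05,
                         mode = c("both", "columns"), reordinate = TRUE,
                         ensemble = NULL) {
  stopifnot(is(m, "IncidenceMatrix"))
  mode <- match.arg(mode)
  ra <- reciprocalAveraging(m, nAxes = max(2, axis))
  om <- orderMatrix(m, ra, axis)
  obsAbs <- countEmbeddedAbsences(om, mode)
  filled <- fillRanges(om)
  obsRe <- countReplacements(filled)
  clump <- morisitaClumping(boundaryCounts(filled))

  if (is.null(ensemble)) ensemble <- generateR1(m, nSim, seed)
  stats <- .nullStatistics(ensemble, axis, mode, reordinate,
                           empOrder = list(site = ra@siteOrder[, axis],
                                           taxon = ra@taxonOrder[, axis]))
  coh <- zTest(obsAbs, stats$abs, "embedded_absences")
  if (coh@p >= alpha || coh@z < 0) {
    label <- classifyStructure(coh, NULL, NULL, alpha)
    return(new("StructureClassification", axis = as.integer(axis),
               label = label, coherence = coh, turnover = NULL,
               clumping = NULL, alpha = alpha))
  }
  turn <- zTest(obsRe, stats$re, "replacements")
  label <- classifyStructure(coh, turn, clump, alpha)
  new("StructureClassification", axis = as.integer(axis), label = label,
      coherence = coh, turnover = turn, clumping = clump, alpha = alpha)
}

## Abs and Re for every null matrix. Nulls with fewer than axis+1 informative
## dimensions after zero-column removal are skipped (rare; counted).
.nullStatistics <- function(ensemble, axis, mode, reordinate, empOrder) {
  nSim <- length(ensemble@matrices)
  absStat <- numeric(nSim)
  reStat <- numeric(nSim)
  ok <- logical(nSim)
  for (i in seq_len(nSim)) {
    M <- ensemble@matrices[[i]]
    M <- M[, colSums(M) > 0, drop = FALSE]
    if (reordinate) {
      ord <- tryCatch(.raCore(M, nAxes = axis), error = function(e) NULL)
      if (is.null(ord)) next
      Mo <- M[ord$siteOrder[, axis], ord$taxonOrder[, axis], drop = FALSE]
    } else {
      Mo <- ensemble@matrices[[i]][empOrder$site, empOrder$taxon,
                                   drop = FALSE]
      Mo <- Mo[, colSums(Mo) > 0, drop = FALSE]
    }
    absStat[i] <- .absCore(Mo, mode)
    reStat[i] <- .reCore(.fillCore(Mo))
    ok[i] <- TRUE
  }
  if (sum(ok) < 2) stop("null ensemble degenerate: too few usable matrices")
  if (any(!ok))
    warning(sum(!ok), " null matrices were degenerate and skipped")
  list(abs = absStat[ok], re = reStat[ok])
}

#' Tabulate EMS results in the standard report layout
#'
#' One row per classification, with the coherence triple (observed, null
#' mean, null SD, z, p), the turnover triple, Morisita's index with its p,
#' and the best-fit label.
#'
#' @param classifications list of [StructureClassification-class] objects.
#' @param labels optional row labels (e.g. river sections).
#' @return data.frame.
#' @export
emsTable <- function(classifications, labels = NULL) {
  row1 <- function(cl) {
    co <- cl@coherence
    tu <- cl@turnover
    bc <- cl@clumping
    data.frame(
      axis = cl@axis,
      Abs = co@observed, Abs_mean = co@nullMean, Abs_SD = co@nullSD,
      Abs_z = co@z, Abs_p = co@p,
      Re = if (is.null(tu)) NA else tu@observed,
      Re_mean = if (is.null(tu)) NA else tu@nullMean,
      Re_SD = if (is.null(tu)) NA else tu@nullSD,
      Re_z = if (is.null(tu)) NA else tu@z,
      Re_p = if (is.null(tu)) NA else tu@p,
      MI = if (is.null(bc)) NA else bc@morisita,
      MI_p = if (is.null(bc)) NA else bc@p,
      structure = cl@label)
  }
  out <- do.call(rbind, lapply(classifications, row1))
  if (!is.null(labels)) out <- cbind(data.frame(set = labels), out)
  out
}
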
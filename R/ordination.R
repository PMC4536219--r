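#' Reciprocal averaging (correspondence analysis) of an incidence matrix
#'
#' Computes the unconstrained correspondence-analysis ordination that the EMS
#' framework uses to arrange sites and taxa along latent gradients: the
#' singular value decomposition of the chi-square standardised matrix
#' `(P - r c') / sqrt(r c')` with `P` the matrix scaled to sum 1 and `r`, `c`
#' its margins. Site and taxon scores are the principal coordinates of the
#' first `nAxes` non-trivial axes. Each axis is deterministically oriented so
#' that the first site (input order) has a non-negative score (tie broken by
#' the first taxon's score); score ties in the orderings are broken by input
#' index.
#'
#' @param m an [IncidenceMatrix-class] with no all-zero rows or columns.
#' @param nAxes number of axes to retain (default 2).
#' @return an [RAResult-class].
#' @examples
#' m <- IncidenceMatrix(rbind(c(1,1,0,0), c(0,1,1,0), c(0,0,1,1)))
#' reciprocalAveraging(m)
#' @export
reciprocalAveraging <- function(m, nAxes = 2) {
  stopifnot(is(m, "IncidenceMatrix"))
  X <- m@mat
  if (any(rowSums(X) == 0)) stop("all-zero site rows; see dropEmptySites()")
  if (any(colSums(X) == 0)) stop("all-zero taxon columns; filter them first")
  ra <- .raCore(X, nAxes)
  new("RAResult", siteScores = ra$siteScores, taxonScores = ra$taxonScores,
      eigenvalues = ra$eigenvalues, siteOrder = ra$siteOrder,
      taxonOrder = ra$taxonOrder)
}

## Bare-matrix CA core, shared with the per-null-matrix hot loop.
.raCore <- function(X, nAxes) {
  P <- X / sum(X)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S, nu = min(dim(X)), nv = min(dim(X)))
  rank <- sum(sv$d > 1e-10)
  if (rank < nAxes)
    stop(sprintf(
      "degenerate matrix: only %d non-trivial axis/axes available (rank %d)",
      rank, rank + 1L))
  k <- seq_len(nAxes)
  d <- sv$d[k]
  site <- sweep(sv$u[, k, drop = FALSE], 1, sqrt(r), "/") %*%
    diag(d, nAxes, nAxes)
  taxon <- sweep(sv$v[, k, drop = FALSE], 1, sqrt(cc), "/") %*%
    diag(d, nAxes, nAxes)
  for (a in k) {
    s1 <- site[1, a]
    flip <- if (abs(s1) > 1e-12) s1 < 0 else taxon[1, a] < 0
    if (flip) {
      site[, a] <- -site[, a]
      taxon[, a] <- -taxon[, a]
    }
  }
  rownames(site) <- rownames(X)
  rownames(taxon) <- colnames(X)
  colnames(site) <- colnames(taxon) <- paste0("axis", k)
  so <- vapply(k, function(a) order(site[, a], seq_len(nrow(X))),
               integer(nrow(X)))
  to <- vapply(k, function(a) order(taxon[, a], seq_len(ncol(X))),
               integer(ncol(X)))
  list(siteScores = site, taxonScores = taxon, eigenvalues = d^2,
       siteOrder = matrix(so, ncol = nAxes),
       taxonOrder = matrix(to, ncol = nAxes))
}

#' Order an incidence matrix by reciprocal-averaging scores
#'
#' Permutes rows and columns by the chosen axis's site and taxon scores, the
#' "best arrangement" on which the EMS statistics are defined.
#'
#' @param m the [IncidenceMatrix-class] the ordination was computed from.
#' @param r an [RAResult-class] for `m`.
#' @param axis 1 or 2.
#' @return the ordered [IncidenceMatrix-class].
#' @export
orderMatrix <- function(m, r, axis = 1) {
  stopifnot(is(m, "IncidenceMatrix"), is(r, "RAResult"))
  if (!axis %in% seq_len(ncol(r@siteOrder)))
    stop("axis must be one of 1..", ncol(r@siteOrder))
  if (nrow(r@siteScores) != nSites(m) || nrow(r@taxonScores) != nTaxa(m))
    stop("ordination does not match matrix dimensions")
  IncidenceMatrix(m@mat[r@siteOrder[, axis], r@taxonOrder[, axis],
                        drop = FALSE])
}

#' Euclidean geographic distances between sites
#'
#' @param t site table with planar coordinates `x`, `y` in metres.
#' @return a symmetric distance matrix (class `dist`) in metres, labelled by
#'   site id.
#' @export
geographicDistances <- function(t) {
  validateSiteTable(t, requireCoords = TRUE)
  if (anyNA(t$x) || anyNA(t$y)) stop("missing coordinates")
  d <- stats::dist(cbind(t$x, t$y))
  attr(d, "Labels") <- as.character(t$site_id)
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Used to turn the geographic distance matrix into spatial eigenvector
#' predictors (PCo1, PCo2). Retained axes must have positive eigenvalues;
#' geographic distances are Euclidean, so no correction is applied.
#'
#' @param d symmetric distance matrix (`dist` or square matrix with zero
#'   diagonal).
#' @param nAxes axes to retain (default 2).
#' @return a [PCoAVectors-class]; vector columns are named `PCo1`, `PCo2`, ...
#' @export
pcoaVectors <- function(d, nAxes = 2) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
    if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  if (nAxes >= n) stop("nAxes must be smaller than the number of sites")
  cs <- stats::cmdscale(d, k = nAxes, eig = TRUE)
  eig <- cs$eig[seq_len(nAxes)]
  if (any(eig <= 0))
    stop("retained principal-coordinate axes must have positive eigenvalues")
  v <- cs$points
  colnames(v) <- paste0("PCo", seq_len(nAxes))
  rownames(v) <- attr(d, "Labels")
  new("PCoAVectors", vectors = v, eigenvalues = eig)
}
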
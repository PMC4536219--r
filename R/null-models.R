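#' Generate the "r1" (fixed-incidence proportional) null ensemble
#'
#' The randomisation all EMS significance tests are judged against: for every
#' null matrix, each site draws exactly its observed richness of taxa without
#' replacement, with selection weight proportional to each taxon's observed
#' incidence (column total) in the source matrix. Row sums (site richness)
#' are therefore preserved exactly, while column totals are proportional to
#' incidence only in expectation.
#'
#' One root seed determines the whole ensemble: per-matrix sub-streams are
#' derived by counter from the root seed, so subsets of the ensemble can be
#' regenerated independently with identical results.
#'
#' @param m a filtered [IncidenceMatrix-class] (taxa with zero incidence get
#'   zero weight and are never drawn).
#' @param nSim number of null matrices (default 1000; at least 2, otherwise
#'   the null SD is undefined).
#' @param seed integer root seed.
#' @return a [NullEnsemble-class].
#' @examples
#' m <- IncidenceMatrix(rbind(c(1,1,0), c(0,1,1), c(1,0,1)))
#' generateR1(m, nSim = 10, seed = 1)
#' @export
generateR1 <- function(m, nSim = 1000, seed) {
  stopifnot(is(m, "IncidenceMatrix"))
  if (nSim < 2) stop("nSim must be >= 2 (null SD undefined otherwise)")
  if (missing(seed) || !is.finite(seed)) stop("an integer seed is required")
  X <- m@mat
  w <- colSums(X)
  rich <- rowSums(X)
  if (any(rich > sum(w > 0)))
    stop("a site's richness exceeds the number of drawable taxa")
  nt <- ncol(X)
  ns <- nrow(X)
  subSeeds <- .deriveSeeds(as.integer(seed), nSim)
  mats <- vector("list", nSim)
  for (i in seq_len(nSim)) {
    set.seed(subSeeds[i])
    M <- matrix(0, ns, nt, dimnames = dimnames(X))
    for (s in seq_len(ns)) {
      r <- rich[s]
      if (r == 0) next
      M[s, sample.int(nt, r, replace = FALSE, prob = w)] <- 1
    }
    mats[[i]] <- M
  }
  new("NullEnsemble", matrices = mats, method = "r1",
      seed = as.integer(seed))
}

## Counter-derived per-matrix seeds: seed_i is a pure function of
## (root seed, i), independent of R's RNG state, so any single matrix of the
## ensemble is reproducible in isolation (and generation can be parallelised).
.deriveSeeds <- function(seed, n) {
  m <- 2^31 - 1
  i <- seq_len(n)
  x <- (((as.double(seed) %% m + m) %% m + 1) * 48271) %% m
  x <- (x + i * 69621) %% m
  x <- (x * 16807 + i) %% m
  as.integer(x %% (2^31 - 2) + 1)
}
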
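#' Configure a synthetic metacommunity
#'
#' Recipes for site-by-taxon incidence matrices with a known idealised
#' structure along a latent gradient, plus conditional abundances and an
#' environmental table carrying the gradient signal — so every pipeline stage
#' can be exercised and its recovery quantified without field data.
#'
#' Structures (sites at gradient positions `1..nSites`):
#' \describe{
#'   \item{clementsian}{`nGroups` contiguous site blocks; all taxa of a group
#'     share the block's range boundaries (compartments).}
#'   \item{gleasonian}{independent uniform range centres and jittered widths
#'     (idiosyncratic turnover); centres are placed so ranges fit inside the
#'     gradient, keeping boundaries away from forced pile-up at the margins.}
#'   \item{nested}{ranges share the gradient's lower end with ordered widths
#'     (species-poor sites are subsets of richer ones).}
#'   \item{evenly_spaced}{equal widths with equidistant boundaries
#'     (hyperdispersed).}
#'   \item{checkerboard}{mutually exclusive taxon pairs on complementary
#'     random site subsets (requires even `nTaxa`).}
#'   \item{random}{independent Bernoulli(`prevalence`) occurrences.}
#' }
#' Each cell is then flipped with probability `noiseEps` (symmetric by
#' default; `noiseType = "false_absence"` only deletes presences, the
#' one-sided detection error of field surveys).
#'
#' @param structure one of the six structures above.
#' @param nSites,nTaxa matrix dimensions.
#' @param nGroups Clementsian blocks (default 4).
#' @param meanRangeWidth mean range width in sites (default 40% of the
#'   gradient, jittered ±25% per taxon).
#' @param noiseEps bit-flip probability in [0, 0.5) (default 0.01).
#' @param noiseType "symmetric" or "false_absence".
#' @param prevalence presence probability for the random structure
#'   (default 0.3).
#' @param abundanceMean mean of positive counts (default 20).
#' @param abundanceDispersion negative-binomial size (default 1).
#' @param envNoiseSD driver noise SD on the standardised gradient
#'   (default 0.25).
#' @param nuisanceCor target correlation of nuisance predictors with the
#'   driver (default 0.3).
#' @param seed integer seed (mandatory; the generator is fully
#'   deterministic given the config).
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(structure = c("clementsian", "gleasonian",
                                          "nested", "evenly_spaced",
                                          "checkerboard", "random"),
                            nSites = 40, nTaxa = 50, nGroups = 4,
                            meanRangeWidth = round(0.4 * nSites),
                            noiseEps = 0.01,
                            noiseType = c("symmetric", "false_absence"),
                            prevalence = 0.3, abundanceMean = 20,
                            abundanceDispersion = 1, envNoiseSD = 0.25,
                            nuisanceCor = 0.3, seed = 1) {
  new("SyntheticConfig", structure = match.arg(structure),
      nSites = as.integer(nSites), nTaxa = as.integer(nTaxa),
      nGroups = as.integer(nGroups),
      meanRangeWidth = as.numeric(meanRangeWidth),
      noiseEps = as.numeric(noiseEps), noiseType = match.arg(noiseType),
      prevalence = as.numeric(prevalence),
      abundanceMean = as.numeric(abundanceMean),
      abundanceDispersion = as.numeric(abundanceDispersion),
      envNoiseSD = as.numeric(envNoiseSD),
      nuisanceCor = as.numeric(nuisanceCor), seed = as.integer(seed))
}

#' Simulate a metacommunity incidence matrix with known structure
#'
#' @param config a [SyntheticConfig-class].
#' @return list with `incidence` ([IncidenceMatrix-class]), `gradient`
#'   (latent site positions, named), and `groups` (taxon group labels for
#'   Clementsian / pair labels for checkerboard, otherwise NA).
#' @export
simulateMetacommunity <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  set.seed(config@seed)
  S <- config@nSites
  K <- config@nTaxa
  w <- config@meanRangeWidth
  groups <- rep(NA_integer_, K)
  X <- matrix(0, S, K)

  rangeMatrix <- function(first, last) {
    idx <- matrix(seq_len(S), S, K)
    1 * (idx >= matrix(first, S, K, byrow = TRUE) &
         idx <= matrix(last, S, K, byrow = TRUE))
  }

  if (config@structure == "clementsian") {
    cuts <- round(seq(0, S, length.out = config@nGroups + 1))
    groups <- rep_len(seq_len(config@nGroups), K)
    X <- rangeMatrix(cuts[groups] + 1, cuts[groups + 1])
  } else if (config@structure == "gleasonian") {
    width <- pmax(2, pmin(S, round(stats::runif(K, 0.75 * w, 1.25 * w))))
    first <- vapply(width, function(wd)
      sample.int(S - wd + 1L, 1L), integer(1))
    X <- rangeMatrix(first, first + width - 1)
  } else if (config@structure == "nested") {
    width <- sort(pmax(2, round(stats::runif(K, 2, S))))
    X <- rangeMatrix(rep(1, K), width)
  } else if (config@structure == "evenly_spaced") {
    wd <- max(2, round(w))
    first <- round(seq(1, S - wd + 1, length.out = K))
    X <- rangeMatrix(first, first + wd - 1)
  } else if (config@structure == "checkerboard") {
    groups <- rep(seq_len(K %/% 2), each = 2)
    for (pr in seq_len(K %/% 2)) {
      a <- sample.int(S, S %/% 2)
      X[a, 2 * pr - 1] <- 1
      X[setdiff(seq_len(S), a), 2 * pr] <- 1
    }
  } else {  # random
    X <- matrix(stats::rbinom(S * K, 1, config@prevalence), S, K)
  }

  if (config@noiseEps > 0) {
    flip <- matrix(stats::runif(S * K) < config@noiseEps, S, K)
    if (config@noiseType == "false_absence") flip <- flip & X == 1
    X[flip] <- 1 - X[flip]
  }
  dimnames(X) <- list(paste0("site", seq_len(S)), paste0("taxon", seq_len(K)))
  list(incidence = IncidenceMatrix(X),
       gradient = stats::setNames(seq_len(S), rownames(X)),
       groups = stats::setNames(groups, colnames(X)))
}

#' Simulate an environmental site table tied to the latent gradient
#'
#' One driver variable is an affine function of the gradient plus Gaussian
#' noise; nuisance predictors share a configured correlation with the driver;
#' catchment sizes are stratified over the three river-section classes (in
#' the 48:69:51 headwater:mid:large proportions of the survey design the
#' generator emulates); coordinates are drawn independently unless
#' `coordGradientCor > 0` aligns `x` with the gradient.
#'
#' @param gradient latent gradient from [simulateMetacommunity()].
#' @param config a [SyntheticConfig-class] (uses `envNoiseSD`,
#'   `nuisanceCor`, `seed`).
#' @param driver name of the driver column (default "chem_chloride").
#' @param nNuisance number of nuisance predictors in addition to the fixed
#'   schema columns (default 6).
#' @param coordGradientCor correlation of the x coordinate with the gradient
#'   (default 0).
#' @return a site table data.frame (see [validateSiteTable()]) with
#'   attribute `"driver"`.
#' @export
simulateEnvironment <- function(gradient, config,
                                driver = "chem_chloride", nNuisance = 6,
                                coordGradientCor = 0) {
  stopifnot(is(config, "SyntheticConfig"))
  set.seed(config@seed + 1L)
  n <- length(gradient)
  if (is.null(names(gradient)))
    names(gradient) <- paste0("site", seq_len(n))
  g <- as.numeric(scale(gradient))
  drv <- 50 + 20 * g + stats::rnorm(n, 0, config@envNoiseSD * 20)
  mkNuisance <- function() {
    z <- config@nuisanceCor * scale(drv) +
      sqrt(max(0, 1 - config@nuisanceCor^2)) * stats::rnorm(n)
    as.numeric(z)
  }
  sections <- rep(riverSections(), round(n * c(48, 69, 51) / 168))
  sections <- sample(rep_len(sections, n))  # independent of the gradient
  size <- numeric(n)
  size[sections == "headwaters"] <- stats::runif(sum(sections == "headwaters"), 3, 20)
  size[sections == "mid-sized"] <- stats::runif(sum(sections == "mid-sized"), 20, 100)
  size[sections == "large"] <- stats::runif(sum(sections == "large"), 100, 975)
  x <- coordGradientCor * g + sqrt(max(0, 1 - coordGradientCor^2)) *
    stats::rnorm(n)
  t <- data.frame(
    site_id = names(gradient),
    catchment_size = size,
    elevation = 190 + 60 * mkNuisance(),
    landuse_agriculture = pmin(100, pmax(0, 53 + 17 * mkNuisance())),
    landuse_forest = pmin(100, pmax(0, 40 + 17 * mkNuisance())),
    x = 3500000 + 50000 * x,
    y = 5500000 + 50000 * stats::rnorm(n))
  t[[driver]] <- drv
  for (i in seq_len(max(0, nNuisance - 3)))
    t[[paste0("chem_nuisance", i)]] <- 0.2 + 0.1 * mkNuisance()
  attr(t, "driver") <- driver
  validateSiteTable(t, requireCoords = TRUE)
  t
}

#' Simulate abundances conditional on incidence
#'
#' Counts are 0 where a taxon is absent; where present they are
#' `1 + NegBin(size = abundanceDispersion, mu = abundanceMean - 1)`, so
#' positive counts have exactly the configured mean and incidence is
#' preserved.
#'
#' @param m an [IncidenceMatrix-class].
#' @param config a [SyntheticConfig-class].
#' @return an [AbundanceMatrix-class] with `asIncidence(result)` equal to
#'   `m`.
#' @export
simulateAbundance <- function(m, config) {
  stopifnot(is(m, "IncidenceMatrix"), is(config, "SyntheticConfig"))
  set.seed(config@seed + 2L)
  X <- m@mat
  pres <- which(X == 1)
  X[pres] <- 1 + stats::rnbinom(length(pres),
                                size = config@abundanceDispersion,
                                mu = config@abundanceMean - 1)
  AbundanceMatrix(X)
}
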
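#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core community containers
## ---------------------------------------------------------------------------

#' Virtual parent of the site-by-taxon containers
#'
#' Both [AbundanceMatrix-class] and [IncidenceMatrix-class] wrap a numeric
#' matrix with sites as rows and taxa as columns; row and column names are the
#' (unique) site and taxon identifiers.
#'
#' @slot mat numeric matrix, sites x taxa, with unique dimnames.
#' @keywords classes
setClass("CommunityMatrix", representation("VIRTUAL", mat = "matrix"))

.validCommunityMatrix <- function(object) {
  m <- object@mat
  msg <- character(0)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "site and taxon identifiers (dimnames) are required")
  else {
    if (anyDuplicated(rownames(m)))
      msg <- c(msg, "site identifiers must be unique")
    if (anyDuplicated(colnames(m)))
      msg <- c(msg, "taxon identifiers must be unique")
  }
  if (!is.numeric(m)) msg <- c(msg, "matrix must be numeric")
  if (anyNA(m)) msg <- c(msg, "matrix must not contain missing values")
  if (length(msg)) msg else TRUE
}

#' Site-by-taxon abundance matrix
#'
#' Integer counts of individuals per site and taxon.
#'
#' @slot mat matrix of non-negative integer counts.
#' @seealso [AbundanceMatrix()], [asIncidence()]
#' @keywords classes
setClass("AbundanceMatrix", contains = "CommunityMatrix", validity =
  function(object) {
    msg <- .validCommunityMatrix(object)
    msg <- if (isTRUE(msg)) character(0) else msg
    m <- object@mat
    if (!anyNA(m)) {
      if (any(m < 0)) {
        bad <- which(m < 0, arr.ind = TRUE)[1, ]
        msg <- c(msg, sprintf("negative count at site '%s', taxon '%s'",
                              rownames(m)[bad[1]], colnames(m)[bad[2]]))
      }
      if (any(m != round(m))) {
        bad <- which(m != round(m), arr.ind = TRUE)[1, ]
        msg <- c(msg, sprintf("non-integer count at site '%s', taxon '%s'",
                              rownames(m)[bad[1]], colnames(m)[bad[2]]))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Site-by-taxon incidence (presence/absence) matrix
#'
#' Binary occurrences; the substrate of the Elements of Metacommunity
#' Structure analysis.
#'
#' @slot mat matrix with entries in \{0, 1\}.
#' @seealso [IncidenceMatrix()], [filterRareTaxa()], [evaluateAxis()]
#' @keywords classes
setClass("IncidenceMatrix", contains = "CommunityMatrix", validity =
  function(object) {
    msg <- .validCommunityMatrix(object)
    msg <- if (isTRUE(msg)) character(0) else msg
    m <- object@mat
    if (!anyNA(m) && !all(m %in% c(0, 1)))
      msg <- c(msg, "incidence entries must be 0 or 1")
    if (length(msg)) msg else TRUE
  })

## ---------------------------------------------------------------------------
## Ordination results
## ---------------------------------------------------------------------------

#' Reciprocal averaging (correspondence analysis) result
#'
#' @slot siteScores sites x axes matrix of site scores (principal
#'   coordinates of the chi-square standardised matrix).
#' @slot taxonScores taxa x axes matrix of taxon scores.
#' @slot eigenvalues non-trivial correspondence-analysis eigenvalues,
#'   descending.
#' @slot siteOrder integer matrix, one column per axis: the permutation of
#'   sites by that axis's score (ties broken by input index).
#' @slot taxonOrder integer matrix, as `siteOrder` for taxa.
#' @keywords classes
setClass("RAResult", representation(
  siteScores = "matrix", taxonScores = "matrix", eigenvalues = "numeric",
  siteOrder = "matrix", taxonOrder = "matrix"))

#' Principal coordinate vectors of a distance matrix
#'
#' @slot vectors sites x axes matrix of centred coordinates.
#' @slot eigenvalues eigenvalues of the retained axes (positive, descending).
#' @keywords classes
setClass("PCoAVectors", representation(
  vectors = "matrix", eigenvalues = "numeric"))

## ---------------------------------------------------------------------------
## Null ensemble and EMS results
## ---------------------------------------------------------------------------

#' Ensemble of "r1" null incidence matrices
#'
#' @slot matrices list of binary site-by-taxon matrices, all with the source
#'   matrix's dimensions and exactly the source's row sums.
#' @slot method randomisation algorithm tag ("r1").
#' @slot seed integer root seed that fully determines the ensemble.
#' @keywords classes
setClass("NullEnsemble", representation(
  matrices = "list", method = "character", seed = "integer"),
  validity = function(object) {
    if (object@method != "r1") return("only the 'r1' method is implemented")
    if (length(object@matrices) < 2) return("ensemble needs >= 2 matrices")
    TRUE
  })

#' One EMS test statistic against its null distribution
#'
#' @slot statisticName "embedded_absences" or "replacements".
#' @slot observed observed count.
#' @slot nullMean,nullSD mean and standard deviation of the null statistics.
#' @slot z z = (nullMean - observed) / nullSD (the sign convention under
#'   which positive z for embedded absences means positive coherence).
#' @slot p two-tailed normal-theory p value.
#' @slot nNull number of null statistics used.
#' @keywords classes
setClass("EMSTestResult", representation(
  statisticName = "character", observed = "numeric", nullMean = "numeric",
  nullSD = "numeric", z = "numeric", p = "numeric", nNull = "integer"),
  validity = function(object) {
    if (!object@statisticName %in% c("embedded_absences", "replacements"))
      return("unknown statistic name")
    if (!is.na(object@nullSD) && object@nullSD <= 0)
      return("null SD must be positive")
    TRUE
  })

#' Boundary clumping (Morisita) result
#'
#' @slot morisita Morisita's index of dispersion of range boundaries.
#' @slot chi2,df,p chi-square goodness-of-fit of the boundary counts against
#'   a uniform expectation, df = positions - 1.
#' @slot counts boundary count per ordered site position.
#' @keywords classes
setClass("ClumpingResult", representation(
  morisita = "numeric", chi2 = "numeric", df = "integer", p = "numeric",
  counts = "numeric"))

setClassUnion("EMSTestResultOrNULL", c("EMSTestResult", "NULL"))
setClassUnion("ClumpingResultOrNULL", c("ClumpingResult", "NULL"))

#' Best-fit metacommunity structure for one ordination axis
#'
#' One of the 14 idealised/quasi structure labels, together with the three
#' component tests (coherence, turnover, boundary clumping). Turnover and
#' clumping are NULL when coherence is non-significant (Random) or
#' significantly negative (Checkerboard), in which case the framework stops.
#'
#' @slot axis ordination axis (1 or 2).
#' @slot label structure label, one of [structureLabels()].
#' @slot coherence embedded-absence test.
#' @slot turnover replacement test, or NULL.
#' @slot clumping Morisita result, or NULL.
#' @slot alpha significance level used.
#' @keywords classes
setClass("StructureClassification", representation(
  axis = "integer", label = "character",
  coherence = "EMSTestResult",
  turnover = "EMSTestResultOrNULL",
  clumping = "ClumpingResultOrNULL",
  alpha = "numeric"))

## ---------------------------------------------------------------------------
## Boosted regression trees
## ---------------------------------------------------------------------------

#' Boosted-regression-tree configuration
#'
#' @slot loss "poisson" (counts, log link) or "gaussian".
#' @slot learningRate shrinkage applied to every tree (default 0.001; lower
#'   it, e.g. to 0.0001, if cross-validation selects fewer than 1000 trees).
#' @slot treeComplexity internal splits per tree (default 5).
#' @slot bagFraction fraction of rows resampled for each tree (default 0.5).
#' @slot nFolds cross-validation folds for tree selection (default 10).
#' @slot stepSize trees added per selection step (default 50).
#' @slot minObs minimum observations per terminal node (default 10).
#' @keywords classes
setClass("BRTConfig", representation(
  loss = "character", learningRate = "numeric", treeComplexity = "integer",
  bagFraction = "numeric", nFolds = "integer", stepSize = "integer",
  minObs = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!object@loss %in% c("poisson", "gaussian"))
      msg <- c(msg, "loss must be 'poisson' or 'gaussian'")
    if (object@learningRate <= 0 || object@learningRate > 1)
      msg <- c(msg, "learningRate must be in (0, 1]")
    if (object@bagFraction <= 0 || object@bagFraction > 1)
      msg <- c(msg, "bagFraction must be in (0, 1]")
    if (object@treeComplexity < 1L)
      msg <- c(msg, "treeComplexity must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Fitted boosted-regression-tree model
#'
#' Prediction on the link scale is `init + learningRate * sum(tree outputs)`;
#' Poisson models exponentiate for the response scale.
#'
#' @slot trees list of node matrices (one per boosting stage).
#' @slot init baseline prediction on the link scale.
#' @slot nTrees number of stages.
#' @slot config the [BRTConfig-class] used.
#' @slot varNames predictor names.
#' @slot varImprovement total squared-error reduction attributed to each
#'   predictor over all splits (the raw material of [relativeInfluence()]).
#' @keywords classes
setClass("BRTModel", representation(
  trees = "list", init = "numeric", nTrees = "integer", config = "BRTConfig",
  varNames = "character", varImprovement = "numeric"))

## ---------------------------------------------------------------------------
## Synthetic generator
## ---------------------------------------------------------------------------

#' Recipe for a synthetic metacommunity
#'
#' See [syntheticConfig()] for the field semantics and defaults.
#'
#' @slot structure idealised structure to generate.
#' @slot nSites,nTaxa matrix dimensions.
#' @slot nGroups number of Clementsian community blocks.
#' @slot meanRangeWidth mean taxon range width (sites).
#' @slot noiseEps per-cell bit-flip probability.
#' @slot noiseType "symmetric" flips both ways; "false_absence" only deletes
#'   presences (one-sided detection error).
#' @slot prevalence Bernoulli presence probability for random structure.
#' @slot abundanceMean mean of positive counts.
#' @slot abundanceDispersion negative-binomial size of positive counts.
#' @slot envNoiseSD driver noise SD on the standardised gradient scale.
#' @slot nuisanceCor target correlation of nuisance predictors with the
#'   driver.
#' @slot seed integer seed.
#' @keywords classes
setClass("SyntheticConfig", representation(
  structure = "character", nSites = "integer", nTaxa = "integer",
  nGroups = "integer", meanRangeWidth = "numeric", noiseEps = "numeric",
  noiseType = "character", prevalence = "numeric", abundanceMean = "numeric",
  abundanceDispersion = "numeric", envNoiseSD = "numeric",
  nuisanceCor = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!object@structure %in% c("clementsian", "gleasonian", "nested",
                                 "evenly_spaced", "checkerboard", "random"))
      msg <- c(msg, "unknown structure")
    if (object@noiseEps < 0 || object@noiseEps >= 0.5)
      msg <- c(msg, "noiseEps must be in [0, 0.5)")
    if (object@nGroups > object@nTaxa)
      msg <- c(msg, "nGroups must not exceed nTaxa")
    if (object@structure == "checkerboard" && object@nTaxa %% 2L != 0L)
      msg <- c(msg, "checkerboard structure needs an even number of taxa")
    if (length(msg)) msg else TRUE
  })
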
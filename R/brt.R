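#' Boosted-regression-tree configuration
#'
#' @param loss "poisson" for counts (richness) or "gaussian" (ordination
#'   scores).
#' @param learningRate shrinkage per tree (default 0.001; use 0.0001 when
#'   cross-validation would otherwise select fewer than 1000 trees).
#' @param treeComplexity internal splits per tree (default 5).
#' @param bagFraction row subsample fraction per tree (default 0.5).
#' @param nFolds cross-validation folds (default 10).
#' @param stepSize trees per selection step (default 50).
#' @param minObs minimum observations per terminal node (default 10).
#' @return a [BRTConfig-class].
#' @export
brtConfig <- function(loss = c("gaussian", "poisson"), learningRate = 0.001,
                      treeComplexity = 5, bagFraction = 0.5, nFolds = 10,
                      stepSize = 50, minObs = 10) {
  new("BRTConfig", loss = match.arg(loss),
      learningRate = as.numeric(learningRate),
      treeComplexity = as.integer(treeComplexity),
      bagFraction = as.numeric(bagFraction), nFolds = as.integer(nFolds),
      stepSize = as.integer(stepSize), minObs = as.integer(minObs))
}

.asPredictorMatrix <- function(X) {
  if (is.data.frame(X)) {
    X[] <- lapply(X, function(col) {
      if (is.factor(col) || is.character(col)) as.numeric(as.factor(col))
      else as.numeric(col)
    })
    X <- as.matrix(X)
  }
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("predictors must not contain missing values")
  X
}

#' Fit a boosted-regression-tree model
#'
#' Stage-wise gradient boosting: each stage fits a regression tree with
#' `treeComplexity` splits to the current loss gradient on a random
#' `bagFraction` row subsample and adds it with shrinkage `learningRate`.
#' The fit is fully determined by the RNG state (use `set.seed()` or the
#' `seed` argument).
#'
#' @param X predictor data.frame or numeric matrix (factors are coded
#'   numerically; no missing values).
#' @param y response: non-negative integers for Poisson loss.
#' @param config a [BRTConfig-class] (see [brtConfig()]).
#' @param nTrees number of boosting stages.
#' @param seed optional integer seed (otherwise the current RNG state is
#'   used).
#' @return a [BRTModel-class].
#' @export
fitBRT <- function(X, y, config = brtConfig(), nTrees = 1000, seed = NULL) {
  Xm <- .asPredictorMatrix(X)
  stopifnot(nrow(Xm) == length(y))
  if (config@loss == "poisson" && (any(y < 0) || any(y != round(y))))
    stop("Poisson loss requires non-negative integer responses")
  if (!is.null(seed)) set.seed(seed)
  fit <- .cppBoost(Xm, as.numeric(y), config@loss, as.integer(nTrees),
                   config@learningRate, config@treeComplexity,
                   config@bagFraction, config@minObs,
                   matrix(0, 0, ncol(Xm)), config@stepSize, TRUE)
  vn <- colnames(Xm)
  if (is.null(vn)) vn <- paste0("x", seq_len(ncol(Xm)))
  new("BRTModel", trees = fit$trees, init = fit$init,
      nTrees = as.integer(nTrees), config = config, varNames = vn,
      varImprovement = stats::setNames(as.numeric(fit$varImprovement), vn))
}

#' Predict from a boosted-regression-tree model
#'
#' @param object a [BRTModel-class].
#' @param newdata predictor data.frame/matrix with the training columns.
#' @param type `"response"` (default; counts for Poisson models) or
#'   `"link"`.
#' @param nTrees number of stages to use (default: all).
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "BRTModel",
  function(object, newdata, type = c("response", "link"), nTrees = NULL,
           ...) {
    type <- match.arg(type)
    Xm <- .asPredictorMatrix(newdata)
    if (ncol(Xm) != length(object@varNames))
      stop("newdata must have the training predictors")
    if (is.null(nTrees)) nTrees <- object@nTrees
    f <- .cppPredict(object@trees, object@init, object@config@learningRate,
                     Xm, as.integer(nTrees))
    if (object@config@loss == "poisson" && type == "response") exp(f) else f
  })

#' Mean deviance of predictions
#'
#' Poisson: mean of `2 * (y * log(y / mu) - (y - mu))` (the log term is 0 at
#' y = 0); Gaussian: mean squared error.
#'
#' @param y observed responses.
#' @param mu predictions on the response scale (positive for Poisson).
#' @param loss "poisson" or "gaussian".
#' @return mean deviance (a single number).
#' @export
devianceStat <- function(y, mu, loss = c("gaussian", "poisson")) {
  loss <- match.arg(loss)
  stopifnot(length(y) == length(mu))
  if (loss == "poisson") {
    if (any(mu <= 0)) stop("Poisson deviance needs positive predictions")
    t <- ifelse(y > 0, y * log(y / mu), 0)
    mean(2 * (t - (y - mu)))
  } else {
    mean((y - mu)^2)
  }
}

#' Percent deviance explained
#'
#' `100 * (null - residual) / null`: the share of the null deviance removed
#' by a model, the headline performance figure for both training and
#' cross-validated fits.
#'
#' @param null mean null deviance (intercept-only model).
#' @param residual mean residual deviance.
#' @return percentage.
#' @examples
#' devianceExplained(3.976, 1.578)  # 60.3
#' @export
devianceExplained <- function(null, residual) 100 * (null - residual) / null

#' Select the number of trees by cross-validation
#'
#' Grows each fold's model in steps of `stepSize` trees up to `maxTrees`,
#' tracks the held-out deviance of every step, and selects the tree count
#' minimising the pooled cross-validated deviance; the final model is then
#' refit on all rows with that many trees. Folds are a seeded random
#' partition, stratified by response tertile for Poisson losses. A warning
#' suggests lowering the learning rate when fewer than 1000 trees are
#' selected.
#'
#' @param X,y as in [fitBRT()].
#' @param config a [BRTConfig-class].
#' @param maxTrees largest tree count tried (default 5000).
#' @param seed optional integer seed.
#' @return list with `model` (the refit [BRTModel-class]), `nTrees`, and
#'   `evaluation`: trainingDevianceExplained, trainingCorrelation,
#'   meanNullDeviance, meanCVResidualDeviance (+ SE), cvDevianceExplained,
#'   cvCorrelation (+ SE).
#' @export
selectNTreesCV <- function(X, y, config = brtConfig(), maxTrees = 5000,
                           seed = NULL) {
  Xm <- .asPredictorMatrix(X)
  n <- nrow(Xm)
  if (n < config@nFolds) stop("need at least nFolds observations")
  if (!is.null(seed)) set.seed(seed)
  folds <- .cvFolds(y, config@nFolds, stratify = config@loss == "poisson")
  k <- max(folds)

  foldDev <- NULL     # folds x checkpoints residual deviance
  foldCor <- NULL
  checkTrees <- NULL
  for (fi in seq_len(k)) {
    test <- folds == fi
    fit <- .cppBoost(Xm[!test, , drop = FALSE], as.numeric(y[!test]),
                     config@loss, as.integer(maxTrees), config@learningRate,
                     config@treeComplexity, config@bagFraction, config@minObs,
                     Xm[test, , drop = FALSE], config@stepSize, FALSE)
    checkTrees <- fit$checkpointTrees
    mu <- fit$testCheckpoints
    if (config@loss == "poisson") mu <- exp(mu)
    dev <- apply(mu, 1, function(m) devianceStat(y[test], m, config@loss))
    cr <- apply(mu, 1, function(m)
      suppressWarnings(stats::cor(y[test], m)))
    foldDev <- rbind(foldDev, dev)
    foldCor <- rbind(foldCor, cr)
  }
  meanDev <- colMeans(foldDev)
  best <- which.min(meanDev)
  nTrees <- checkTrees[best]
  if (nTrees < 1000)
    warning("cross-validation selected ", nTrees, " trees (< 1000); ",
            "consider lowering the learning rate (e.g. to ",
            format(config@learningRate / 10), ")")

  model <- fitBRT(Xm, y, config, nTrees = nTrees)
  muTrain <- predict(model, Xm, type = "response")
  nullDev <- devianceStat(y, rep(.nullPrediction(y, config@loss), n),
                          config@loss)
  trainDev <- devianceStat(y, muTrain, config@loss)
  cvCor <- foldCor[, best]
  evaluation <- list(
    nTrees = nTrees,
    trainingDevianceExplained = devianceExplained(nullDev, trainDev),
    trainingCorrelation = suppressWarnings(stats::cor(y, muTrain)),
    meanNullDeviance = nullDev,
    meanCVResidualDeviance = meanDev[best],
    cvResidualDevianceSE = stats::sd(foldDev[, best]) / sqrt(k),
    cvDevianceExplained = devianceExplained(nullDev, meanDev[best]),
    cvCorrelation = mean(cvCor, na.rm = TRUE),
    cvCorrelationSE = stats::sd(cvCor, na.rm = TRUE) / sqrt(k))
  list(model = model, nTrees = nTrees, evaluation = evaluation)
}

.nullPrediction <- function(y, loss) mean(y)

## Seeded fold assignment; stratified by response tertile when asked, which
## stabilises the small-N section models under the Poisson loss.
.cvFolds <- function(y, nFolds, stratify = FALSE) {
  n <- length(y)
  folds <- integer(n)
  if (stratify) {
    strata <- cut(rank(y, ties.method = "first"), 3, labels = FALSE)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      folds[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
  } else {
    folds <- sample(rep_len(seq_len(nFolds), n))
  }
  folds
}

#' Relative influence of the predictors
#'
#' gbm-style accounting: each split's squared-error reduction is credited to
#' its predictor, totals are scaled to percentages (sum 100). With a category
#' map the per-category aggregates (physical, land use, chemical, spatial)
#' are attached.
#'
#' @param m a fitted [BRTModel-class].
#' @param categories optional named character vector mapping variable names
#'   to categories.
#' @return data.frame with variable, influence (and category); per-category
#'   totals in the `"categoryInfluence"` attribute.
#' @export
relativeInfluence <- function(m, categories = NULL) {
  stopifnot(is(m, "BRTModel"))
  imp <- m@varImprovement
  total <- sum(imp)
  infl <- if (total > 0) 100 * imp / total else {
    warning("no splits improved the model; influences undefined (all 0)")
    imp * 0
  }
  out <- data.frame(variable = names(infl), influence = as.numeric(infl),
                    row.names = NULL)
  out <- out[order(-out$influence), ]
  rownames(out) <- NULL
  if (!is.null(categories)) {
    out$category <- unname(categories[out$variable])
    agg <- tapply(out$influence, out$category, sum)
    attr(out, "categoryInfluence") <- agg
  }
  out
}

#' Assemble the predictor table for a BRT model
#'
#' All physical, land-use and chemical variables of the site table; the raw
#' catchment size is included only for the all-sites model (the section
#' subsets are themselves defined by catchment-size ranges); the two spatial
#' principal-coordinate vectors are appended when supplied; an optional
#' two-level drainage factor marks the major catchment a site belongs to.
#'
#' @param t site table (see [validateSiteTable()]); columns other than
#'   `site_id`, `x`, `y`, `drainage` are treated as predictors, with
#'   `catchment_size` and `elevation` categorised as physical, `landuse_*`
#'   as land use, and the rest as chemical.
#' @param pcoa optional [PCoAVectors-class] of geographic distances.
#' @param section `"all"` or one of [riverSections()].
#' @param includeDrainage append the `drainage` factor column.
#' @return data.frame of predictors with a `"categories"` attribute (named
#'   character vector) for [relativeInfluence()].
#' @export
assemblePredictors <- function(t, pcoa = NULL, section = "all",
                               includeDrainage = FALSE) {
  validateSiteTable(t)
  stopifnot(section %in% c("all", riverSections()))
  drop <- c("site_id", "x", "y", "drainage")
  vars <- setdiff(names(t), drop)
  if (section != "all") vars <- setdiff(vars, "catchment_size")
  if (!length(vars)) stop("no predictor columns in the site table")
  X <- t[, vars, drop = FALSE]
  cat <- ifelse(vars %in% c("catchment_size", "elevation"), "physical",
                ifelse(grepl("^landuse_", vars), "land use", "chemical"))
  names(cat) <- vars
  if (!is.null(pcoa)) {
    stopifnot(is(pcoa, "PCoAVectors"))
    if (nrow(pcoa@vectors) != nrow(t))
      stop("spatial vectors do not match the site table")
    X <- cbind(X, as.data.frame(pcoa@vectors))
    cat <- c(cat, stats::setNames(rep("spatial", ncol(pcoa@vectors)),
                                  colnames(pcoa@vectors)))
  }
  if (includeDrainage) {
    if (is.null(t$drainage)) stop("site table has no 'drainage' column")
    X$drainage <- factor(t$drainage)
    if (nlevels(X$drainage) != 2) stop("drainage must have two levels")
    cat <- c(cat, drainage = "spatial")
  }
  attr(X, "categories") <- cat
  X
}
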
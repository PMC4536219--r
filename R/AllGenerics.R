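#' Accessors for community matrices and results
#'
#' `siteIDs`/`taxonIDs` return identifiers, `nSites`/`nTaxa` the dimensions,
#' and `as.matrix` the underlying numeric matrix of a community container.
#'
#' @param x a [CommunityMatrix-class] (or result object, where applicable).
#' @return character vector, integer, or matrix as appropriate.
#' @examples
#' m <- IncidenceMatrix(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("t1", "t2"))))
#' siteIDs(m); nTaxa(m)
#' @name community-accessors
#' @aliases siteIDs taxonIDs nSites nTaxa
NULL

#' @rdname community-accessors
#' @export
setGeneric("siteIDs", function(x) standardGeneric("siteIDs"))
#' @rdname community-accessors
#' @export
setGeneric("taxonIDs", function(x) standardGeneric("taxonIDs"))
#' @rdname community-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname community-accessors
#' @export
setGeneric("nTaxa", function(x) standardGeneric("nTaxa"))

#' @rdname community-accessors
setMethod("siteIDs", "CommunityMatrix", function(x) rownames(x@mat))
#' @rdname community-accessors
setMethod("taxonIDs", "CommunityMatrix", function(x) colnames(x@mat))
#' @rdname community-accessors
setMethod("nSites", "CommunityMatrix", function(x) nrow(x@mat))
#' @rdname community-accessors
setMethod("nTaxa", "CommunityMatrix", function(x) ncol(x@mat))

#' @rdname community-accessors
#' @param ... ignored.
#' @export
setMethod("as.matrix", "CommunityMatrix", function(x, ...) x@mat)

setMethod("show", "AbundanceMatrix", function(object) {
  cat(sprintf("AbundanceMatrix: %d sites x %d taxa, %d individuals\n",
              nSites(object), nTaxa(object), sum(object@mat)))
})

setMethod("show", "IncidenceMatrix", function(object) {
  cat(sprintf("IncidenceMatrix: %d sites x %d taxa, fill %.1f%%\n",
              nSites(object), nTaxa(object), 100 * mean(object@mat)))
})

setMethod("show", "RAResult", function(object) {
  cat(sprintf(
    "RAResult: %d sites, %d taxa, %d axes (eigenvalues %s)\n",
    nrow(object@siteScores), nrow(object@taxonScores),
    ncol(object@siteScores),
    paste(signif(object@eigenvalues, 4), collapse = ", ")))
})

setMethod("show", "NullEnsemble", function(object) {
  d <- dim(object@matrices[[1]])
  cat(sprintf("NullEnsemble: %d '%s' matrices of %d x %d (seed %d)\n",
              length(object@matrices), object@method, d[1], d[2],
              object@seed))
})

setMethod("show", "EMSTestResult", function(object) {
  cat(sprintf(
    "%s: observed %s, null %.1f (SD %.2f), z = %.2f, p = %.3g (n = %d)\n",
    object@statisticName, format(object@observed), object@nullMean,
    object@nullSD, object@z, object@p, object@nNull))
})

setMethod("show", "ClumpingResult", function(object) {
  cat(sprintf(
    "Boundary clumping: Morisita %.3f, chi2 = %.2f (df %d), p = %.3g\n",
    object@morisita, object@chi2, object@df, object@p))
})

setMethod("show", "StructureClassification", function(object) {
  cat(sprintf("Axis %d best-fit structure: %s (alpha = %g)\n",
              object@axis, object@label, object@alpha))
  show(object@coherence)
  if (!is.null(object@turnover)) show(object@turnover)
  if (!is.null(object@clumping)) show(object@clumping)
})

setMethod("show", "BRTModel", function(object) {
  cat(sprintf(
    "BRTModel: %d trees (%s loss, lr %g, complexity %d, bag %g)\n",
    object@nTrees, object@config@loss, object@config@learningRate,
    object@config@treeComplexity, object@config@bagFraction))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %s, %d sites x %d taxa, noise %g, seed %d\n",
    object@structure, object@nSites, object@nTaxa, object@noiseEps,
    object@seed))
})
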
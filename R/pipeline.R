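#' Run the full regional-assemblage analysis
#'
#' Orchestrates every stage for the combined data and the three river
#' sections: EMS classification of ordination axes 1 and 2 (shared null
#' ensemble per site set), per-site diversity with between-section ANOVA +
#' Tukey HSD and Bray-Curtis beta dispersion, and boosted regression trees
#' predicting richness (Poisson) and the primary ordination axis (Gaussian;
#' axis 2 is classified but never modelled against the environment), with and
#' without the spatial principal-coordinate predictors, and optionally with a
#' two-level drainage factor on the all-sites models.
#'
#' @param abundance an [AbundanceMatrix-class].
#' @param siteTable site table (see [validateSiteTable()]) with coordinates.
#' @param nSim null matrices per EMS test (default 1000).
#' @param seed root seed for all randomised stages.
#' @param alpha significance level (default 0.05).
#' @param breaks catchment-size section breaks in km^2 (default 20, 100).
#' @param rarefyN rarefaction sample size (default 100 individuals).
#' @param minSites rare-taxon threshold (default 2 sites).
#' @param refilterSections re-apply the rare-taxon filter inside each section
#'   subset (default TRUE; a taxon at two sites overall may occupy one site
#'   within a subset).
#' @param learningRate,maxTrees BRT shrinkage and tree-count ceiling for the
#'   cross-validated selection.
#' @param spatial also fit the composition models with PCo1/PCo2 appended.
#' @param drainageFactor also fit all-sites models with the drainage factor.
#' @param minSectionSites smallest section analysed (default 10 sites).
#' @return list with elements `sections`, `ems` (classification objects and
#'   the Table-2-style data.frame), `diversity` (per-site table, test
#'   results, beta dispersion), `brt` (per model: evaluation + influence),
#'   and `manifest`.
#' @export
runPipeline <- function(abundance, siteTable, nSim = 1000, seed = 1,
                        alpha = 0.05, breaks = c(20, 100), rarefyN = 100,
                        minSites = 2, refilterSections = TRUE,
                        learningRate = 0.001, maxTrees = 5000,
                        spatial = TRUE, drainageFactor = FALSE,
                        minSectionSites = 10) {
  stopifnot(is(abundance, "AbundanceMatrix"))
  validateSiteTable(siteTable, requireCoords = TRUE)
  if (!all(siteIDs(abundance) %in% siteTable$site_id))
    stop("site table is missing sites present in the abundance matrix")
  siteTable <- siteTable[match(siteIDs(abundance), siteTable$site_id), ]
  sections <- categorizeSites(siteTable, breaks)

  incidence <- filterRareTaxa(asIncidence(abundance), minSites)
  siteSets <- c(list(all = siteIDs(abundance)),
                split(siteTable$site_id, sections))
  siteSets <- Filter(function(s) length(s) >= minSectionSites, siteSets)

  ## ---- EMS ------------------------------------------------------------
  emsResults <- list()
  raAxis1 <- list()
  setSeeds <- .deriveSeeds(as.integer(seed), length(siteSets))
  for (si in seq_along(siteSets)) {
    nm <- names(siteSets)[si]
    sub <- IncidenceMatrix(
      incidence@mat[siteIDs(incidence) %in% siteSets[[si]], , drop = FALSE])
    if (refilterSections) sub <- filterRareTaxa(sub, minSites)
    sub <- suppressMessages(dropEmptySites(sub))
    ens <- generateR1(sub, nSim, seed = setSeeds[si])
    cls <- lapply(1:2, function(ax)
      evaluateAxis(sub, axis = ax, alpha = alpha, ensemble = ens))
    emsResults[[nm]] <- cls
    ra <- reciprocalAveraging(sub, nAxes = 2)
    raAxis1[[nm]] <- stats::setNames(ra@siteScores[, 1], siteIDs(sub))
  }
  emsFlat <- unlist(emsResults, recursive = FALSE)
  emsTab <- emsTable(emsFlat,
                     labels = rep(names(emsResults), each = 2))

  ## ---- diversity ------------------------------------------------------
  divTab <- diversitySummary(abundance, sections, rarefyN)
  nonEmpty <- rowSums(abundance@mat) > 0
  bc <- brayCurtis(AbundanceMatrix(abundance@mat[nonEmpty, , drop = FALSE]))
  disp <- betaDispersion(bc, sections[nonEmpty])
  tests <- list(
    richness = anovaTukey(divTab$richness, divTab$section, alpha),
    rarefied_richness = anovaTukey(divTab$rarefied_richness,
                                   divTab$section, alpha),
    simpson = anovaTukey(divTab$simpson, divTab$section, alpha),
    beta_dispersion = anovaTukey(disp$distances, disp$group, alpha))

  ## ---- boosted regression trees --------------------------------------
  brt <- list()
  brtSeeds <- .deriveSeeds(as.integer(seed) + 1L, 4L * length(siteSets))
  bi <- 0L
  for (nm in names(siteSets)) {
    idx <- siteTable$site_id %in% siteSets[[nm]]
    st <- siteTable[idx, , drop = FALSE]
    sectionArg <- if (nm == "all") "all" else nm
    pc <- pcoaVectors(geographicDistances(st), nAxes = 2)

    rich <- richness(abundance)[st$site_id]
    Xr <- assemblePredictors(st, section = sectionArg)
    bi <- bi + 1L
    brt[[paste0(nm, "_richness")]] <- .brtStage(
      Xr, rich, "poisson", learningRate, maxTrees, brtSeeds[bi])

    scores <- raAxis1[[nm]]
    stc <- st[st$site_id %in% names(scores), , drop = FALSE]
    Xc <- assemblePredictors(stc, section = sectionArg)
    bi <- bi + 1L
    brt[[paste0(nm, "_composition")]] <- .brtStage(
      Xc, scores[stc$site_id], "gaussian", learningRate, maxTrees,
      brtSeeds[bi])

    if (spatial) {
      pcc <- pcoaVectors(geographicDistances(stc), nAxes = 2)
      Xs <- assemblePredictors(stc, pcoa = pcc, section = sectionArg)
      bi <- bi + 1L
      brt[[paste0(nm, "_composition_spatial")]] <- .brtStage(
        Xs, scores[stc$site_id], "gaussian", learningRate, maxTrees,
        brtSeeds[bi])
    }
    if (drainageFactor && nm == "all") {
      Xd <- assemblePredictors(st, section = "all", includeDrainage = TRUE)
      bi <- bi + 1L
      brt[["all_richness_drainage"]] <- .brtStage(
        Xd, rich, "poisson", learningRate, maxTrees, brtSeeds[bi])
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("riverEMS")),
    seed = seed, n_sim = nSim, alpha = alpha, breaks = breaks,
    rarefy_n = rarefyN, min_sites = minSites,
    refilter_sections = refilterSections, learning_rate = learningRate,
    max_trees = maxTrees, spatial = spatial,
    drainage_factor = drainageFactor,
    n_sites = nSites(abundance), n_taxa = nTaxa(abundance),
    section_counts = as.list(attr(sections, "counts")))

  list(sections = sections,
       ems = list(classifications = emsResults, table = emsTab),
       diversity = list(table = divTab, tests = tests, dispersion = disp),
       brt = brt, manifest = manifest)
}

.brtStage <- function(X, y, loss, learningRate, maxTrees, seed) {
  cfg <- brtConfig(loss = loss, learningRate = learningRate)
  withCallingHandlers({
    sel <- selectNTreesCV(X, y, cfg, maxTrees = maxTrees, seed = seed)
    infl <- relativeInfluence(sel$model, attr(X, "categories"))
    list(evaluation = sel$evaluation, influence = infl, nTrees = sel$nTrees)
  }, warning = function(w) {
    message("BRT note: ", conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

#' Write a pipeline report bundle
#'
#' Exports the EMS table (Table 2 layout: coherence, turnover and clumping
#' columns per site set and axis), the per-site diversity table with the
#' section test summaries, the BRT evaluation table (Table 3 layout) and the
#' long-format influence table, plus a JSON run manifest.
#'
#' @param results output of [runPipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
reportBundle <- function(results, dir) {
  if (!length(results$ems$classifications)) stop("no completed stages")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(obj, file) {
    p <- file.path(dir, file)
    utils::write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(results$ems$table, "ems_table.csv")
  wr(results$diversity$table, "diversity.csv")

  ev <- do.call(rbind, lapply(names(results$brt), function(nm) {
    e <- results$brt[[nm]]$evaluation
    data.frame(model = nm, n_trees = e$nTrees,
               training_deviance_explained = e$trainingDevianceExplained,
               training_correlation = e$trainingCorrelation,
               mean_null_deviance = e$meanNullDeviance,
               mean_cv_residual_deviance = e$meanCVResidualDeviance,
               cv_residual_deviance_se = e$cvResidualDevianceSE,
               cv_deviance_explained = e$cvDevianceExplained,
               cv_correlation = e$cvCorrelation,
               cv_correlation_se = e$cvCorrelationSE)
  }))
  wr(ev, "brt_evaluation.csv")

  infl <- do.call(rbind, lapply(names(results$brt), function(nm) {
    tab <- results$brt[[nm]]$influence
    cbind(model = nm, tab)
  }))
  wr(infl, "brt_influence.csv")

  tj <- file.path(dir, "diversity_tests.json")
  jsonlite::write_json(
    lapply(results$diversity$tests, function(tst)
      list(F = tst$F, df1 = tst$df1, df2 = tst$df2, p = tst$p,
           letters = as.list(tst$letters))),
    tj, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, tj)

  mj <- file.path(dir, "manifest.json")
  jsonlite::write_json(results$manifest, mj, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, mj)
  invisible(paths)
}
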
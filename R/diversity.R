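## Alpha diversity, Bray-Curtis beta dispersion, and between-section
## inference. The standard metrics are delegated to vegan (rarefy, diversity,
## vegdist, betadisper) behind this module's interface.

#' Taxonomic richness per site
#'
#' @param a an [AbundanceMatrix-class] or [IncidenceMatrix-class].
#' @return named integer vector: number of taxa with count > 0 per site.
#' @export
richness <- function(a) {
  stopifnot(is(a, "CommunityMatrix"))
  rowSums(a@mat > 0)
}

#' Rarefied richness (expected taxa per standard count of individuals)
#'
#' Hurlbert's expectation `E(S_n) = sum_i [1 - choose(N - N_i, n) /
#' choose(N, n)]` of the number of taxa in a random subsample of `n`
#' individuals. Sites with fewer than `n` individuals return their observed
#' richness and are flagged.
#'
#' @param a an [AbundanceMatrix-class].
#' @param n subsample size (default 100 individuals).
#' @return named numeric vector with a logical `"flagged"` attribute marking
#'   sites whose total count was below `n`.
#' @export
rarefiedRichness <- function(a, n = 100) {
  stopifnot(is(a, "AbundanceMatrix"))
  if (n <= 0) stop("n must be positive")
  N <- rowSums(a@mat)
  out <- numeric(nSites(a))
  names(out) <- siteIDs(a)
  small <- N < n
  if (any(!small))
    out[!small] <- withCallingHandlers(
      vegan::rarefy(a@mat[!small, , drop = FALSE], sample = n),
      warning = function(w) {
        # vegan advises when every count exceeds 1; harmless for real counts
        if (grepl("smallest count", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  if (any(small)) {
    out[small] <- richness(a)[small]
    warning(sum(small), " site(s) had fewer than ", n,
            " individuals; observed richness returned and flagged")
  }
  attr(out, "flagged") <- stats::setNames(small, siteIDs(a))
  out
}

#' Simpson's diversity index per site
#'
#' `1 - sum(p_i^2)` with `p_i` the relative abundances; 0 for a monoculture.
#' Empty sites are undefined and returned as NA with a warning.
#'
#' @param a an [AbundanceMatrix-class].
#' @return named numeric vector in [0, 1).
#' @export
simpsonIndex <- function(a) {
  stopifnot(is(a, "AbundanceMatrix"))
  tot <- rowSums(a@mat)
  out <- vegan::diversity(a@mat, index = "simpson")
  if (any(tot == 0)) {
    out[tot == 0] <- NA_real_
    warning("empty site(s): Simpson's index undefined, returned NA")
  }
  out
}

#' Bray-Curtis dissimilarities between sites
#'
#' @param a an [AbundanceMatrix-class] with no empty sites.
#' @return `dist` object in [0, 1].
#' @export
brayCurtis <- function(a) {
  stopifnot(is(a, "AbundanceMatrix"))
  if (any(rowSums(a@mat) == 0))
    stop("Bray-Curtis is undefined for empty sites; drop them first")
  vegan::vegdist(a@mat, method = "bray")
}

#' Multivariate dispersion (distance to group centroid)
#'
#' Beta diversity of each river section as the dispersion of its sites in the
#' principal-coordinate space of a dissimilarity matrix: each site's distance
#' to its own group centroid, keeping axes with negative eigenvalues through
#' the imaginary correction `sqrt(max(d_real^2 - d_imag^2, 0))` (Bray-Curtis
#' is non-Euclidean). Group differences are tested with a one-way ANOVA F on
#' the distances.
#'
#' @param d `dist` object (e.g. from [brayCurtis()]).
#' @param groups factor of group memberships (>= 2 groups of >= 2 sites).
#' @return list with `distances` (named per site), `group`, and `anova`
#'   (data.frame with F, df and p).
#' @export
betaDispersion <- function(d, groups) {
  stopifnot(inherits(d, "dist"))
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size"))
    stop("groups must match the distance matrix")
  tab <- table(droplevels(groups))
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < 2)) stop("every group needs at least two sites")
  bd <- vegan::betadisper(d, groups, type = "centroid")
  an <- stats::anova(bd)
  list(distances = bd$distances, group = groups,
       anova = data.frame(F = an$F[1], df1 = an$Df[1], df2 = an$Df[2],
                          p = an$`Pr(>F)`[1]))
}

#' One-way ANOVA with Tukey HSD letters
#'
#' Standard one-way ANOVA (F with k-1, N-k df) followed by Tukey's honest
#' significant difference for all pairwise group contrasts, summarised as a
#' compact letter display (groups sharing a letter do not differ at `alpha`).
#'
#' @param values numeric response per site.
#' @param groups factor of group memberships (>= 2 groups, >= 2 values each).
#' @param alpha significance level for the letters (default 0.05).
#' @return list with `F`, `df1`, `df2`, `p`, `tukey` (data.frame of pairwise
#'   differences and adjusted p), and `letters` (named by group).
#' @export
anovaTukey <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs at least two values")
  if (all(tapply(values, groups, stats::var) == 0))
    stop("zero within-group variance in all groups")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  pm <- .pairwiseMatrix(tukey, levels(groups))
  list(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
       p = an$`Pr(>F)`[1], tukey = tukey,
       letters = .letterDisplay(pm, alpha))
}

.pairwiseMatrix <- function(tukey, lev) {
  pm <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
  ## contrast strings are "levB-levA"; match against the known level set
  ## rather than splitting on "-" (level names may contain hyphens)
  pairs <- expand.grid(a = lev, b = lev, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  key <- paste(pairs$b, pairs$a, sep = "-")
  for (i in seq_len(nrow(tukey))) {
    hit <- match(tukey$contrast[i], key)
    if (is.na(hit)) stop("cannot parse Tukey contrast: ", tukey$contrast[i])
    pm[pairs$a[hit], pairs$b[hit]] <- tukey$p_adj[i]
    pm[pairs$b[hit], pairs$a[hit]] <- tukey$p_adj[i]
  }
  pm
}

## Compact letter display: letters = maximal cliques of the "not
## significantly different" graph, found by subset enumeration (few groups).
.letterDisplay <- function(pmat, alpha) {
  lev <- rownames(pmat)
  k <- length(lev)
  ns <- pmat >= alpha
  diag(ns) <- TRUE
  cliques <- list()
  for (code in seq_len(2^k - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    if (all(ns[members, members])) cliques <- c(cliques, list(members))
  }
  sizes <- lengths(cliques)
  maximal <- vapply(seq_along(cliques), function(i) {
    !any(sizes > sizes[i] & vapply(cliques, function(cl)
      all(cliques[[i]] %in% cl), logical(1)))
  }, logical(1))
  cliques <- cliques[maximal]
  cliques <- cliques[order(vapply(cliques, min, integer(1)))]
  out <- stats::setNames(rep("", k), lev)
  for (i in seq_along(cliques))
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  out
}

#' Per-site diversity summary table
#'
#' @param a an [AbundanceMatrix-class].
#' @param sections factor of river sections per site (see
#'   [categorizeSites()]), optional.
#' @param rarefyN rarefaction sample size (default 100 individuals).
#' @return data.frame with site_id, richness, rarefied_richness (with
#'   `rarefied_flagged`), simpson, and section.
#' @export
diversitySummary <- function(a, sections = NULL, rarefyN = 100) {
  rr <- rarefiedRichness(a, n = rarefyN)
  data.frame(
    site_id = siteIDs(a),
    richness = as.integer(richness(a)),
    rarefied_richness = as.numeric(rr),
    rarefied_flagged = as.logical(attr(rr, "flagged")),
    simpson = as.numeric(simpsonIndex(a)),
    section = if (is.null(sections)) NA else
      as.character(sections[siteIDs(a)]),
    row.names = NULL)
}
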
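#' Construct an abundance matrix
#'
#' @param mat numeric matrix of non-negative integer counts, sites as rows,
#'   taxa as columns; dimnames are the identifiers. A data.frame is accepted.
#' @return an [AbundanceMatrix-class].
#' @examples
#' AbundanceMatrix(matrix(0:3, 2, 2,
#'   dimnames = list(c("s1", "s2"), c("t1", "t2"))))
#' @export
AbundanceMatrix <- function(mat) {
  mat <- .asCommunityMatrix(mat)
  new("AbundanceMatrix", mat = mat)
}

#' Construct an incidence matrix
#'
#' @param mat binary matrix (0/1), sites as rows, taxa as columns, with
#'   dimnames. A data.frame is accepted.
#' @return an [IncidenceMatrix-class].
#' @export
IncidenceMatrix <- function(mat) {
  mat <- .asCommunityMatrix(mat)
  new("IncidenceMatrix", mat = mat)
}

.asCommunityMatrix <- function(mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (!is.matrix(mat)) stop("need a matrix or data.frame")
  storage.mode(mat) <- "double"
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("site", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("taxon", seq_len(ncol(mat)))
  mat
}

#' Read a site-by-taxon abundance CSV
#'
#' Expected dialect: comma-separated, UTF-8, header row of taxon identifiers,
#' first column of site identifiers, integer cells.
#'
#' @param path CSV file path.
#' @return an [AbundanceMatrix-class].
#' @seealso [writeAbundance()]
#' @export
readAbundance <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("abundance CSV needs a site-id column plus taxa")
  sites <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric cell at site '%s', taxon '%s'",
                 sites[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- sites
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative or non-integer count at site '%s', taxon '%s'",
                 sites[bad[1, 1]], colnames(m)[bad[1, 2]]))
  AbundanceMatrix(m)
}

#' Write a community matrix as CSV
#'
#' Inverse of [readAbundance()]: first column `site_id`, one column per taxon.
#'
#' @param x a [CommunityMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAbundance <- function(x, path) {
  stopifnot(is(x, "CommunityMatrix"))
  df <- data.frame(site_id = siteIDs(x), as.data.frame(x@mat),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Collapse counts to presence/absence
#'
#' @param a an [AbundanceMatrix-class] or [IncidenceMatrix-class] (the latter
#'   is returned unchanged, so the operation is idempotent).
#' @return an [IncidenceMatrix-class] with presence = 1 iff count > 0.
#' @export
asIncidence <- function(a) {
  if (is(a, "IncidenceMatrix")) return(a)
  stopifnot(is(a, "AbundanceMatrix"))
  IncidenceMatrix(1 * (a@mat > 0))
}

#' Drop taxa occurring at fewer than `minSites` sites
#'
#' Rare taxa bias the coherence and boundary-clumping components of the EMS
#' analysis; taxa found at fewer than two sites are excluded by default.
#' Site rows are kept (possibly becoming empty); see [dropEmptySites()].
#'
#' @param m an [IncidenceMatrix-class].
#' @param minSites minimum number of occupied sites for a taxon to be kept.
#' @return filtered [IncidenceMatrix-class].
#' @export
filterRareTaxa <- function(m, minSites = 2) {
  stopifnot(is(m, "IncidenceMatrix"))
  keep <- colSums(m@mat) >= minSites
  if (!any(keep))
    stop("no taxa occur at >= ", minSites, " sites")
  IncidenceMatrix(m@mat[, keep, drop = FALSE])
}

#' Drop sites with no occurrences
#'
#' Reciprocal averaging is undefined for all-zero rows, so empty sites are
#' removed from the EMS input (they stay in diversity analyses). Dropped
#' identifiers are attached as the `"dropped"` attribute and messaged.
#'
#' @param m an [IncidenceMatrix-class].
#' @return an [IncidenceMatrix-class] without all-zero rows; attribute
#'   `"dropped"` holds the removed site ids.
#' @export
dropEmptySites <- function(m) {
  stopifnot(is(m, "IncidenceMatrix"))
  empty <- rowSums(m@mat) == 0
  if (all(empty)) stop("all sites are empty")
  dropped <- siteIDs(m)[empty]
  out <- IncidenceMatrix(m@mat[!empty, , drop = FALSE])
  if (length(dropped))
    message("dropped empty sites: ", paste(dropped, collapse = ", "))
  attr(out, "dropped") <- dropped
  out
}

#' Validate a site (environmental) table
#'
#' The site table carries one row per site: `site_id`, `catchment_size`
#' (km^2, > 0), `elevation` (m a.s.l.), planar coordinates `x`, `y` (m),
#' land-use percentages (columns flagged by the `"landuse"` prefix or listed
#' in `landUse`) and chemical summary means.
#'
#' @param t data.frame site table.
#' @param requireCoords require `x`/`y` columns.
#' @return `t`, invisibly, or an error.
#' @export
validateSiteTable <- function(t, requireCoords = FALSE) {
  stopifnot(is.data.frame(t))
  need <- c("site_id", "catchment_size")
  if (requireCoords) need <- c(need, "x", "y")
  miss <- setdiff(need, names(t))
  if (length(miss))
    stop("site table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(t$site_id)) stop("site_id must be unique")
  if (anyNA(t$catchment_size)) stop("missing catchment size")
  if (any(t$catchment_size <= 0)) stop("catchment sizes must be positive")
  lu <- grep("^landuse_", names(t), value = TRUE)
  for (v in lu)
    if (any(t[[v]] < 0 | t[[v]] > 100, na.rm = TRUE))
      stop("land-use percentage out of [0, 100] in ", v)
  invisible(t)
}

#' Read a site table CSV
#'
#' @param path CSV with the [validateSiteTable()] schema.
#' @param requireCoords passed to [validateSiteTable()].
#' @return validated data.frame.
#' @export
readSiteTable <- function(path, requireCoords = FALSE) {
  t <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  validateSiteTable(t, requireCoords = requireCoords)
  t
}

#' River-section labels
#'
#' @return the ordered labels of the catchment-size partition.
#' @export
riverSections <- function() c("headwaters", "mid-sized", "large")

#' Categorise sites into river sections by catchment size
#'
#' Sites are partitioned by upstream catchment area into headwaters
#' `[min, breaks[1])`, mid-sized `[breaks[1], breaks[2])` and large rivers
#' `[breaks[2], Inf)`. The intervals are half-open on the right so that every
#' site falls in exactly one class (a site at exactly 100 km^2 is "large").
#'
#' @param t site table with `catchment_size` in km^2.
#' @param breaks two increasing break points in km^2 (default 20 and 100).
#' @return factor of section labels, named by `site_id`, with a `"counts"`
#'   attribute giving the per-class site counts.
#' @examples
#' t <- data.frame(site_id = c("a", "b", "c"),
#'                 catchment_size = c(3.34, 20, 975.23))
#' categorizeSites(t)
#' @export
categorizeSites <- function(t, breaks = c(20, 100)) {
  validateSiteTable(t)
  stopifnot(length(breaks) == 2, breaks[1] < breaks[2])
  sec <- cut(t$catchment_size, c(-Inf, breaks, Inf), right = FALSE,
             labels = riverSections())
  names(sec) <- t$site_id
  attr(sec, "counts") <- table(sec)
  sec
}
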
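#' Plate-wise standard scaling against DMSO controls
#'
#' Each feature is z-scored within its plate using the mean and sample
#' standard deviation of that plate's DMSO (negative control) cells only:
#' `z = (f - mu_DMSO) / sd_DMSO`. Features constant across a plate's DMSO
#' cells are set to 0 on that plate and reported in the
#' `"flagged_constant"` attribute.
#'
#' @param features Feature table from [extract_features()] (metadata plus
#'   catalog columns).
#' @param dmso Logical vector marking DMSO rows, or `NULL` to use
#'   `features$treatment == "DMSO"`.
#' @return The table with feature columns replaced by their per-plate
#'   z-scores; attribute `flagged_constant` is a data.frame of
#'   (plate, feature) pairs that were zeroed.
#' @export
normalize_platewise <- function(features, dmso = NULL) {
  if (is.null(dmso)) dmso <- features$treatment == "DMSO"
  stopifnot(length(dmso) == nrow(features))
  fcols <- intersect(feature_catalog(), names(features))
  if (!length(fcols)) stop("normalize_platewise: no catalog feature columns")
  flagged <- list()
  for (p in unique(features$plate)) {
    on_plate <- features$plate %in% p
    ref <- on_plate & dmso
    if (sum(ref) < 2)
      stop("normalize_platewise: plate '", p, "' has fewer than 2 DMSO cells")
    mu <- colMeans(features[ref, fcols, drop = FALSE])
    sdv <- vapply(features[ref, fcols, drop = FALSE], stats::sd, numeric(1))
    const <- sdv == 0 | !is.finite(sdv)
    for (f in fcols) {
      if (const[[f]]) {
        features[on_plate, f] <- 0
      } else {
        features[on_plate, f] <- (features[on_plate, f] - mu[[f]]) / sdv[[f]]
      }
    }
    if (any(const))
      flagged[[length(flagged) + 1]] <-
        data.frame(plate = p, feature = fcols[const], stringsAsFactors = FALSE)
  }
  attr(features, "flagged_constant") <- if (length(flagged))
    do.call(rbind, flagged) else
    data.frame(plate = character(0), feature = character(0))
  features
}

#' 2-D UMAP embedding of single-cell profiles
#'
#' Deterministic wrapper around [uwot::umap()]: single-threaded
#' optimization under a caller-supplied seed, so identical input and seed
#' give identical coordinates. The embedding internals are delegated; this
#' layer owns determinism and input validation only.
#'
#' @param features Feature table ([extract_features()] /
#'   [normalize_platewise()] output) or a numeric matrix.
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighborhood size (needs `>= n_neighbors + 1`
#'   rows).
#' @return Numeric matrix, one row per input row, columns `umap1`, `umap2`.
#' @export
embed_2d <- function(features, seed = 42, n_neighbors = 15) {
  X <- if (is.matrix(features)) features else {
    fcols <- intersect(feature_catalog(), names(features))
    as.matrix(features[, fcols, drop = FALSE])
  }
  if (nrow(X) < n_neighbors + 1)
    stop("embed_2d: need at least n_neighbors + 1 = ", n_neighbors + 1,
         " rows, got ", nrow(X))
  coords <- .with_seed(seed,
    uwot::umap(X, n_neighbors = n_neighbors, n_components = 2,
               n_threads = 1, n_sgd_threads = 1, batch = TRUE,
               verbose = FALSE))
  colnames(coords) <- c("umap1", "umap2")
  coords
}

#' Hierarchical clustering of treatment-level profiles
#'
#' Aggregates normalized single-cell features to group means (one profile
#' per treatment x model group), computes pairwise Euclidean distances and
#' clusters them by average-linkage agglomeration. Groups enter in
#' lexicographic name order, making leaf order deterministic.
#'
#' @param features Feature table with catalog columns (normalized).
#' @param grouping Character/factor vector, one group label per row.
#' @return List with `profiles` (group x feature matrix), `dist`, and `hc`
#'   (an [stats::hclust] tree; degenerate single-group input gives
#'   `hc = NULL`).
#' @export
cluster_profiles <- function(features, grouping) {
  stopifnot(length(grouping) == nrow(features))
  fcols <- intersect(feature_catalog(), names(features))
  X <- as.matrix(features[, fcols, drop = FALSE])
  groups <- sort(unique(as.character(grouping)))
  profiles <- do.call(rbind, lapply(groups, function(g)
    colMeans(X[grouping == g, , drop = FALSE])))
  rownames(profiles) <- groups
  if (length(groups) < 2)
    return(list(profiles = profiles, dist = NULL, hc = NULL))
  d <- stats::dist(profiles, method = "euclidean")
  list(profiles = profiles, dist = d,
       hc = stats::hclust(d, method = "average"))
}
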
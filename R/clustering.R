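#' Gut-similarity distance matrix from flux profiles
#'
#' Pairwise Euclidean distances `d_ij` between per-node flux vectors and the
#' derived gut similarity `theta_ij = max(floor, 1 - d_ij / max d)` used to
#' rescale the Fermi temperature (most distant pair at the floor, identical
#' profiles at 1). Profiles must share one reaction index. Fluxes are used
#' raw by default (all entries share units); `standardize` z-scores each
#' reaction column first.
#'
#' @param profiles Nodes x reactions numeric matrix, or a list of
#'   `flux_profile` objects over the same reaction set.
#' @param floor Lower bound of theta in (0, 1).
#' @param standardize Z-score columns before computing distances?
#' @return Object of class `gut_distance`: list with `d` (distance matrix),
#'   `theta` (similarity matrix) and `floor`.
#' @examples
#' X <- rbind(a = c(0, 0), b = c(3, 4))
#' flux_distance_matrix(X)$d["a", "b"]  # 5
#' @export
flux_distance_matrix <- function(profiles, floor = 0.05,
                                 standardize = FALSE) {
  if (is.list(profiles) && !is.data.frame(profiles) &&
      !is.matrix(profiles)) {
    rn <- lapply(profiles, function(p) names(p$flux))
    if (!all(vapply(rn, identical, logical(1), rn[[1]])))
      stop("profiles must share the same reaction set", call. = FALSE)
    profiles <- do.call(rbind, lapply(profiles, function(p) p$flux))
  }
  X <- as.matrix(profiles)
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    X <- scale(X, scale = ifelse(sds > 0, sds, 1))
  }
  d <- as.matrix(stats::dist(X))
  mx <- max(d)
  theta <- if (mx > 0) pmax(1 - d / mx, floor)
           else matrix(1, nrow(d), ncol(d), dimnames = dimnames(d))
  diag(theta) <- 1
  structure(list(d = d, theta = theta, floor = floor),
            class = "gut_distance")
}

#' @export
print.gut_distance <- function(x, ...) {
  cat("Gut distance over", nrow(x$d), "nodes; max distance",
      round(max(x$d), 4), "| theta floor", x$floor, "\n")
  invisible(x)
}

#' Ward agglomerative clustering of flux profiles
#'
#' Minimum-variance (Ward) linkage on the Euclidean flux distances: at each
#' step the pair of clusters whose merge least increases the total
#' within-cluster sum of squared distances to cluster means is joined.
#'
#' @param d A [flux_distance_matrix()] object, a `dist`, or a square distance
#'   matrix of Euclidean distances.
#' @return An `hclust` object (`merge`, `height`, `labels`).
#' @export
ward_clustering <- function(d) {
  if (inherits(d, "gut_distance")) d <- d$d
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  stats::hclust(d, method = "ward.D2")
}

#' Cut a dendrogram into clusters
#'
#' Deterministic labels (clusters numbered by first appearance in node-id
#' order, i.e. ties go to the lower node id).
#'
#' @param dendro An `hclust` object.
#' @param k Number of clusters, or
#' @param h Height threshold (used if `k` is `NULL`; defaults to 0.7 of the
#'   maximum merge height, mirroring the usual dendrogram display cut).
#' @return Integer vector of per-node labels.
#' @export
cut_clusters <- function(dendro, k = NULL, h = NULL) {
  n <- length(dendro$order)
  if (!is.null(k)) {
    if (k > n) stop("k cannot exceed the number of nodes", call. = FALSE)
    return(stats::cutree(dendro, k = k))
  }
  h <- h %||% (0.7 * max(dendro$height))
  stats::cutree(dendro, h = h)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths carry the merge heights.
#'
#' @param dendro An `hclust` object.
#' @param path Output file.
#' @export
write_newick <- function(dendro, path) {
  ape::write.tree(ape::as.phylo(dendro), file = path)
  invisible(path)
}
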
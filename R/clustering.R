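# Hierarchical agglomerative clustering of polymers on standardized
# descriptors: Manhattan (city-block) distances, complete linkage.

#' Manhattan distance matrix between polymers
#'
#' City-block distance on (by default standardized) descriptor rows:
#' `d_ij = sum_k |z_ik - z_jk|`. Computed on z-scored columns so that
#' molecular-weight-scale descriptors do not dominate mixed-unit tables.
#'
#' @param x A `standardized_table` (from [standardize_descriptors()]), a
#'   [descriptor_table()], or a bare numeric matrix. A `descriptor_table` is
#'   standardized first unless `scale = FALSE`.
#' @param scale Standardize a raw table before computing distances
#'   (default `TRUE`; ignored for an already-standardized input).
#' @return An object of class `polymer_dist`: list with `ids` and `values`
#'   (symmetric matrix, zero diagonal).
#' @export
manhattan_distances <- function(x, scale = TRUE) {
  m <- if (inherits(x, "standardized_table")) {
    x$z_values
  } else if (inherits(x, "descriptor_table")) {
    if (scale) standardize_descriptors(x)$z_values else x$values
  } else {
    as.matrix(x)
  }
  if (nrow(m) < 2L) stop("need at least 2 polymers")
  if (anyNA(m) || any(!is.finite(m))) stop("distance input contains NA/Inf")
  d <- as.matrix(stats::dist(m, method = "manhattan"))
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, values = d), class = "polymer_dist")
}

#' Complete-linkage hierarchical clustering of polymers
#'
#' Agglomerates polymers by repeatedly merging the pair of clusters with the
#' smallest inter-cluster distance, where the distance between clusters is
#' the maximum over cross-pair leaf distances; the merge height is that
#' distance. Complete linkage guarantees nondecreasing merge heights (no
#' dendrogram inversions).
#'
#' @param d A `polymer_dist` from [manhattan_distances()] (or a `dist` /
#'   symmetric matrix).
#' @return An object of class `polymer_hclust`: list with the underlying
#'   [stats::hclust] object (`hclust`), `ids`, and `merges` (data frame:
#'   step, a, b, height; negative a/b index leaves, positive index prior
#'   merge steps, following the `hclust` convention).
#' @export
cluster_polymers <- function(d) {
  if (inherits(d, "polymer_dist")) {
    dd <- stats::as.dist(d$values)
    ids <- d$ids
  } else {
    dd <- stats::as.dist(d)
    ids <- attr(dd, "Labels") %||% as.character(seq_len(attr(dd, "Size")))
  }
  hc <- stats::hclust(dd, method = "complete")
  hc$labels <- ids
  merges <- data.frame(step = seq_len(nrow(hc$merge)),
                       a = hc$merge[, 1L], b = hc$merge[, 2L],
                       height = hc$height)
  structure(list(hclust = hc, ids = ids, merges = merges),
            class = "polymer_hclust")
}

#' @export
print.polymer_hclust <- function(x, ...) {
  cat("<polymer_hclust> complete linkage,", length(x$ids), "polymers,",
      nrow(x$merges), "merges\n")
  cat("  merge heights:", paste(signif(range(x$merges$height), 4),
                                collapse = " .. "), "\n")
  invisible(x)
}

#' Cut a polymer cluster tree into k groups
#'
#' Undoes the last `k - 1` merges. Label values are arbitrary integers; the
#' induced partition is what is meaningful (and deterministic).
#'
#' @param tree A `polymer_hclust`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector of cluster labels (names = polymer ids).
#' @export
cut_polymer_tree <- function(tree, k) {
  stopifnot(inherits(tree, "polymer_hclust"))
  n <- length(tree$ids)
  if (k < 1L || k > n) stop("k must be in [1, ", n, "]")
  stats::cutree(tree$hclust, k = k)
}

#' Serialize a cluster tree to Newick
#'
#' Ultrametric export: leaf depths equal half the root merge height, the
#' standard dendrogram-to-phylogram convention of [ape::as.phylo()].
#'
#' @param tree A `polymer_hclust`.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
tree_to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "polymer_hclust"))
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Write the merge table of a cluster tree to CSV
#'
#' @param tree A `polymer_hclust`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_merge_table <- function(tree, path) {
  stopifnot(inherits(tree, "polymer_hclust"))
  utils::write.csv(tree$merges, path, row.names = FALSE)
  invisible(path)
}
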
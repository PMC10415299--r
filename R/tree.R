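## sample_tree: a rooted dendrogram over a patient's samples, with
## optional cluster assignments.  Wraps an hclust (when produced by
## scratch_cluster) and/or an ape phylo (when read from newick).

#' Construct a sample tree
#'
#' @param hclust an `hclust` object, or NULL.
#' @param phylo an ape `phylo`, or NULL (derived from `hclust` when
#'   absent).
#' @param labels leaf labels.
#' @param clusters named integer vector of cluster assignments, or NULL.
#' @param k number of clusters.
#' @param silhouette mean silhouette width at k.
#' @param sil_by_k silhouette profile over scanned k.
#' @return object of class `sample_tree`.
#' @export
sample_tree <- function(hclust = NULL, phylo = NULL, labels = NULL,
                        clusters = NULL, k = NA_integer_,
                        silhouette = NA_real_, sil_by_k = NULL) {
  if (is.null(phylo) && !is.null(hclust)) phylo <- ape::as.phylo(hclust)
  if (is.null(labels))
    labels <- if (!is.null(hclust)) hclust$labels else phylo$tip.label
  structure(list(hclust = hclust, phylo = phylo, labels = labels,
                 clusters = clusters, k = k, silhouette = silhouette,
                 sil_by_k = sil_by_k),
            class = "sample_tree")
}

#' @export
print.sample_tree <- function(x, ...) {
  cat("sample_tree:", length(x$labels), "leaves",
      if (!is.na(x$k)) sprintf("in %d clusters (silhouette %.3f)",
                               x$k, x$silhouette) else "", "\n")
  invisible(x)
}

## hclust view of a sample_tree (reconstructed from the phylo if needed;
## requires an ultrametric binary rooted tree)
tree_as_hclust <- function(tree) {
  if (!is.null(tree$hclust)) return(tree$hclust)
  phy <- binarize_phylo(tree$phylo)
  if (is.null(phy$edge.length))
    phy <- ape::compute.brlen(phy)
  if (!ape::is.ultrametric(phy, tol = 1e-6)) {
    ## embed a non-ultrametric tree by UPGMA on its cophenetic distances
    ## (exact for ultrametric input, an approximation otherwise)
    hc <- stats::hclust(stats::as.dist(ape::cophenetic.phylo(phy)) / 2,
                        method = "average")
    return(hc)
  }
  ape::as.hclust.phylo(phy)
}

## deterministic left-leaning resolution of multifurcations: children of
## a multifurcating node are combined pairwise in order of their
## smallest leaf label (zero-length internal edges)
binarize_phylo <- function(phy) {
  if (ape::is.binary(phy)) return(phy)
  phy <- ape::makeNodeLabel(phy)
  ape::multi2di(phy, random = FALSE)
}

## encode a rooted binary tree in postorder child arrays for the MAST
## DP: returns left/right (0-based node indices, -1 at leaves) and leaf
## (0-based index into `labels`, -1 at internal nodes)
encode_tree <- function(tree, labels) {
  phy <- if (inherits(tree, "phylo")) tree else tree$phylo
  phy <- binarize_phylo(phy)
  n <- length(phy$tip.label)
  if (n != length(labels) || !setequal(phy$tip.label, labels))
    stop("leaf-set mismatch")
  m <- n + phy$Nnode
  kids <- vector("list", m)
  for (e in seq_len(nrow(phy$edge)))
    kids[[phy$edge[e, 1]]] <- c(kids[[phy$edge[e, 1]]], phy$edge[e, 2])
  if (any(vapply(kids[(n + 1):m], length, integer(1)) != 2))
    stop("tree is not binary after resolution")
  ## postorder over internal structure
  root <- n + 1L
  order <- integer(0)
  stack <- root
  seen <- integer(0)
  while (length(stack)) {
    top <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, top)
    if (top > n) stack <- c(stack, kids[[top]])
  }
  order <- rev(seen)  # children before parents
  pos <- integer(m); pos[order] <- seq_along(order)
  left <- right <- leaf <- integer(length(order))
  for (i in seq_along(order)) {
    node <- order[i]
    if (node <= n) {
      left[i] <- -1L; right[i] <- -1L
      leaf[i] <- match(phy$tip.label[node], labels) - 1L
    } else {
      left[i] <- pos[kids[[node]][1]] - 1L
      right[i] <- pos[kids[[node]][2]] - 1L
      leaf[i] <- -1L
    }
  }
  list(left = left, right = right, leaf = leaf)
}
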
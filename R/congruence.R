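## Congruence of two dendrograms over the same leaves: Baker's Gamma on
## pairwise merge levels, and a congruence index built on the rooted
## maximum agreement subtree (MAST) with a label-permutation null.

## merge level of every leaf pair: the number of clusters present when
## the pair first co-clusters, scanning cuts from n down to 1 (the
## highest k at which the pair shares a cluster)
merge_level_matrix <- function(tree, labels) {
  hc <- tree_as_hclust(tree)
  n <- length(hc$labels)
  if (!setequal(hc$labels, labels)) stop("leaf-set mismatch")
  L <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  ## merge step m joins two clusters; pairs first united there get level n - m
  members <- as.list(seq_len(n))          # by hclust leaf index
  idx <- match(hc$labels, labels)         # hclust leaf -> label position
  grp <- vector("list", n - 1)
  for (m in seq_len(n - 1)) {
    a <- hc$merge[m, 1]; b <- hc$merge[m, 2]
    ma <- if (a < 0) -a else grp[[a]]
    mb <- if (b < 0) -b else grp[[b]]
    L[idx[ma], idx[mb]] <- n - m
    L[idx[mb], idx[ma]] <- n - m
    grp[[m]] <- c(ma, mb)
  }
  L
}

## Goodman-Kruskal gamma: (concordant - discordant) / (concordant + discordant)
gk_gamma <- function(x, y) {
  sx <- sign(outer(x, x, "-")); sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  s <- sx[up] * sy[up]
  denom <- sum(s != 0)
  if (denom == 0) return(NA_real_)
  sum(s) / denom
}

#' Baker's Gamma between two dendrograms
#'
#' For every leaf pair the merge level (number of clusters present when
#' the pair first co-clusters) is computed in each tree; Baker's Gamma
#' is the rank correlation between the two level vectors —
#' Goodman-Kruskal gamma by default, Spearman as an option.
#'
#' @param t1,t2 [sample_tree()]s (or `hclust` objects) over identical
#'   leaf sets, n >= 3.
#' @param method `"gamma"` (Goodman-Kruskal, default) or `"spearman"`.
#' @return correlation in `[-1, 1]`.
#' @export
bakers_gamma <- function(t1, t2, method = c("gamma", "spearman")) {
  method <- match.arg(method)
  t1 <- as_sample_tree(t1); t2 <- as_sample_tree(t2)
  labels <- sort(t1$labels)
  if (!setequal(t2$labels, labels)) stop("leaf-set mismatch")
  if (length(labels) < 3) stop("need >= 3 leaves")
  L1 <- merge_level_matrix(t1, labels)
  L2 <- merge_level_matrix(t2, labels)
  up <- upper.tri(L1)
  if (method == "gamma") gk_gamma(L1[up], L2[up])
  else stats::cor(L1[up], L2[up], method = "spearman")
}

as_sample_tree <- function(x) {
  if (inherits(x, "sample_tree")) x
  else if (inherits(x, "hclust")) sample_tree(hclust = x)
  else if (inherits(x, "phylo")) sample_tree(phylo = x)
  else stop("cannot interpret tree of class ", paste(class(x), collapse = "/"))
}

#' Permutation p-value for a tree-association statistic
#'
#' Permutes the leaf labels of `t2` and recomputes the statistic,
#' returning `p = (1 + #(perm >= observed)) / (n_perm + 1)`.
#'
#' @param statistic function of two `sample_tree`s returning a number
#'   (larger = more congruent).
#' @param t1,t2 trees over identical leaf sets.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return list (p, observed, perm — the permuted statistics).
#' @export
permutation_p <- function(statistic, t1, t2, n_perm = 999, seed = 1) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  t1 <- as_sample_tree(t1); t2 <- as_sample_tree(t2)
  obs <- statistic(t1, t2)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) {
      t2p <- t2
      relab <- sample(t2$labels)
      if (!is.null(t2p$hclust))
        t2p$hclust$labels <- relab[match(t2p$hclust$labels, t2$labels)]
      t2p$phylo$tip.label <- relab[match(t2p$phylo$tip.label, t2$labels)]
      t2p$labels <- relab[match(t2p$labels, t2$labels)]
      statistic(t1, t2p)
    }, numeric(1))
    list(p = (1 + sum(perm >= obs)) / (n_perm + 1), observed = obs,
         perm = perm)
  })
}

#' Rooted maximum agreement subtree size
#'
#' The size of the largest leaf subset on which the two rooted trees
#' induce the same topology, by exact dynamic programming over node
#' pairs.  Multifurcations are resolved deterministically before the
#' DP.  Trees above `max_leaves` (default 64, the clade-bitmask limit)
#' are refused.
#'
#' @param t1,t2 trees over identical leaf sets.
#' @param max_leaves refusal cap.
#' @return integer MAST size.
#' @export
mast_size <- function(t1, t2, max_leaves = 64) {
  t1 <- as_sample_tree(t1); t2 <- as_sample_tree(t2)
  labels <- sort(t1$labels)
  if (!setequal(t2$labels, labels)) stop("leaf-set mismatch")
  if (length(labels) > max_leaves)
    stop("trees with more than ", max_leaves, " leaves are not supported; ",
         "subset the leaves or raise max_leaves (hard limit 64)")
  e1 <- encode_tree(t1, labels)
  e2 <- encode_tree(t2, labels)
  mast_size_cpp(e1$left, e1$right, e1$leaf, e2$left, e2$right, e2$leaf)
}

#' Congruence of two sample trees
#'
#' Computes Baker's Gamma with a label-permutation p-value, the rooted
#' MAST size, and the congruence index
#' `I_cong = MAST / mean(MAST over label permutations)` with its
#' permutation p-value.  Congruence is declared at `icong_p < 0.01`.
#'
#' @param t1,t2 trees over identical leaf sets.
#' @param n_perm permutations for both nulls.
#' @param seed integer seed.
#' @return object of class `congruence_result`: bakers_gamma, gamma_p,
#'   mast_size, i_cong, icong_p, congruent, n_permutations, seed,
#'   degenerate (TRUE for n <= 3, where every pair of trees agrees).
#' @export
congruence_index <- function(t1, t2, n_perm = 999, seed = 1) {
  t1 <- as_sample_tree(t1); t2 <- as_sample_tree(t2)
  labels <- sort(t1$labels)
  if (!setequal(t2$labels, labels)) stop("leaf-set mismatch")
  n <- length(labels)
  obs <- mast_size(t1, t2)

  e1 <- encode_tree(t1, labels)
  e2 <- encode_tree(t2, labels)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) sample.int(n) - 1L, integer(n)))
  })
  perm_mast <- mast_perm_cpp(e1$left, e1$right, e1$leaf,
                             e2$left, e2$right, e2$leaf, perms)
  icong <- obs / mean(perm_mast)
  icong_p <- (1 + sum(perm_mast >= obs)) / (n_perm + 1)

  ## Baker's Gamma null from the same permutations, by permuting the
  ## precomputed merge-level matrix of t2
  L1 <- merge_level_matrix(t1, labels)
  L2 <- merge_level_matrix(t2, labels)
  up <- upper.tri(L1)
  bg <- gk_gamma(L1[up], L2[up])
  perm_g <- vapply(seq_len(n_perm), function(i) {
    pr <- perms[i, ] + 1L
    gk_gamma(L1[up], L2[pr, pr][up])
  }, numeric(1))
  gp <- (1 + sum(perm_g >= bg)) / (n_perm + 1)

  structure(list(bakers_gamma = bg, gamma_p = gp, mast_size = obs,
                 i_cong = icong, icong_p = icong_p,
                 congruent = icong_p < 0.01,
                 n_permutations = n_perm, seed = seed,
                 degenerate = n <= 3),
            class = "congruence_result")
}

#' @export
print.congruence_result <- function(x, ...) {
  cat(sprintf(
    "congruence: Baker's Gamma %.3f (p = %.4g); MAST %d, I_cong %.3f (p = %.4g)%s\n",
    x$bakers_gamma, x$gamma_p, x$mast_size, x$i_cong, x$icong_p,
    if (x$degenerate) " [degenerate: n <= 3]" else ""))
  invisible(x)
}
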
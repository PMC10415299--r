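# Shared fixtures: tiny genomes, noiseless profiles, random trees, and
# brute-force oracles kept independent of the implementation paths they
# check.

tiny_genome <- function(autosome_bins = 40, x_bins = 20) {
  default_genome(n_autosomes = 2, autosome_bins = autosome_bins,
                 x_bins = x_bins)
}

# profile with given per-bin ratios (already "normalized")
ratio_profile <- function(ratios, grid, sample_id = "S1") {
  p <- binned_profile(sample_id, grid, count = rep(1, grid$n_bins))
  p$ratio <- ratios
  p
}

# noiseless expected-ratio profiles for every sample of a clone tree
noiseless_profiles <- function(tree) {
  grid <- tree$genome$grid
  cn <- tumor_cn_matrix(tree)
  c_n <- normal_copy(grid)
  out <- lapply(seq_len(nrow(tree$samples)), function(si) {
    rho <- tree$samples$purity[si]
    D <- rho * tree$samples$ploidy[si] + 2 * (1 - rho)
    r <- (rho * cn[, si] + c_n * (1 - rho)) / D
    ratio_profile(r, grid, tree$samples$sample_id[si])
  })
  names(out) <- tree$samples$sample_id
  out
}

random_sample_tree <- function(n, seed) {
  set.seed(seed)
  hc <- stats::hclust(stats::dist(matrix(stats::rnorm(n * 4), n)))
  hc$labels <- paste0("s", seq_len(n))
  sample_tree(hclust = hc)
}

shuffled_labels_tree <- function(tree, seed) {
  set.seed(seed)
  hc <- tree$hclust
  hc$labels <- sample(hc$labels)
  sample_tree(hclust = hc)
}

# ---- brute-force MAST oracle (independent of the DP) -----------------
# clades of a tree as leaf bitmasks over `labels`
tree_clade_masks <- function(tree, labels) {
  e <- scratchcn:::encode_tree(tree, labels)
  m <- length(e$left)
  mask <- integer(m)
  for (i in seq_len(m)) {
    mask[i] <- if (e$left[i] < 0) bitwShiftL(1L, e$leaf[i])
    else bitwOr(mask[e$left[i] + 1L], mask[e$right[i] + 1L])
  }
  mask
}

# two rooted trees agree on leaf subset S iff their clade families
# restricted to S coincide (as laminar set families)
agrees_on_subset <- function(masks1, masks2, s) {
  r1 <- unique(bitwAnd(masks1, s)); r1 <- sort(r1[r1 != 0L])
  r2 <- unique(bitwAnd(masks2, s)); r2 <- sort(r2[r2 != 0L])
  identical(r1, r2)
}

mast_brute <- function(t1, t2) {
  labels <- sort(t1$labels)
  n <- length(labels)
  m1 <- tree_clade_masks(t1, labels)
  m2 <- tree_clade_masks(t2, labels)
  best <- 0L
  for (s in seq_len(2^n - 1)) {
    size <- sum(bitwAnd(s, bitwShiftL(1L, 0:(n - 1))) != 0L)
    if (size > best && agrees_on_subset(m1, m2, s)) best <- size
  }
  best
}

# segment a tree's noiseless profiles and call absolute CN with truth
truth_called_segments <- function(tree, profiles = noiseless_profiles(tree),
                                  merge_tol = 0.05) {
  out <- lapply(names(profiles), function(sid) {
    i <- match(sid, tree$samples$sample_id)
    seg <- segment_profile(profiles[[sid]], merge_tol = merge_tol,
                           smooth_outliers = FALSE)
    call_absolute_cn(seg, tree$samples$purity[i], tree$samples$ploidy[i])
  })
  names(out) <- names(profiles)
  out
}
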
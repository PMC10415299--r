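test_that("single-clone degenerate tree gives identical samples", {
  tree <- simulate_clone_tree(n_clusters = 1, samples_per_cluster = 3,
                              n_truncal = 5, n_cluster = 0, n_private = 0,
                              seed = 1, genome = tiny_genome())
  cn <- tumor_cn_matrix(tree)
  expect_equal(ncol(cn), 3)
  expect_true(all(cn[, 1] == cn[, 2]) && all(cn[, 1] == cn[, 3]))
})

test_that("cluster bookkeeping and purity draws respect the request", {
  tree <- simulate_clone_tree(n_clusters = 3, samples_per_cluster = 4, seed = 2)
  expect_equal(nrow(tree$samples), 12)
  expect_equal(as.vector(table(tree$samples$cluster)), rep(4L, 3))
  expect_true(all(tree$samples$purity >= 0.2 & tree$samples$purity <= 0.9))
  expect_error(simulate_clone_tree(purity_range = c(0, 1.2)), "purity_range")
  expect_error(simulate_clone_tree(n_truncal = -1), "counts")
})

test_that("every simulator is byte-identical under the same seed", {
  g <- tiny_genome()
  sim <- function(seed) simulate_clone_tree(
    seed = seed, genome = g, n_truncal = 3, n_cluster = 3, n_private = 1,
    n_cluster_x = 1, anchor_len = 12, event_len_range = c(3, 8))
  t1 <- sim(5)
  t2 <- sim(5)
  expect_identical(t1, t2)
  expect_identical(simulate_binned_counts(t1, seed = 3),
                   simulate_binned_counts(t2, seed = 3))
  expect_identical(simulate_phased_snps(t1, seed = 3),
                   simulate_phased_snps(t2, seed = 3))
  expect_identical(simulate_clonal_mutations(t1, seed = 3),
                   simulate_clonal_mutations(t2, seed = 3))
  expect_identical(simulate_expression(t1, seed = 3),
                   simulate_expression(t2, seed = 3))
  ## and a different seed changes the draw
  expect_false(identical(simulate_binned_counts(t1, seed = 3),
                         simulate_binned_counts(t1, seed = 4)))
})

test_that("event nesting: truncal everywhere, cluster events only in their cluster", {
  tree <- simulate_clone_tree(seed = 3)
  cn <- tumor_cn_matrix(tree)
  grid <- tree$genome$grid
  ev <- tree$events
  covered <- function(classes) {
    hit <- logical(grid$n_bins)
    for (i in which(ev$class %in% classes)) {
      r0 <- min(chrom_bin_rows(grid, ev$chrom[i]))
      hit[r0 + seq.int(ev$start_bin[i], ev$end_bin[i] - 1L)] <- TRUE
    }
    hit
  }
  ## bins touched only by truncal content are identical across all samples
  truncal_only <- !covered(c("cluster", "private"))
  expect_true(all(apply(cn[truncal_only, , drop = FALSE], 1,
                        function(z) length(unique(z)) == 1)))
  ## away from private events, samples of one cluster are identical
  no_private <- !covered("private")
  for (cl in tree$clusters) {
    cols <- tree$samples$cluster == cl
    expect_true(all(apply(cn[no_private, cols, drop = FALSE], 1,
                          function(z) length(unique(z)) == 1)))
  }
  ## and cluster events do separate the clusters somewhere
  expect_gt(sum(apply(cn[, , drop = FALSE], 1,
                      function(z) length(unique(z)) > 1)), 0)
  expect_true(all(cn >= 0))
})

test_that("binned counts match the closed-form expected ratio", {
  ## one sample, one truncal gain over many bins: iid draws per (rho, c_t)
  g <- default_genome(n_autosomes = 2, autosome_bins = 150, x_bins = 20)
  for (rho in c(0.3, 0.5, 0.9)) {
    tree <- simulate_clone_tree(n_clusters = 1, samples_per_cluster = 1,
                                n_truncal = 0, n_cluster = 0, n_private = 0,
                                n_anchors = 0, n_cluster_x = 0,
                                purities = rho, seed = 1, genome = g,
                                ar_classes = "none")
    tree$events <- rbind(tree$events, data.frame(
      chrom = "chr1", start_bin = 10L, end_bin = 110L, delta = 1L,
      allele = "A", class = "truncal", owner = "truncal"))
    cn <- tumor_cn_matrix(tree)
    auto <- !is_chrx(g$grid$bins$chrom)
    tree$samples$ploidy <- mean(cn[auto, 1])
    prof <- simulate_binned_counts(tree, depth_per_bin = 100,
                                   dispersion = 100, seed = 7)[[1]]
    for (ct in c(2, 3)) {
      idx <- which(cn[, 1] == ct & auto)
      mu_exp <- 100 * prof$true_ratio[idx[1]]
      counts <- prof$count[idx]
      se <- sqrt((mu_exp + mu_exp^2 / 100) / length(idx))
      expect_lt(abs(mean(counts) - mu_exp), 3 * se)
    }
    ## Poisson limit: dispersion = Inf still valid draws around the mean
    p2 <- simulate_binned_counts(tree, depth_per_bin = 10000,
                                 dispersion = Inf, seed = 8)[[1]]
    idx <- which(cn[, 1] == 2 & auto)[1:50]
    expect_lt(abs(mean(p2$count[idx]) - 10000 * p2$true_ratio[idx[1]]),
              3 * sqrt(10000 / 50))
  }
})

test_that("phased SNPs follow the allele-specific BAF and switch process", {
  g <- tiny_genome(autosome_bins = 60)
  tree <- simulate_clone_tree(n_clusters = 1, samples_per_cluster = 2,
                              purities = c(0.5, 1), seed = 2, genome = g,
                              anchor_len = 20, n_cluster_x = 0,
                              ar_classes = "none")
  ## no switches, full purity, LOH (1,0): reported hap-A BAF is 1
  snps <- simulate_phased_snps(tree, snp_density = 50, depth = 50,
                               switch_rate = 0, seed = 3)
  expect_true(all(!snps$snps$flipped))
  s2 <- snps$counts[snps$counts$sample_id == tree$samples$sample_id[2], ]
  expect_equal(sum(s2$a_count), sum(s2$depth))
  ## rho = 0.5, deep coverage: hap-A BAF -> 2/3
  s1 <- snps$counts[snps$counts$sample_id == tree$samples$sample_id[1], ]
  expect_lt(abs(sum(s1$a_count) / sum(s1$depth) - 2 / 3), 0.01)
  ## switch process: ~ rate * n flips of orientation state
  sw <- simulate_phased_snps(tree, snp_density = 120, depth = 10,
                             switch_rate = 0.1, seed = 4)
  n <- nrow(sw$snps)
  n_switch_events <- sum(abs(diff(as.integer(sw$snps$flipped))) != 0) +
    sum(sw$snps$flipped[1])
  expect_lt(abs(n_switch_events - 0.1 * n), 4 * sqrt(n * 0.1 * 0.9))
  expect_error(simulate_phased_snps(tree, switch_rate = 0.6), "switch_rate")
})

test_that("clonal mutation sets are nested by the clone tree", {
  tree <- simulate_clone_tree(seed = 4)
  sets <- simulate_clonal_mutations(tree, 30, 20, 0, seed = 1)
  cl <- tree$samples$cluster
  same <- which(cl == cl[1]); diff_cl <- which(cl != cl[1])
  expect_identical(sort(sets[[same[1]]]), sort(sets[[same[2]]]))
  truncal <- grep("^mt_truncal", sets[[1]], value = TRUE)
  expect_length(truncal, 30)
  expect_identical(sort(intersect(sets[[1]], sets[[diff_cl[1]]])),
                   sort(truncal))
  ## with private mutations, same-cluster overlap dominates cross-cluster
  sets <- simulate_clonal_mutations(tree, seed = 2)
  ov <- pairwise_clonal_overlap(sets, stats::setNames(cl, names(sets)))
  p <- overlap_by_cluster_test(ov$overlap, ov$same_cluster)
  expect_lt(p, 0.05)
})

test_that("expression shifts follow AR copy number", {
  tree <- simulate_clone_tree(seed = 6)   # focal/none/broad AR classes
  sig <- read_ar_signature()
  ## no effect: scores should not separate by AR class
  e0 <- simulate_expression(tree, sig, effect_size = 0, noise_sd = 0.1,
                            seed = 1)
  expect_true(all(e0$counts >= 0))
  ## strong effect, little noise: up-genes high where AR is gained
  e1 <- simulate_expression(tree, sig, effect_size = 2, noise_sd = 0.05,
                            seed = 1)
  z <- zscore_by_gene(log2(e1$counts[sig$gene[sig$direction == "up"], ] + 1))
  gained <- e1$ar_cn > 1
  expect_true(all(colMeans(z[, gained]) > colMeans(z[, !gained])))
})
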
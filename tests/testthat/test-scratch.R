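g <- tiny_genome()

seg_from_cn <- function(cn_blocks, grid = g$grid, sample_id = "S1") {
  ## cn_blocks: per-bin CN vector; build a called segment_profile
  seg <- segment_profile(ratio_profile(cn_blocks / 2, grid, sample_id),
                         merge_tol = 0.01, smooth_outliers = FALSE)
  call_absolute_cn(seg, rho = 1, psi_t = 2)
}

test_that("transition points sit at adjacent-segment CN changes", {
  cn <- rep(2, g$grid$n_bins)
  cn[21:40] <- 3                      # second half of chr1
  seg <- seg_from_cn(cn)
  tp <- extract_transition_points(seg)
  expect_equal(nrow(tp), 1)
  expect_equal(tp$pos, 20 * g$grid$bin_width)
  expect_equal(c(tp$left_cn, tp$right_cn, tp$direction), c(2, 3, 1))
  ## flat chromosome contributes none; chromosome ends are not TPs
  expect_equal(nrow(extract_transition_points(seg_from_cn(rep(2, g$grid$n_bins)))), 0)
})

test_that("extractor agrees with a brute-force adjacent diff oracle", {
  set.seed(21)
  for (i in 1:50) {
    cn <- unlist(lapply(g$grid$chrom_bins, function(nb)
      rep(sample(1:4, 6, replace = TRUE), each = ceiling(nb / 6))[seq_len(nb)]))
    seg <- seg_from_cn(unname(cn))
    tp <- extract_transition_points(seg, chrom_subset = g$grid$chroms)
    ## oracle: diff of per-bin values within each chromosome
    expected <- do.call(rbind, lapply(g$grid$chroms, function(ch) {
      rows <- which(g$grid$bins$chrom == ch)
      v <- cn[rows]
      j <- which(diff(v) != 0)
      if (!length(j)) return(NULL)
      data.frame(chrom = ch, pos = j * g$grid$bin_width)
    }))
    if (is.null(expected)) expect_equal(nrow(tp), 0)
    else {
      expect_equal(tp$chrom, expected$chrom)
      expect_equal(tp$pos, expected$pos)
    }
    ## k segments on a chromosome yield k - 1 transition points
    for (ch in g$grid$chroms) {
      k <- sum(seg$segments$chrom == ch)
      expect_equal(sum(tp$chrom == ch), k - 1)
    }
  }
})

test_that("transition matrix entries are covering-segment values", {
  cn1 <- rep(2, g$grid$n_bins); cn1[11:40] <- 3
  cn2 <- rep(2, g$grid$n_bins)            # flat: no own boundary
  profs <- list(A = seg_from_cn(cn1, sample_id = "A"),
                B = seg_from_cn(cn2, sample_id = "B"))
  tm <- build_transition_matrix(profs, chrom_subset = "autosomes")
  expect_equal(ncol(tm$values), 1)
  expect_equal(unname(tm$values["A", 1]), 3)   # right of the boundary
  expect_equal(unname(tm$values["B", 1]), 2)   # covering segment, no boundary
  ## identical profiles give identical rows
  tm2 <- build_transition_matrix(list(A = profs$A, C = profs$A))
  expect_equal(unname(tm2$values["A", ]), unname(tm2$values["C", ]))
  ## grid mismatch is refused
  other <- seg_from_cn(rep(2, tiny_genome(41)$grid$n_bins),
                       grid = tiny_genome(41)$grid)
  expect_error(build_transition_matrix(list(A = profs$A, D = other)), "grid")
})

test_that("noiseless transition matrix reproduces planted event boundaries", {
  tree <- simulate_clone_tree(seed = 12, genome = tiny_genome(200, 60),
                              n_truncal = 4, n_cluster = 4, n_private = 1)
  segs <- truth_called_segments(tree, merge_tol = 0.01)
  tm <- build_transition_matrix(segs, "autosomes")
  ev <- tree$events[!is_chrx(tree$events$chrom), ]
  planted <- unique(data.frame(
    chrom = rep(ev$chrom, 2),
    pos = c(ev$start_bin, ev$end_bin) * tree$genome$grid$bin_width))
  ## drop planted boundaries at chromosome ends (not transition points)
  nb <- tree$genome$grid$chrom_bins[planted$chrom] * tree$genome$grid$bin_width
  planted <- planted[planted$pos > 0 & planted$pos < nb, ]
  expect_setequal(paste0(tm$boundaries$chrom, ":", tm$boundaries$pos),
                  paste0(planted$chrom, ":", planted$pos))
})

test_that("correlation distance honors its invariances", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8) + 1, c = c(4, 3, 2, 1))
  d <- correlation_distance(m)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(unname(d["a", "b"]), 0)       # positive affine image
  expect_equal(unname(d["a", "c"]), 2)       # anti-correlated
  expect_true(isSymmetric(d))
  m0 <- rbind(a = c(1, 2, 3), b = c(1, 1, 1))
  expect_warning(d0 <- correlation_distance(m0), "zero-variance")
  expect_equal(unname(d0["a", "b"]), 2)
})

test_that("scratch clustering recovers well-separated clusters and merges singletons", {
  set.seed(5)
  centers <- matrix(rnorm(3 * 30, sd = 4), nrow = 3)
  m <- centers[rep(1:3, each = 4), ] + matrix(rnorm(12 * 30, sd = 0.2), 12)
  rownames(m) <- paste0("s", 1:12)
  st <- scratch_cluster(correlation_distance(m))
  expect_equal(st$k, 3)
  expect_equal(adjusted_rand_index(st$clusters, rep(1:3, each = 4)), 1)
  ## an outlier singleton is merged into its sister clade
  m2 <- rbind(m[1:8, ], outlier = rnorm(30, sd = 4))
  st2 <- scratch_cluster(correlation_distance(m2))
  expect_true(all(table(st2$clusters) >= 2))
  ## order invariance
  for (i in 1:5) {
    perm <- sample(nrow(m))
    stp <- scratch_cluster(correlation_distance(m[perm, ]))
    expect_equal(stp$k, st$k)
    expect_equal(adjusted_rand_index(stp$clusters[rownames(m)],
                                     st$clusters[rownames(m)]), 1)
  }
  expect_warning(st3 <- scratch_cluster(matrix(0, 2, 2,
                                               dimnames = list(c("a", "b"),
                                                               c("a", "b")))),
                 "3 samples")
  expect_equal(st3$k, 1L)
})

test_that("shared transition fractions and the categorical bins", {
  cnA <- rep(2, g$grid$n_bins); cnA[11:20] <- 3; cnA[51:60] <- 1
  cnB <- cnA                                  # superset sharer
  cnC <- rep(2, g$grid$n_bins); cnC[25:30] <- 3
  profs <- list(A = seg_from_cn(cnA, sample_id = "A"),
                B = seg_from_cn(cnB, sample_id = "B"),
                C = seg_from_cn(cnC, sample_id = "C"))
  expect_equal(shared_transition_fraction(profs$A, profs["B"]), 1)
  expect_equal(shared_transition_fraction(profs$A, profs["C"]), 0)
  expect_equal(shared_transition_fraction(profs$A, profs[c("B", "C")],
                                          mode = "all"), 0)
  expect_equal(shared_transition_fraction(profs$A, profs[c("B", "C")],
                                          mode = "any"), 1)
  ## detection against a growing target set is monotone non-decreasing
  tree <- simulate_clone_tree(seed = 13, genome = tiny_genome(200, 60))
  segs <- truth_called_segments(tree, merge_tol = 0.01)
  fr <- vapply(seq_len(11), function(k)
    shared_transition_fraction(segs[[12]], segs[seq_len(k)], mode = "any"),
    numeric(1))
  expect_true(all(diff(fr) >= 0))
  ## categorical binning of pairwise fractions
  pm <- pairwise_shared_matrix(profs)
  expect_equal(unname(pm$category["A", "B"]), ">80%")
  expect_equal(unname(pm$category["A", "C"]), "<20%")
  expect_equal(unname(cut(c(0.5, 0.19), breaks = c(-Inf, 0.2, 0.8, Inf),
                          labels = c("<20%", "20-80%", ">80%"), right = FALSE)),
               factor(c("20-80%", "<20%"), levels = c("<20%", "20-80%", ">80%")))
})
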
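test_that("haplotype-BAF inversion matches the allele-specific model", {
  loh <- data.frame(anchor_id = "a1", chrom = "chr1", start = 0, end = 1e7,
                    n_A = 1L, n_B = 0L)
  fake_table <- function(B, depth = 1e6) {
    list(snps = data.frame(snp_id = "s1", chrom = "chr1", pos = 5e6,
                           anchor_id = "a1"),
         counts = data.frame(sample_id = "S", snp_id = "s1",
                             a_count = round(B * depth), depth = depth))
  }
  expect_equal(purity_from_haplotype_baf(fake_table(2 / 3), loh,
                                         min_snps = 1), 0.5,
               tolerance = 1e-5)
  expect_equal(purity_from_haplotype_baf(fake_table(1), loh, min_snps = 1), 1)
  expect_equal(purity_from_haplotype_baf(fake_table(0.5), loh, min_snps = 1), 0)
  ## monotone in B for an LOH anchor
  rhos <- vapply(seq(0.55, 0.95, by = 0.1), function(B)
    purity_from_haplotype_baf(fake_table(B), loh, min_snps = 1), numeric(1))
  expect_true(all(diff(rhos) > 0))
  ## (2,1) anchor: B = (2 rho + (1-rho)) / (3 rho + 2 (1-rho))
  anchor21 <- within(loh, {n_A <- 2L; n_B <- 1L})
  rho <- 0.37
  B <- (2 * rho + (1 - rho)) / (3 * rho + 2 * (1 - rho))
  expect_equal(purity_from_haplotype_baf(fake_table(B), anchor21,
                                         min_snps = 1), rho,
               tolerance = 1e-5)
})

test_that("switch-error correction relabels against the high-purity sample", {
  g <- tiny_genome(60)
  tree <- simulate_clone_tree(n_clusters = 1, samples_per_cluster = 2,
                              purities = c(0.5, 0.95), seed = 3, genome = g,
                              anchor_len = 20, n_cluster_x = 0,
                              ar_classes = "none")
  ref <- tree$samples$sample_id[2]
  ## no planted switches: correction changes nothing
  sn0 <- simulate_phased_snps(tree, depth = 60, switch_rate = 0, seed = 1)
  cor0 <- correct_switch_errors(sn0, ref)
  expect_equal(cor0$counts$a_count,
               sn0$counts$a_count[sn0$counts$snp_id %in% cor0$snps$snp_id])
  ## 10% switch rate at deep coverage: nearly all SNPs relabeled correctly
  sn <- simulate_phased_snps(tree, depth = 60, switch_rate = 0.1, seed = 2)
  corrected <- correct_switch_errors(sn, ref)
  cc <- merge(corrected$counts[corrected$counts$sample_id == ref, ],
              sn$counts[sn$counts$sample_id == ref, ],
              by = "snp_id", suffixes = c("_cor", "_rep"))
  cc <- merge(cc, sn$snps, by = "snp_id")
  ## after correction the count must equal the true-haplotype count
  true_count <- ifelse(cc$flipped, cc$depth_rep - cc$a_count_rep,
                       cc$a_count_rep)
  expect_gte(mean(cc$a_count_cor == true_count), 0.99)
  ## an all-flipped table is fully corrected (symmetry)
  sn_flip <- sn0
  sn_flip$counts$a_count <- sn_flip$counts$depth - sn_flip$counts$a_count
  cor_flip <- correct_switch_errors(sn_flip, ref)
  keep <- sn0$counts$snp_id %in% cor_flip$snps$snp_id
  expect_equal(cor_flip$counts$a_count, sn0$counts$a_count[keep])
})

test_that("anchor selection recovers planted LOH arms and rejects balanced regions", {
  g <- tiny_genome(200, 20)
  tree <- simulate_clone_tree(n_clusters = 1, samples_per_cluster = 1,
                              n_truncal = 0, n_cluster = 0, n_private = 0,
                              purities = 0.9, seed = 4, genome = g,
                              anchor_len = 24, n_cluster_x = 0,
                              ar_classes = "none")
  profs <- noiseless_profiles(tree)
  seg <- truth_called_segments(tree, profs, merge_tol = 0.01)[[1]]
  snps <- simulate_phased_snps(tree, depth = 80, switch_rate = 0, seed = 5)
  sid <- tree$samples$sample_id[1]
  anchors <- suppressWarnings(
    select_anchor_regions(seg, snps, sid, min_length_bp = 8e6, min_snps = 10))
  expect_gte(nrow(anchors), length(unique(tree$anchors$anchor_id)))
  got <- anchors[order(anchors$chrom, anchors$start), ]
  planted <- tree$anchors[order(tree$anchors$chrom, tree$anchors$start), ]
  hit <- mapply(function(ch, s, e) any(planted$chrom == ch &
                                         planted$start <= s &
                                         planted$end >= e),
                got$chrom, got$start, got$end)
  expect_true(all(got$n_A[hit] == 1 & got$n_B[hit] == 0))
})

test_that("grid fit recovers purity and ploidy from clean profiles", {
  g <- tiny_genome(100, 30)
  ## piecewise profile with integer CN {1,2,3,4} at known (rho, psi = 2)
  mk_ratios <- function(rho) {
    D <- rho * 2 + 2 * (1 - rho)
    cns <- rep(c(2, 3, 1, 2, 4, 2), length.out = 23)
    blocks <- rep(cns, each = 10)[seq_len(g$grid$n_bins)]
    c_n <- normal_copy(g$grid)
    (rho * blocks + c_n * (1 - rho)) / D
  }
  seg06 <- segment_profile(ratio_profile(mk_ratios(0.6), g$grid),
                           merge_tol = 0.01)
  fit1 <- grid_fit_purity_ploidy(seg06)
  expect_equal(fit1$rho, 0.6)
  expect_equal(fit1$psi, 2)
  expect_equal(fit1$score, 0)
  ## integer profile at rho = 1: exact recovery with score 0
  fit2 <- grid_fit_purity_ploidy(
    segment_profile(ratio_profile(mk_ratios(1), g$grid), merge_tol = 0.01))
  expect_equal(fit2$rho, 1)
  expect_equal(fit2$score, 0)
  expect_false(fit2$degenerate)
  ## flat profile: degeneracy flag
  flat <- segment_profile(ratio_profile(rep(1, g$grid$n_bins), g$grid),
                          merge_tol = 0.1)
  expect_error(grid_fit_purity_ploidy(flat), "segments")
  flat5 <- flat
  flat5$segments <- do.call(rbind, replicate(5, flat$segments[1, ],
                                             simplify = FALSE))
  expect_true(grid_fit_purity_ploidy(flat5)$degenerate)
})

test_that("consensus follows the concordance rule", {
  expect_equal(consensus_purity(0.50, 0.52)$rho, 0.51)
  expect_false(consensus_purity(0.50, 0.52)$discordant)
  disc <- consensus_purity(0.50, 0.80)
  expect_equal(disc$rho, 0.50)
  expect_true(disc$discordant)
  expect_equal(consensus_purity(NA, 0.7)$rho, 0.7)
  expect_equal(consensus_purity(0.3, NA)$rho, 0.3)
  expect_error(consensus_purity(NA, NA), "valid")
})

test_that("cohort purity estimation stays within 0.05 of planted truth", {
  rhos <- c(0.25, 0.45, 0.65, 0.85)
  tree <- simulate_clone_tree(n_clusters = 1, samples_per_cluster = 5,
                              purities = c(rhos, 0.9), seed = 6)
  binned <- lapply(simulate_binned_counts(tree, seed = 7), normalize_counts)
  segs <- lapply(binned, segment_profile)
  snps <- simulate_phased_snps(tree, depth = 30, switch_rate = 0.05, seed = 8)
  est <- suppressWarnings(
    estimate_purity(segs, snps, tree$anchors, tree$samples$sample_id[5]))
  err <- abs(est$rho_consensus[1:4] - rhos)
  expect_lte(median(err), 0.05)
  expect_true(all(est$n_anchors_used >= 3))
})
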
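## File formats and the end-to-end pipeline driver.

#' Write segment profiles to a SEG-like TSV
#'
#' Columns: sample, chrom, start, end, value (mean ratio) and, when
#' absolute CN has been called, cn.
#'
#' @param profiles named list of `segment_profile`s.
#' @param path output path.
#' @export
write_seg <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    s <- p$segments
    out <- data.frame(sample = p$sample_id, chrom = s$chrom,
                      start = s$start, end = s$end, value = s$ratio,
                      stringsAsFactors = FALSE)
    if (!is.null(s$cn)) out$cn <- s$cn
    out
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read segment profiles from a SEG-like TSV
#'
#' Rows are validated against the grid (coordinates must be bin edges)
#' and sorted deterministically; malformed rows are reported with line
#' numbers.
#'
#' @param path TSV with header sample, chrom, start, end, value.
#' @param grid the [bin_grid()] the segments live on.
#' @return named list of `segment_profile`s.
#' @export
read_seg <- function(path, grid) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty SEG file: ", path)
  need <- c("sample", "chrom", "start", "end", "value")
  if (!all(need %in% names(df)))
    stop("SEG file must have columns ", paste(need, collapse = ", "))
  bad <- which(!(df$chrom %in% grid$chroms) |
                 df$start %% grid$bin_width != 0 |
                 df$end %% grid$bin_width != 0 | df$end <= df$start)
  if (length(bad))
    stop("malformed SEG rows (1-based, excluding header): ",
         paste(utils::head(bad, 5), collapse = ", "))
  df <- df[order(df$sample, match(df$chrom, grid$chroms), df$start), ]
  lapply(split(df, df$sample), function(s) {
    seg <- data.frame(chrom = s$chrom,
                      start_bin = as.integer(s$start / grid$bin_width),
                      end_bin = as.integer(s$end / grid$bin_width),
                      start = s$start, end = s$end,
                      n_bins = as.integer((s$end - s$start) / grid$bin_width),
                      ratio = s$value, stringsAsFactors = FALSE)
    if (!is.null(s$cn)) seg$cn <- s$cn
    structure(list(sample_id = s$sample[1], grid = grid, segments = seg,
                   purity = NA_real_, ploidy = NA_real_),
              class = "segment_profile")
  })
}

#' Write a sample tree as newick
#'
#' @param tree a [sample_tree()].
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(as_sample_tree(tree)$phylo, file = path)
  invisible(path)
}

#' Read a newick file as a sample tree
#'
#' @param path newick file.
#' @return a [sample_tree()].
#' @export
read_newick <- function(path) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse newick file: ", path)
  sample_tree(phylo = phy)
}

## small FNV-1a hash so runs can stamp their configuration
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE,
                                      digits = NA, force = TRUE))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Default pipeline configuration
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param ... overrides of any default field.
#' @return named list.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_clusters = 3, samples_per_cluster = 4,
    n_truncal = 10, n_cluster = 15, n_private = 3,
    purity_range = c(0.2, 0.9),
    depth_per_bin = 100, dispersion = 100,
    snp_density = 25, snp_depth = 30, switch_rate = 0.05,
    merge_tol = 0.3, min_tf = 0.2,
    linkage = "complete", k_max = 8, cor_method = "pearson",
    n_perm = 999,
    effect_size = 1, noise_sd = 0.3
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full analysis pipeline on a simulated patient
#'
#' Simulates a patient under `config`, then runs the entire analysis:
#' normalization, segmentation, purity estimation (haplotype-BAF +
#' grid fit consensus), tumor-fraction filtering, absolute copy number,
#' autosomal and chrX SCRATCH networks, their congruence, AR copy
#' number/gain and AR activity score, and clonal-mutation overlap
#' statistics.  All artifacts are written under `outdir` together with
#' a machine-readable summary stamped with the configuration hash.
#' Identical config and seed give an identical summary.
#'
#' @param config list from [default_config()], or a YAML file path.
#' @param outdir output directory (created if needed); NULL for none.
#' @return the summary list, invisibly when writing files.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  seed <- cfg$seed
  genome <- default_genome()

  tree <- simulate_clone_tree(
    n_clusters = cfg$n_clusters, samples_per_cluster = cfg$samples_per_cluster,
    n_truncal = cfg$n_truncal, n_cluster = cfg$n_cluster,
    n_private = cfg$n_private, purity_range = cfg$purity_range,
    seed = seed, genome = genome)
  binned <- simulate_binned_counts(tree, depth_per_bin = cfg$depth_per_bin,
                                   dispersion = cfg$dispersion,
                                   seed = seed + 1)
  snps <- simulate_phased_snps(tree, snp_density = cfg$snp_density,
                               depth = cfg$snp_depth,
                               switch_rate = cfg$switch_rate, seed = seed + 2)
  muts <- simulate_clonal_mutations(tree, seed = seed + 3)
  expr <- simulate_expression(tree, effect_size = cfg$effect_size,
                              noise_sd = cfg$noise_sd, seed = seed + 4)

  binned <- lapply(binned, normalize_counts)
  segs <- lapply(binned, segment_profile, merge_tol = cfg$merge_tol)

  ## purity: haplotype reference = sample with highest grid-fit purity
  grid_rho <- vapply(segs, function(s)
    tryCatch(grid_fit_purity_ploidy(s)$rho, error = function(e) NA_real_),
    numeric(1))
  ref_sample <- names(segs)[which.max(grid_rho)]
  purity <- estimate_purity(segs, snps, tree$anchors, ref_sample)

  keep <- filter_by_tumor_fraction(
    data.frame(sample_id = purity$sample_id, purity = purity$rho_consensus,
               stringsAsFactors = FALSE), min_tf = cfg$min_tf)$sample_id
  segs_cn <- lapply(keep, function(sid) {
    i <- match(sid, purity$sample_id)
    call_absolute_cn(segs[[sid]], purity$rho_consensus[i], purity$psi_grid[i])
  })
  names(segs_cn) <- keep

  tm_auto <- build_transition_matrix(segs_cn, "autosomes", binned[keep])
  tree_auto <- scratch_cluster(
    correlation_distance(tm_auto, cfg$cor_method),
    linkage = cfg$linkage, k_max = cfg$k_max)
  tm_x <- build_transition_matrix(segs_cn, "chrX", binned[keep])
  tree_x <- scratch_cluster(
    correlation_distance(tm_x, cfg$cor_method),
    linkage = cfg$linkage, k_max = cfg$k_max)
  cong <- congruence_index(tree_auto, tree_x, n_perm = cfg$n_perm,
                           seed = seed + 5)

  ## AR status and activity
  ar <- data.frame(
    sample_id = keep,
    ar_cn = vapply(segs_cn, ar_copy_number, numeric(1),
                   ar_interval = genome$ar_interval),
    xq_gained = vapply(segs_cn, xq_gained_fraction, numeric(1),
                       genome = genome),
    stringsAsFactors = FALSE)
  ar$gain <- mapply(classify_ar_gain, ar$ar_cn, ar$xq_gained)
  norm_expr <- filter_and_normalize(expr$counts)
  scores <- ar_score(zscore_by_gene(norm_expr), read_ar_signature())

  ov <- pairwise_clonal_overlap(muts[keep], tree_auto$clusters[keep])
  ov_p <- if (length(unique(ov$same_cluster)) == 2)
    overlap_by_cluster_test(ov$overlap, ov$same_cluster) else NA_real_

  truth_cl <- stats::setNames(tree$samples$cluster, tree$samples$sample_id)
  summary <- list(
    config_hash = config_hash(cfg),
    seed = seed,
    n_samples = nrow(tree$samples),
    n_retained = length(keep),
    purity_mae = mean(abs(purity$rho_consensus -
                            tree$samples$purity[match(purity$sample_id,
                                                      tree$samples$sample_id)])),
    k_autosome = tree_auto$k,
    silhouette = tree_auto$silhouette,
    ari_vs_truth = adjusted_rand_index(tree_auto$clusters[keep],
                                       truth_cl[keep]),
    bakers_gamma = cong$bakers_gamma,
    icong = cong$i_cong,
    icong_p = cong$icong_p,
    ar_gain_fraction = mean(ar$gain),
    overlap_wilcoxon_p = ov_p
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_seg(segs_cn, file.path(outdir, "segments.tsv"))
    utils::write.table(purity, file.path(outdir, "purity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ar, file.path(outdir, "ar_status.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = names(tree_auto$clusters),
                 cluster = tree_auto$clusters),
      file.path(outdir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_newick(tree_auto, file.path(outdir, "tree_autosome.nwk"))
    write_newick(tree_x, file.path(outdir, "tree_chrX.nwk"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(summary))
  }
  summary
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b cluster assignments over the same elements.
#' @return ARI in `[-1, 1]` (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
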
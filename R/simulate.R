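## Clone-tree simulator: plants a fully specified multi-metastasis
## "patient" (clone tree, copy-number events, purities, phased SNPs,
## clonal mutation sets, AR-response expression) so every downstream
## stage can be validated against known truth.

## evaluate expr under a temporary RNG state so simulators are
## deterministic given `seed` without clobbering the caller's stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

empty_events <- function() {
  data.frame(chrom = character(), start_bin = integer(), end_bin = integer(),
             delta = integer(), allele = character(), class = character(),
             owner = character(), stringsAsFactors = FALSE)
}

#' Simulate a planted clone tree for one patient
#'
#' Generates a patient with `n_clusters` dominant clones, each sampled
#' by `samples_per_cluster` metastases.  Copy-number events are planted
#' at three levels: truncal (all samples), cluster-specific (exactly the
#' samples of one cluster) and private (one sample).  Event boundaries
#' are rejection-sampled so that no two events share a boundary bin,
#' keeping the planted transition points unambiguous.  Truncal LOH
#' "anchor" events (single-copy loss of the B allele over a long
#' autosomal stretch) are planted for purity estimation, and each
#' cluster receives a chrX AR-locus class (`none`, `broad` Xq gain, or
#' `focal` high-level AR amplification) plus cluster-specific chrX
#' events, so chromosome-X architecture tracks the autosomal clusters.
#'
#' @param n_clusters number of clusters (dominant clones), >= 1.
#' @param samples_per_cluster samples per cluster, >= 1.
#' @param n_truncal,n_cluster,n_private autosomal event counts: truncal
#'   total, cluster-specific per cluster, private per sample.
#' @param purity_range interval from which per-sample tumor fractions
#'   are drawn uniformly; default `c(0.2, 0.9)`.
#' @param seed integer seed; same seed gives an identical object.
#' @param genome genome model from [default_genome()].
#' @param n_anchors truncal LOH anchor events (>= 0).
#' @param anchor_len anchor length in bins (default 24 = 12 Mb).
#' @param n_cluster_x cluster-specific chrX events per cluster.
#' @param event_len_range event length range in bins.
#' @param ar_classes optional character vector (recycled over clusters)
#'   of AR classes in `c("none","broad","focal")`; default assigns
#'   classes round-robin starting from "focal" so that at least one
#'   cluster is AR-gained.
#' @param purities optional explicit per-sample purities overriding
#'   `purity_range` (length `n_clusters * samples_per_cluster`).
#' @param patient_id label stored in the object.
#' @return an object of class `clone_tree_sim`: samples table
#'   (sample_id, cluster, purity), events table (with `class` in
#'   truncal/cluster/private/anchor and `owner`), `anchors` table with
#'   per-anchor allele copies, the genome model, and the seed.
#' @export
simulate_clone_tree <- function(n_clusters = 3, samples_per_cluster = 4,
                                n_truncal = 10, n_cluster = 15, n_private = 3,
                                purity_range = c(0.2, 0.9), seed = 1,
                                genome = default_genome(),
                                n_anchors = 3, anchor_len = 24,
                                n_cluster_x = 3,
                                event_len_range = c(4, 30),
                                ar_classes = NULL,
                                purities = NULL,
                                patient_id = "SIM01") {
  if (n_clusters < 1 || samples_per_cluster < 1)
    stop("n_clusters and samples_per_cluster must be >= 1")
  if (min(n_truncal, n_cluster, n_private, n_anchors, n_cluster_x) < 0)
    stop("event counts must be >= 0")
  if (length(purity_range) != 2 || purity_range[1] <= 0 ||
      purity_range[2] > 1 || purity_range[1] > purity_range[2])
    stop("purity_range must be an interval within (0, 1]")
  grid <- genome$grid
  autosomes <- grid$chroms[!is_chrx(grid$chroms)]
  if (length(autosomes) == 0) stop("genome model needs >= 1 autosome")

  with_seed(seed, {
    n_samples <- n_clusters * samples_per_cluster
    samples <- data.frame(
      sample_id = sprintf("%s_S%02d", patient_id, seq_len(n_samples)),
      cluster   = rep(seq_len(n_clusters), each = samples_per_cluster),
      stringsAsFactors = FALSE
    )
    samples$purity <- if (!is.null(purities)) {
      stopifnot(length(purities) == n_samples)
      as.numeric(purities)
    } else {
      stats::runif(n_samples, purity_range[1], purity_range[2])
    }

    ## boundary-bin bookkeeping for rejection sampling: keys "chrom:bin"
    used <- new.env(parent = emptyenv())
    claim <- function(chrom, s, e) {
      k1 <- paste0(chrom, ":", s); k2 <- paste0(chrom, ":", e)
      if (!is.null(used[[k1]]) || !is.null(used[[k2]])) return(FALSE)
      used[[k1]] <- TRUE; used[[k2]] <- TRUE
      TRUE
    }

    draw_event <- function(chroms, len_range, delta, allele, class, owner,
                           span_fn = NULL) {
      for (try in 1:2000) {
        chrom <- if (length(chroms) == 1) chroms else sample(chroms, 1)
        nb <- grid$chrom_bins[[chrom]]
        if (!is.null(span_fn)) {
          span <- span_fn(try)
          s <- max(span[1], 0L); e <- min(span[2], nb)
        } else {
          lens <- seq.int(len_range[1], min(len_range[2], nb - 1L))
          len <- if (length(lens) == 1) lens else sample(lens, 1)
          s <- sample.int(nb - len, 1) - 1L   # start bin in [0, nb-len-1]
          e <- s + len
        }
        if (claim(chrom, s, e))
          return(data.frame(chrom = chrom, start_bin = s, end_bin = e,
                            delta = delta, allele = allele, class = class,
                            owner = owner, stringsAsFactors = FALSE))
      }
      stop("could not place event without boundary collision; ",
           "genome too small for requested event counts")
    }

    events <- list()

    ## truncal LOH anchors: -1 on allele B, long autosomal stretches
    anchor_chroms <- rep(autosomes, length.out = max(n_anchors, 1))
    if (n_anchors > 0) {
      for (i in seq_len(n_anchors)) {
        events[[length(events) + 1L]] <- draw_event(
          anchor_chroms[i], c(anchor_len, anchor_len), -1L, "B",
          "anchor", "truncal")
      }
    }

    ## truncal autosomal events
    for (i in seq_len(n_truncal)) {
      events[[length(events) + 1L]] <- draw_event(
        autosomes, event_len_range, sample(c(-1L, 1L), 1), "A",
        "truncal", "truncal")
    }

    ## cluster-specific autosomal events
    for (cl in seq_len(n_clusters)) {
      for (i in seq_len(n_cluster)) {
        events[[length(events) + 1L]] <- draw_event(
          autosomes, event_len_range, sample(c(-1L, 1L), 1), "A",
          "cluster", as.character(cl))
      }
    }

    ## chrX: AR class per cluster + cluster-specific chrX events
    if (is.null(ar_classes))
      ar_classes <- c("focal", "none", "broad")
    ar_classes <- rep(ar_classes, length.out = n_clusters)
    xq <- genome$xq_bins
    x_nb <- grid$chrom_bins[["chrX"]]
    if (!is.na(x_nb)) {
      for (cl in seq_len(n_clusters)) {
        cls <- ar_classes[cl]
        if (cls == "focal") {
          amp <- sample(5:12, 1)
          ## focal amp spanning enhancer + AR; widen slightly on retries
          events[[length(events) + 1L]] <- draw_event(
            "chrX", NULL, amp, "A", "cluster", as.character(cl),
            span_fn = function(try) c(genome$enhancer_bin - 1L - (try - 1L),
                                      genome$ar_bin + 1L + (try %/% 2)))
        } else if (cls == "broad") {
          ## gain covering AR but < 80% of Xq
          events[[length(events) + 1L]] <- draw_event(
            "chrX", NULL, 1L, "A", "cluster", as.character(cl),
            span_fn = function(try) {
              span <- as.integer(round(length(xq) * stats::runif(1, 0.4, 0.7)))
              s <- max(genome$ar_bin - sample.int(span - 2L, 1), xq[1])
              c(s, s + span)
            })
        }
        for (i in seq_len(n_cluster_x)) {
          events[[length(events) + 1L]] <- draw_event(
            "chrX", c(3, 12), 1L, "A", "cluster", as.character(cl))
        }
      }
    }

    ## private autosomal events
    for (si in seq_len(n_samples)) {
      for (i in seq_len(n_private)) {
        events[[length(events) + 1L]] <- draw_event(
          autosomes, event_len_range, sample(c(-1L, 1L), 1), "A",
          "private", samples$sample_id[si])
      }
    }

    events <- if (length(events)) do.call(rbind, events) else empty_events()

    tree <- structure(
      list(patient_id = patient_id,
           clusters = seq_len(n_clusters),
           samples = samples,
           events = events,
           ar_class = stats::setNames(ar_classes, seq_len(n_clusters)),
           genome = genome,
           seed = seed),
      class = "clone_tree_sim")

    ## enforce CN >= 0 everywhere: flip offending deletions to gains
    cn <- tumor_cn_matrix(tree)
    while (any(cn < 0)) {
      bad_bin <- which(rowSums(cn < 0) > 0)[1]
      chrom <- grid$bins$chrom[bad_bin]
      bin0 <- bad_bin - min(chrom_bin_rows(grid, chrom))
      hit <- which(tree$events$chrom == chrom & tree$events$delta < 0 &
                   tree$events$start_bin <= bin0 & tree$events$end_bin > bin0)
      tree$events$delta[hit[length(hit)]] <- 1L
      cn <- tumor_cn_matrix(tree)
    }

    ## per-sample tumor mean autosomal ploidy
    auto_rows <- which(!is_chrx(grid$bins$chrom))
    tree$samples$ploidy <- colMeans(cn[auto_rows, , drop = FALSE])

    ## anchor table with allele-specific copies (truncal, so shared)
    anch <- tree$events[tree$events$class == "anchor", , drop = FALSE]
    tree$anchors <- if (nrow(anch)) data.frame(
      anchor_id = sprintf("anchor%02d", seq_len(nrow(anch))),
      chrom = anch$chrom,
      start = anch$start_bin * grid$bin_width,
      end   = anch$end_bin * grid$bin_width,
      n_A = 1L, n_B = 0L,
      stringsAsFactors = FALSE
    ) else NULL

    tree
  })
}

#' @export
print.clone_tree_sim <- function(x, ...) {
  cat("clone_tree_sim:", x$patient_id, "-", nrow(x$samples), "samples in",
      length(x$clusters), "clusters;", nrow(x$events), "planted CN events\n")
  invisible(x)
}

#' True per-bin tumor copy number of every sample
#'
#' Applies the planted events of a [simulate_clone_tree()] object to the
#' male baseline (2 copies autosome, 1 copy chrX) and returns the
#' resulting total tumor copy number.
#'
#' @param tree a `clone_tree_sim`.
#' @return numeric matrix, bins x samples.
#' @export
tumor_cn_matrix <- function(tree) {
  grid <- tree$genome$grid
  base <- normal_copy(grid)
  n_samples <- nrow(tree$samples)
  cn <- matrix(rep(base, n_samples), ncol = n_samples,
               dimnames = list(NULL, tree$samples$sample_id))
  ev <- tree$events
  if (nrow(ev) == 0) return(cn)
  for (i in seq_len(nrow(ev))) {
    rows0 <- min(chrom_bin_rows(grid, ev$chrom[i]))
    idx <- rows0 + seq.int(ev$start_bin[i], ev$end_bin[i] - 1L)
    cols <- switch(ev$class[i],
      truncal = , anchor = seq_len(n_samples),
      cluster = which(tree$samples$cluster == as.integer(ev$owner[i])),
      private = which(tree$samples$sample_id == ev$owner[i]))
    cn[idx, cols] <- cn[idx, cols] + ev$delta[i]
  }
  cn
}

## expected normalized read-depth ratio per bin for one sample:
## r = (rho * c_t + c_n * (1 - rho)) / D with D = rho * psi_t + 2 (1 - rho)
expected_ratio <- function(cn_bins, c_n, rho, psi_t) {
  D <- rho * psi_t + 2 * (1 - rho)
  (rho * cn_bins + c_n * (1 - rho)) / D
}

#' Simulate binned sequencing read counts
#'
#' Negative-binomial counts on the bin grid for every sample of a
#' planted clone tree.  The expected normalized ratio of a bin is
#' `r = (rho * c_t + c_n (1 - rho)) / D` with `c_t` the tumor copy
#' number, `c_n` the normal copy number (2 autosome / 1 male chrX),
#' `rho` the sample purity and `D = rho * psi_t + 2 (1 - rho)` the
#' genome-average copies (psi_t = mean autosomal tumor ploidy); the
#' count is NB with mean `depth_per_bin * r` and size `dispersion`
#' (`Inf` gives the Poisson limit).
#'
#' @param tree a `clone_tree_sim`.
#' @param depth_per_bin expected reads in a neutral bin.
#' @param dispersion NB size parameter k (variance `mu + mu^2/k`).
#' @param seed integer seed.
#' @return list of `binned_profile` objects, one per sample (see
#'   [normalize_counts()]), each also carrying the expected ratio as
#'   `true_ratio`.
#' @export
simulate_binned_counts <- function(tree, depth_per_bin = 100,
                                   dispersion = 100, seed = 1) {
  if (depth_per_bin <= 0 || dispersion <= 0)
    stop("depth_per_bin and dispersion must be positive")
  grid <- tree$genome$grid
  cn <- tumor_cn_matrix(tree)
  c_n <- normal_copy(grid)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(tree$samples)), function(si) {
      rho <- tree$samples$purity[si]
      psi <- tree$samples$ploidy[si]
      r <- expected_ratio(cn[, si], c_n, rho, psi)
      mu <- depth_per_bin * r
      counts <- if (is.finite(dispersion))
        stats::rnbinom(length(mu), mu = mu, size = dispersion)
      else stats::rpois(length(mu), mu)
      p <- binned_profile(tree$samples$sample_id[si], grid, counts)
      p$true_ratio <- r
      p
    })
    names(out) <- tree$samples$sample_id
    out
  })
}

#' Simulate phased heterozygous-SNP allele counts in anchor regions
#'
#' Places SNPs uniformly in each anchor region and, for each sample,
#' draws reads supporting the (true) haplotype-A allele binomially
#' around the allele-specific expected BAF implied by the local allele
#' copies and the sample purity.  The reported haplotype labels are
#' corrupted by a Markov switch process: walking along each anchor's
#' SNPs, the orientation flips with probability `switch_rate` per step,
#' emulating phasing switch errors.
#'
#' @param tree a `clone_tree_sim` with planted anchors.
#' @param anchor_regions anchor table (default `tree$anchors`).
#' @param snp_density heterozygous SNPs per Mb.
#' @param depth expected read depth per SNP (Poisson).
#' @param switch_rate per-SNP switch probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @return list: `snps` (snp_id, chrom, pos, anchor_id, flipped — the
#'   truth), `counts` (sample_id, snp_id, a_count = reads supporting the
#'   *reported* haplotype-A allele, depth).
#' @export
simulate_phased_snps <- function(tree, anchor_regions = tree$anchors,
                                 snp_density = 25, depth = 30,
                                 switch_rate = 0.05, seed = 1) {
  if (is.null(anchor_regions) || nrow(anchor_regions) == 0)
    stop("no anchor regions")
  if (switch_rate < 0 || switch_rate >= 0.5)
    stop("switch_rate must be in [0, 0.5)")
  grid <- tree$genome$grid
  with_seed(seed, {
    snp_list <- lapply(seq_len(nrow(anchor_regions)), function(ai) {
      a <- anchor_regions[ai, ]
      n <- max(2L, round(snp_density * (a$end - a$start) / 1e6))
      pos <- sort(sample.int(a$end - a$start, n)) + a$start
      ## Markov switch chain along the anchor
      flips <- stats::runif(n) < switch_rate
      state <- cumsum(flips) %% 2 == 1
      data.frame(chrom = a$chrom, pos = pos, anchor_id = a$anchor_id,
                 n_A = a$n_A, n_B = a$n_B, flipped = state,
                 stringsAsFactors = FALSE)
    })
    snps <- do.call(rbind, snp_list)
    snps$snp_id <- sprintf("snp%05d", seq_len(nrow(snps)))

    counts <- do.call(rbind, lapply(seq_len(nrow(tree$samples)), function(si) {
      rho <- tree$samples$purity[si]
      ## anchors are truncal: allele copies shared by all samples
      baf <- (rho * snps$n_A + (1 - rho)) /
             (rho * (snps$n_A + snps$n_B) + 2 * (1 - rho))
      dp <- stats::rpois(nrow(snps), depth)
      a_true <- stats::rbinom(nrow(snps), dp, baf)
      a_rep <- ifelse(snps$flipped, dp - a_true, a_true)
      data.frame(sample_id = tree$samples$sample_id[si],
                 snp_id = snps$snp_id, a_count = a_rep, depth = dp,
                 stringsAsFactors = FALSE)
    }))
    list(snps = snps[, c("snp_id", "chrom", "pos", "anchor_id", "flipped")],
         counts = counts)
  })
}

#' Simulate nested clonal mutation sets
#'
#' Mutation identifiers are nested by the clone tree: all samples share
#' the truncal ids, samples of one cluster additionally share that
#' cluster's ids, and each sample carries its own private ids.
#'
#' @param tree a `clone_tree_sim`.
#' @param n_truncal_mut,n_cluster_mut,n_private_mut counts per level.
#' @param seed integer seed (only used for reproducible id ordering).
#' @return named list of character vectors, one mutation-id set per
#'   sample.
#' @export
simulate_clonal_mutations <- function(tree, n_truncal_mut = 30,
                                      n_cluster_mut = 20, n_private_mut = 10,
                                      seed = 1) {
  if (min(n_truncal_mut, n_cluster_mut, n_private_mut) < 0)
    stop("mutation counts must be >= 0")
  with_seed(seed, {
    truncal <- sprintf("mt_truncal_%03d", seq_len(n_truncal_mut))
    cl_ids <- lapply(tree$clusters, function(cl)
      sprintf("mt_cl%d_%03d", cl, seq_len(n_cluster_mut)))
    sets <- lapply(seq_len(nrow(tree$samples)), function(si) {
      cl <- tree$samples$cluster[si]
      priv <- sprintf("mt_%s_%03d", tree$samples$sample_id[si],
                      seq_len(n_private_mut))
      c(truncal, cl_ids[[cl]], priv)
    })
    names(sets) <- tree$samples$sample_id
    sets
  })
}

#' Simulate AR-response gene expression counts
#'
#' Signature up-genes are shifted by `+effect_size * log2(AR copy
#' number)` on the log2 scale (down-genes by the negative shift), with
#' Gaussian log-scale noise, then exponentiated and rounded to counts.
#' The sample's AR copy number is the planted tumor copy number at the
#' AR bin.
#'
#' @param tree a `clone_tree_sim`.
#' @param signature data.frame (gene, direction) as from
#'   [read_ar_signature()].
#' @param effect_size log2-scale shift per log2 AR copy number.
#' @param noise_sd log2-scale Gaussian noise SD.
#' @param n_background unrelated background genes to add.
#' @param seed integer seed.
#' @return list: `counts` (gene x sample integer matrix), `ar_cn`
#'   (per-sample planted AR tumor copy number).
#' @export
simulate_expression <- function(tree, signature = read_ar_signature(),
                                effect_size = 1, noise_sd = 0.3,
                                n_background = 200, seed = 1) {
  if (nrow(signature) == 0) stop("empty signature")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  grid <- tree$genome$grid
  cn <- tumor_cn_matrix(tree)
  ar_row <- min(chrom_bin_rows(grid, "chrX")) + tree$genome$ar_bin
  ar_cn <- pmax(cn[ar_row, ], 1)
  with_seed(seed, {
    genes <- c(signature$gene, sprintf("BG%04d", seq_len(n_background)))
    dir <- c(ifelse(signature$direction == "up", 1, -1),
             rep(0, n_background))
    base <- stats::runif(length(genes), 5, 10)   # baseline log2 expression
    shift <- outer(dir, log2(ar_cn)) * effect_size
    logx <- base + shift +
      matrix(stats::rnorm(length(genes) * length(ar_cn), 0, noise_sd),
             nrow = length(genes))
    counts <- round(2^logx)
    dimnames(counts) <- list(genes, tree$samples$sample_id)
    list(counts = counts, ar_cn = ar_cn)
  })
}
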
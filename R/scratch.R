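## SCRATCH: Start of Copy number change for Relationship Assessment and
## Testing Clone Histories.  Copy-number transition points (boundaries
## between adjacent segments of different copy number) fingerprint the
## dominant clone of a sample; hierarchical clustering on the
## correlation of copy numbers at the union of a patient's transition
## points recovers the relationships of its metastases.

#' Extract copy-number transition points from a segmented profile
#'
#' One transition point per internal segment boundary where the copy
#' number changes; chromosome ends are not transition points.
#'
#' @param seg a `segment_profile` (uses the `cn` column when absolute CN
#'   has been called, otherwise the ratio).
#' @param chrom_subset `"autosomes"` (default), `"chrX"`, or a character
#'   vector of chromosome names.
#' @return data.frame (chrom, pos, left_cn, right_cn, direction) with
#'   `pos` the boundary in bp (a bin edge) and `direction` the sign of
#'   `right_cn - left_cn`.
#' @export
extract_transition_points <- function(seg, chrom_subset = "autosomes") {
  chroms <- resolve_chrom_subset(seg$grid, chrom_subset)
  s <- seg$segments
  val <- if (!is.null(s$cn)) s$cn else s$ratio
  out <- list()
  for (chrom in chroms) {
    idx <- which(s$chrom == chrom)
    if (length(idx) < 2) next
    v <- val[idx]
    keep <- which(diff(v) != 0)
    if (length(keep) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = chrom,
      pos = s$end[idx[keep]],
      left_cn = v[keep],
      right_cn = v[keep + 1],
      direction = sign(v[keep + 1] - v[keep]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), pos = numeric(),
                      left_cn = numeric(), right_cn = numeric(),
                      direction = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

resolve_chrom_subset <- function(grid, chrom_subset) {
  if (identical(chrom_subset, "autosomes"))
    grid$chroms[!is_chrx(grid$chroms)]
  else if (identical(chrom_subset, "chrX"))
    grid$chroms[is_chrx(grid$chroms)]
  else intersect(chrom_subset, grid$chroms)
}

#' Build the samples x transition-points copy-number matrix
#'
#' Columns are the union of all samples' transition-point positions
#' (exact bin-edge matching; every sample shares the grid).  The entry
#' for sample `s` at boundary `b` is the sample's revised copy number
#' immediately right of `b`: its length-weighted mean copy number over
#' the interval from `b` to the next union boundary (or chromosome
#' end).  When per-bin profiles are supplied via `binned`, the mean is
#' taken over the sample's bin-level copy numbers, which pools
#' information for samples whose own segmentation missed a boundary;
#' otherwise the sample's segment values are averaged over the interval
#' (identical on noiseless data).
#'
#' @param profiles named list of `segment_profile`s on one grid (CN
#'   called for absolute values; plain ratios otherwise).
#' @param chrom_subset as in [extract_transition_points()].
#' @param binned optional named list of normalized [binned_profile()]s
#'   matching `profiles`, used for bin-level averaging.
#' @return object of class `transition_matrix`: `values` (samples x
#'   boundaries matrix), `boundaries` (chrom, pos), and the transition
#'   point sets per sample.
#' @export
build_transition_matrix <- function(profiles, chrom_subset = "autosomes",
                                    binned = NULL) {
  if (length(profiles) < 1) stop("need >= 1 profile")
  grid <- profiles[[1]]$grid
  same <- vapply(profiles, function(p) identical(p$grid$bins, grid$bins),
                 logical(1))
  if (!all(same)) stop("profiles do not share one bin grid")
  tps <- lapply(profiles, extract_transition_points, chrom_subset = chrom_subset)
  chroms <- resolve_chrom_subset(grid, chrom_subset)
  bounds <- unique(do.call(rbind, lapply(tps, function(t) t[, c("chrom", "pos")])))
  bounds <- bounds[order(match(bounds$chrom, grid$chroms), bounds$pos), ,
                   drop = FALSE]
  if (nrow(bounds) == 0) stop("no transition points in any sample")

  ## per-sample per-bin copy-number values
  per_bin <- lapply(names(profiles), function(sid) {
    p <- profiles[[sid]]
    col <- if (!is.null(p$segments$cn)) "cn" else "ratio"
    if (!is.null(binned) && !is.null(binned[[sid]])) {
      b <- binned[[sid]]
      if (col == "cn") {
        D <- p$purity * p$ploidy + 2 * (1 - p$purity)
        c_n <- ifelse(is_chrx(grid$bins$chrom), 1, 2)
        pmax((b$ratio * D - c_n * (1 - p$purity)) / p$purity, 0)
      } else b$ratio
    } else segment_cn_per_bin(p, col)
  })
  names(per_bin) <- names(profiles)

  values <- matrix(NA_real_, nrow = length(profiles), ncol = nrow(bounds),
                   dimnames = list(names(profiles),
                                   paste0(bounds$chrom, ":", bounds$pos)))
  interval_bins <- integer(nrow(bounds))
  for (chrom in chroms) {
    bi <- which(bounds$chrom == chrom)
    if (length(bi) == 0) next
    rows <- chrom_bin_rows(grid, chrom)
    chrom_start <- grid$bins$start[rows[1]]
    edges <- c(bounds$pos[bi], grid$bins$end[rows[length(rows)]])
    for (j in seq_along(bi)) {
      from_bin <- (edges[j] - chrom_start) / grid$bin_width
      to_bin <- (edges[j + 1] - chrom_start) / grid$bin_width
      idx <- rows[1] + seq.int(from_bin, to_bin - 1L)
      interval_bins[bi[j]] <- length(idx)
      for (sid in names(profiles))
        values[sid, bi[j]] <- mean(per_bin[[sid]][idx])
    }
  }
  structure(list(values = values, boundaries = bounds,
                 interval_bins = interval_bins, transition_points = tps),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "transition points\n")
  invisible(x)
}

#' Correlation distance between samples
#'
#' `d(i, j) = 1 - cor(row_i, row_j)` (Pearson by default), giving
#' distances in `[0, 2]`.  For a `transition_matrix` the Pearson
#' correlation is precision-weighted by the number of bins behind each
#' column: an entry averaged over L bins has noise variance
#' proportional to 1/L, so long intervals carry proportionally more
#' weight (`weights = NULL` disables this; Spearman is always
#' unweighted).  Zero-variance rows cannot be correlated and get the
#' maximum distance (with a warning).
#'
#' @param tm a `transition_matrix` (or a plain samples x features
#'   matrix).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param weights per-column weights; defaults to the transition
#'   matrix's interval lengths for Pearson.
#' @return symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(tm, method = c("pearson", "spearman"),
                                 weights = NULL) {
  method <- match.arg(method)
  m <- if (inherits(tm, "transition_matrix")) tm$values else tm
  if (ncol(m) < 2) stop("need >= 2 transition points")
  if (is.null(weights) && inherits(tm, "transition_matrix") &&
      method == "pearson")
    weights <- tm$interval_bins
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " zero-variance sample(s); distances set to max")
  r <- if (method == "pearson" && !is.null(weights)) {
    suppressWarnings(stats::cov.wt(t(m), wt = weights / sum(weights),
                                   cor = TRUE)$cor)
  } else {
    suppressWarnings(stats::cor(t(m), method = method))
  }
  r[!is.finite(r)] <- -1
  d <- 1 - r
  diag(d) <- 0
  d
}

#' SCRATCH clustering of a patient's samples
#'
#' Agglomerative clustering on the transition-point correlation
#' distance.  The number of clusters is chosen by maximum mean
#' silhouette width over `k = 2 .. min(k_max, n - 1)` (ties to the
#' smallest k); any cluster with fewer than two samples is then merged
#' into the cluster sharing its most recent common ancestor (the
#' nearest cluster in cophenetic distance), iterated until all clusters
#' have >= 2 members or only one remains.
#'
#' @param d distance matrix from [correlation_distance()].
#' @param linkage `"complete"` (default), `"average"` or `"ward.D2"`.
#' @param k_max maximum number of clusters scanned.
#' @return a [sample_tree()] with cluster assignments, chosen k and the
#'   silhouette profile.
#' @export
scratch_cluster <- function(d, linkage = c("complete", "average", "ward.D2"),
                            k_max = 8) {
  linkage <- match.arg(linkage)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  if (n < 3) {
    warning("fewer than 3 samples: single cluster returned")
    cl <- stats::setNames(rep(1L, n), labels)
    return(sample_tree(hclust = NULL, labels = labels, clusters = cl,
                       k = 1L, silhouette = NA_real_))
  }
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  ks <- seq(2L, min(k_max, n - 1L))
  sil <- vapply(ks, function(k) {
    a <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(a, dmatrix = d)[, "sil_width"])
  }, numeric(1))
  k_star <- ks[which.max(sil)]
  assign <- stats::cutree(hc, k = k_star)

  ## merge rule: absorb singletons into the cophenetically nearest cluster
  coph <- as.matrix(stats::cophenetic(hc))
  repeat {
    sizes <- table(assign)
    small <- names(sizes)[sizes < 2]
    if (length(small) == 0 || length(sizes) == 1) break
    cl_small <- as.integer(small[1])
    members <- names(assign)[assign == cl_small]
    others <- setdiff(unique(assign), cl_small)
    nearest <- others[which.min(vapply(others, function(o) {
      min(coph[members, names(assign)[assign == o], drop = FALSE])
    }, numeric(1)))]
    assign[assign == cl_small] <- nearest
  }
  assign <- stats::setNames(match(assign, sort(unique(assign))), names(assign))
  sample_tree(hclust = hc, labels = labels, clusters = assign,
              k = length(unique(assign)),
              silhouette = max(sil), sil_by_k = stats::setNames(sil, ks))
}

tp_key <- function(tp, match_direction) {
  if (nrow(tp) == 0) return(character(0))
  if (match_direction) paste0(tp$chrom, ":", tp$pos, ":", tp$direction)
  else paste0(tp$chrom, ":", tp$pos)
}

#' Fraction of a sample's transition points shared with targets
#'
#' @param query a `segment_profile` (or a transition-point data.frame).
#' @param targets list of `segment_profile`s (or data.frames).
#' @param mode `"any"`: present in at least one target; `"all"`: present
#'   in every target.
#' @param match_direction also require the same sign of copy-number
#'   change.
#' @param chrom_subset as in [extract_transition_points()].
#' @return fraction in `[0, 1]`, or `NA` when the query has no
#'   transition points.
#' @export
shared_transition_fraction <- function(query, targets, mode = c("any", "all"),
                                       match_direction = FALSE,
                                       chrom_subset = "autosomes") {
  mode <- match.arg(mode)
  as_tp <- function(x) if (inherits(x, "segment_profile"))
    extract_transition_points(x, chrom_subset) else x
  q <- tp_key(as_tp(query), match_direction)
  if (length(q) == 0) return(NA_real_)
  hits <- vapply(targets, function(t) q %in% tp_key(as_tp(t), match_direction),
                 logical(length(q)))
  if (length(targets) == 1) hits <- matrix(hits, ncol = 1)
  shared <- if (mode == "any") apply(hits, 1, any) else apply(hits, 1, all)
  mean(shared)
}

#' Pairwise shared-transition-point matrix with categorical binning
#'
#' The (i, j) entry is the fraction of sample i's transition points
#' found in sample j (so the matrix is not symmetric unless
#' `symmetrize`); entries are also binned into `<20%`, `20-80%` and
#' `>80%`.
#'
#' @param profiles named list of `segment_profile`s.
#' @param match_direction as in [shared_transition_fraction()].
#' @param chrom_subset as in [extract_transition_points()].
#' @param symmetrize average the two directed fractions (default TRUE).
#' @return list: `fraction` matrix and `category` factor matrix.
#' @export
pairwise_shared_matrix <- function(profiles, match_direction = FALSE,
                                   chrom_subset = "autosomes",
                                   symmetrize = TRUE) {
  if (length(profiles) < 2) stop("need >= 2 profiles")
  n <- length(profiles)
  ids <- names(profiles)
  keys <- lapply(profiles, function(p)
    tp_key(extract_transition_points(p, chrom_subset), match_direction))
  f <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { f[i, j] <- 1; next }
    if (length(keys[[i]]) == 0) next
    f[i, j] <- mean(keys[[i]] %in% keys[[j]])
  }
  if (symmetrize) f <- (f + t(f)) / 2
  cat_m <- matrix(cut(f, breaks = c(-Inf, 0.2, 0.8, Inf),
                      labels = c("<20%", "20-80%", ">80%"), right = FALSE),
                  n, n, dimnames = dimnames(f))
  list(fraction = f, category = cat_m)
}
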
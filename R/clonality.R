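## Breakpoint cancer-cell-fraction arithmetic, clonal-mutation overlap
## statistics, AR-locus breakpoint counting and the associated exact
## tests.

#' Cancer cell fraction of a structural-variant breakpoint
#'
#' The allelic fraction is first normalized by tumor content and then
#' adjusted for the local chromosome number of variant and wild-type
#' alleles:
#' `CCF = AF * (rho * CN_t + c_n (1 - rho)) / (rho * m)`,
#' with `c_n` = 2 on autosomes and 1 on the male chrX, and `m` the
#' variant-allele multiplicity (default 1 — shallow data cannot resolve
#' it).  Values above `ccf_cap` arise from noise or mis-specified copy
#' number and are capped; the raw value is kept in the `raw` attribute.
#'
#' @param AF allelic fraction in `[0, 1]`.
#' @param rho tumor purity in (0, 1].
#' @param CN_t local total copy number (> 0).
#' @param m variant multiplicity (integer >= 1).
#' @param chrx TRUE for a male chrX breakpoint.
#' @param ccf_cap cap (default 1).
#' @return CCF (vectorized), capped, with attribute `raw`.
#' @export
breakpoint_ccf <- function(AF, rho, CN_t, m = 1, chrx = FALSE, ccf_cap = 1) {
  if (any(rho <= 0) || any(rho > 1)) stop("rho must be in (0, 1]")
  if (any(m < 1)) stop("multiplicity m must be >= 1")
  if (any(AF < 0 | AF > 1)) stop("AF must be in [0, 1]")
  c_n <- ifelse(chrx, 1, 2)
  raw <- AF * (rho * CN_t + c_n * (1 - rho)) / (rho * m)
  out <- pmin(raw, ccf_cap)
  attr(out, "raw") <- raw
  out
}

#' Clonal mutation overlap between two samples
#'
#' The intersection of the two non-silent clonal mutation sets,
#' normalized by the smaller set size: `|a . b| / min(|a|, |b|)`.
#'
#' @param a,b character vectors of mutation ids (non-empty).
#' @return fraction in `[0, 1]`; NA with a warning on an empty set.
#' @export
clonal_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) {
    warning("empty mutation set: overlap undefined")
    return(NA_real_)
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

#' All pairwise clonal overlaps with same-cluster flags
#'
#' @param mutation_sets named list of mutation-id vectors.
#' @param clusters named cluster assignment for the same samples.
#' @return data.frame (sample1, sample2, overlap, same_cluster).
#' @export
pairwise_clonal_overlap <- function(mutation_sets, clusters) {
  ids <- names(mutation_sets)
  pairs <- utils::combn(ids, 2)
  data.frame(
    sample1 = pairs[1, ], sample2 = pairs[2, ],
    overlap = apply(pairs, 2, function(p)
      clonal_overlap(mutation_sets[[p[1]]], mutation_sets[[p[2]]])),
    same_cluster = clusters[pairs[1, ]] == clusters[pairs[2, ]],
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Exact rank-sum test by enumeration
#'
#' Conditional (permutation) distribution of the rank sum of the first
#' group, with average ranks under ties, enumerated exactly when the
#' number of group assignments is at most `max_tables`; otherwise
#' delegates to [stats::wilcox.test()] (exact when tie-free, normal
#' approximation otherwise).
#'
#' @param x,y numeric samples.
#' @param alternative `"greater"`, `"less"` or `"two.sided"` (for x
#'   relative to y).
#' @param max_tables enumeration cap.
#' @return p-value.
#' @export
rank_sum_test <- function(x, y, alternative = c("greater", "less",
                                                "two.sided"),
                          max_tables = 2e5) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n <- n1 + length(y)
  if (n1 >= 1 && choose(n, n1) <= max_tables) {
    r <- rank(c(x, y))
    obs <- sum(r[seq_len(n1)])
    combs <- utils::combn(n, n1)
    stats <- colSums(matrix(r[combs], nrow = n1))
    eps <- 1e-9
    pg <- mean(stats >= obs - eps)
    pl <- mean(stats <= obs + eps)
    switch(alternative, greater = pg, less = pl,
           two.sided = min(1, 2 * min(pg, pl)))
  } else {
    exact <- n1 <= 50 && (n - n1) <= 50 && !anyDuplicated(c(x, y))
    suppressWarnings(stats::wilcox.test(
      x, y, alternative = alternative, exact = exact)$p.value)
  }
}

#' One-sided test of higher overlap within clusters
#'
#' Wilcoxon rank-sum test of H1: same-cluster overlaps exceed
#' cross-cluster overlaps; exact for small tie-free samples.
#'
#' @param overlaps numeric overlap fractions.
#' @param same_cluster logical flags.
#' @return p-value.
#' @export
overlap_by_cluster_test <- function(overlaps, same_cluster) {
  x <- overlaps[same_cluster]; y <- overlaps[!same_cluster]
  if (length(x) == 0 || length(y) == 0) stop("a group is empty")
  rank_sum_test(x, y, "greater")
}

#' Unique AR-locus breakpoints per patient, with group comparison
#'
#' Counts unique breakpoint positions (deduplicated at base-pair
#' identity within a patient) falling inside a half-open chrX window
#' around the AR gene, and compares two patient groups by exact
#' Mann-Whitney.
#'
#' @param calls data.frame with columns patient, chrom, pos.
#' @param window list/data.frame with chrom, start, end (half-open).
#' @param groups optional named group labels per patient (two levels)
#'   for the comparison.
#' @return list: `counts` (per-patient unique-breakpoint counts) and,
#'   when groups are given, `p` from the one-sided Mann-Whitney test
#'   that the first group level has fewer breakpoints.
#' @export
count_ar_locus_breakpoints <- function(calls, window, groups = NULL) {
  inside <- calls$chrom == window$chrom & calls$pos >= window$start &
    calls$pos < window$end
  cc <- calls[inside, , drop = FALSE]
  counts <- vapply(split(cc$pos, cc$patient), function(p)
    length(unique(p)), integer(1))
  ## patients with no in-window breakpoint still count as zero
  all_pat <- unique(calls$patient)
  full <- stats::setNames(integer(length(all_pat)), all_pat)
  full[names(counts)] <- counts
  out <- list(counts = full)
  if (!is.null(groups)) {
    g <- as.factor(groups[names(full)])
    x <- full[g == levels(g)[1]]; y <- full[g == levels(g)[2]]
    out$p <- rank_sum_test(x, y, "less")
  }
  out
}

#' One-sided Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric tail probability; degenerate margins (an empty
#' row or column) return p = 1 with a warning.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"less"` or `"greater"` (odds ratio of the table).
#' @return p-value.
#' @export
fisher_exact_one_sided <- function(table, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("degenerate margins: p = 1 by convention")
    return(1)
  }
  stats::fisher.test(table, alternative = alternative)$p.value
}
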
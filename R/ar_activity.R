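## Androgen-receptor transcriptional activity: a ternary z-score sum
## over an AR-response gene signature.

#' Read an AR-response gene signature
#'
#' The signature is data, not code: a two-column TSV (gene, direction
#' in up/down).  The bundled default reconstructs the classical
#' 27-gene androgen-response signature of Hieronymus et al. (2006) and
#' can be replaced by any user file.
#'
#' @param path TSV path; default the bundled signature.
#' @return data.frame (gene, direction), duplicates refused.
#' @export
read_ar_signature <- function(path = system.file("extdata", "ar_signature.tsv",
                                                 package = "scratchcn")) {
  sig <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "direction") %in% names(sig)))
    stop("signature needs columns gene, direction")
  if (anyDuplicated(sig$gene)) stop("duplicate genes in signature")
  if (!all(sig$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  sig
}

#' Filter and normalize an expression count table
#'
#' Keeps genes with at least 10 reads in at least 90% of samples,
#' transforms to log2 counts-per-million (+0.5 offset), and quantile
#' normalizes the samples to a common empirical distribution.
#'
#' @param counts gene x sample count matrix (>= 2 samples).
#' @param min_count,min_fraction filter: `count >= min_count` in
#'   `>= min_fraction` of samples.
#' @return normalized log2 expression matrix over the surviving genes.
#' @export
filter_and_normalize <- function(counts, min_count = 10, min_fraction = 0.9) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  keep <- rowMeans(counts >= min_count) >= min_fraction
  if (!any(keep)) stop("no genes survive the expression filter")
  counts <- counts[keep, , drop = FALSE]
  lib <- colSums(counts)
  logcpm <- log2(t(t(counts) / lib) * 1e6 + 0.5)
  limma::normalizeQuantiles(logcpm)
}

#' Gene-wise z-scores across samples
#'
#' @param expr normalized log-expression matrix (genes x samples).
#' @return z-score matrix with per-gene mean 0 and SD 1; zero-variance
#'   genes get z = 0.
#' @export
zscore_by_gene <- function(expr) {
  mu <- rowMeans(expr)
  sd <- apply(expr, 1, stats::sd)
  z <- (expr - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Ternary score of a z-score
#'
#' Up-regulated genes: `+1` at `z >= 1`, `-1` at `z <= -1`, else 0.
#' Down-regulated genes use the converse rule (the negation).
#'
#' @param z finite z-score(s).
#' @param direction `"up"` or `"down"` (recycled).
#' @return integer(s) in `{-1, 0, 1}`.
#' @export
ternary_score <- function(z, direction) {
  stopifnot(all(is.finite(z)), all(direction %in% c("up", "down")))
  up <- ifelse(z >= 1, 1L, ifelse(z <= -1, -1L, 0L))
  ifelse(direction == "up", up, -up)
}

#' Aggregate AR score per sample
#'
#' Sums the ternary scores of the signature genes present in the
#' z-score matrix; genes missing from the matrix are skipped with a
#' message.  The result is an integer in `[-G, G]`, G = genes used.
#'
#' @param zm gene x sample z-score matrix (see [zscore_by_gene()]).
#' @param sig signature data.frame (gene, direction).
#' @return named integer vector of per-sample AR scores; attribute
#'   `n_genes_used` records G.
#' @export
ar_score <- function(zm, sig) {
  present <- sig$gene %in% rownames(zm)
  if (!any(present)) stop("no signature genes present in the z-score matrix")
  if (any(!present))
    message(sum(!present), " signature gene(s) absent; scoring over ",
            sum(present), " genes")
  sig <- sig[present, , drop = FALSE]
  z <- zm[sig$gene, , drop = FALSE]
  scores <- vapply(seq_len(ncol(z)), function(j)
    sum(ternary_score(z[, j], sig$direction)), integer(1))
  names(scores) <- colnames(z)
  attr(scores, "n_genes_used") <- nrow(sig)
  scores
}

#' Mann-Whitney comparison of expression (or scores) between groups
#'
#' Exact-distribution p for small groups (<= 12 per group, no ties),
#' normal approximation otherwise.
#'
#' @param values numeric vector.
#' @param groups two-level grouping vector.
#' @param alternative `"two.sided"` (default), `"less"`, `"greater"`
#'   (with respect to the first group level).
#' @return p-value.
#' @export
compare_expression_by_group <- function(values, groups,
                                        alternative = "two.sided") {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("need exactly two groups")
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  if (length(x) == 0 || length(y) == 0) stop("a group is empty")
  if (length(x) <= 12 && length(y) <= 12)
    rank_sum_test(x, y, alternative)
  else suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = FALSE)$p.value)
}
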
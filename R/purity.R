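## Tumor purity estimation: haplotype-BAF anchor method, penalized
## purity/ploidy grid fit, and their consensus.
##
## The anchor method works because in an allelically imbalanced region
## with allele copies (n_A, n_B), n_A > n_B, the expected haplotype-A
## BAF at purity rho is
##   B = (rho * n_A + (1 - rho)) / (rho * (n_A + n_B) + 2 (1 - rho)),
## which inverts to
##   rho = (1 - 2 B) / (B * (n_A + n_B - 2) - (n_A - 1)).
## Haplotype labels first need switch-error correction against a
## high-purity sample, whose BAF modes are well separated.

#' Select anchor regions for haplotype-BAF purity estimation
#'
#' Anchors are long segments with a low read-depth ratio (below the
#' sample median by `ratio_margin`) and clear allelic imbalance (pooled
#' phased BAF away from 0.5 by more than `baf_margin`) in the
#' high-coverage sample.  Each anchor is annotated with the allele
#' copies `(n_A, n_B)` consistent with its ratio and BAF under the known
#' purity/ploidy of that sample.
#'
#' @param high_cov_seg a `segment_profile` of the high-coverage sample
#'   with absolute CN called (purity/ploidy known).
#' @param snp_table output of [simulate_phased_snps()] (or a list with
#'   the same `snps`/`counts` layout).
#' @param high_cov_sample sample id of the high-coverage sample in
#'   `snp_table$counts`.
#' @param ratio_margin how far below the median ratio a segment must be.
#' @param baf_margin minimum |pooled BAF - 0.5|.
#' @param min_length_bp minimum anchor length (default 10 Mb).
#' @param min_snps minimum SNP count inside the segment.
#' @return data.frame of anchors (anchor_id, chrom, start, end, n_A,
#'   n_B); a warning is raised when fewer than 3 qualify.
#' @export
select_anchor_regions <- function(high_cov_seg, snp_table, high_cov_sample,
                                  ratio_margin = 0.1, baf_margin = 0.08,
                                  min_length_bp = 1e7, min_snps = 20) {
  s <- high_cov_seg$segments
  rho <- high_cov_seg$purity; psi <- high_cov_seg$ploidy
  if (is.na(rho) || is.na(psi)) stop("high-coverage sample needs known purity/ploidy")
  med <- stats::median(rep(s$ratio, s$n_bins))
  cnt <- snp_table$counts[snp_table$counts$sample_id == high_cov_sample, ]
  cnt <- merge(cnt, snp_table$snps, by = "snp_id")
  out <- list()
  for (i in seq_len(nrow(s))) {
    if (is_chrx(s$chrom[i])) next
    if (s$end[i] - s$start[i] < min_length_bp) next
    if (s$ratio[i] >= med - ratio_margin) next
    in_seg <- cnt$chrom == s$chrom[i] & cnt$pos >= s$start[i] &
      cnt$pos < s$end[i]
    if (sum(in_seg) < min_snps) next
    baf <- sum(cnt$a_count[in_seg]) / sum(cnt$depth[in_seg])
    ## orient so haplotype A is the over-represented allele
    baf_a <- max(baf, 1 - baf)
    if (baf_a - 0.5 <= baf_margin) next
    D <- rho * psi + 2 * (1 - rho)
    c_tot <- round((s$ratio[i] * D - 2 * (1 - rho)) / rho)
    n_a <- round((baf_a * (rho * c_tot + 2 * (1 - rho)) - (1 - rho)) / rho)
    n_b <- c_tot - n_a
    if (is.na(n_a) || n_a <= n_b || n_b < 0) next
    out[[length(out) + 1L]] <- data.frame(
      anchor_id = sprintf("anchor%02d", length(out) + 1L),
      chrom = s$chrom[i], start = s$start[i], end = s$end[i],
      n_A = as.integer(n_a), n_B = as.integer(n_b),
      stringsAsFactors = FALSE)
  }
  anchors <- if (length(out)) do.call(rbind, out) else
    data.frame(anchor_id = character(), chrom = character(),
               start = numeric(), end = numeric(),
               n_A = integer(), n_B = integer(), stringsAsFactors = FALSE)
  if (nrow(anchors) < 3)
    warning("only ", nrow(anchors),
            " anchor region(s) qualify; haplotype-BAF purity will be invalid")
  anchors
}

#' Correct phasing switch errors against a high-purity sample
#'
#' In a high-purity sample the phased BAF inside an allelically
#' imbalanced anchor splits into two well separated modes, so each SNP's
#' reported orientation can be read off that sample: SNPs whose
#' high-purity BAF is below 0.5 are flipped so that haplotype A is the
#' over-represented allele throughout.  SNPs whose high-purity BAF lies
#' within `ambiguous_margin` of 0.5 are dropped (count reported in the
#' `n_dropped` attribute).
#'
#' @param snp_table list with `snps` and `counts` (see
#'   [simulate_phased_snps()]).
#' @param high_purity_sample sample id used as the haplotype reference.
#' @param ambiguous_margin half-width of the drop zone around BAF 0.5.
#' @return the snp_table with corrected `a_count` for every sample and
#'   ambiguous SNPs removed; attribute `n_dropped` gives the drop count.
#' @export
correct_switch_errors <- function(snp_table, high_purity_sample,
                                  ambiguous_margin = 0.05) {
  ref <- snp_table$counts[snp_table$counts$sample_id == high_purity_sample, ]
  if (nrow(ref) == 0) stop("high-purity sample not found in snp table")
  baf <- ref$a_count / pmax(ref$depth, 1)
  flip <- baf < 0.5
  drop <- abs(baf - 0.5) <= ambiguous_margin | ref$depth == 0
  flip_ids <- ref$snp_id[flip & !drop]
  keep_ids <- ref$snp_id[!drop]
  cnt <- snp_table$counts[snp_table$counts$snp_id %in% keep_ids, ]
  do_flip <- cnt$snp_id %in% flip_ids
  cnt$a_count[do_flip] <- cnt$depth[do_flip] - cnt$a_count[do_flip]
  out <- list(snps = snp_table$snps[snp_table$snps$snp_id %in% keep_ids, ],
              counts = cnt)
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Purity from pooled haplotype BAF in one anchor
#'
#' Pools corrected haplotype-A counts over the anchor's SNPs (weighting
#' by depth) and inverts the allele-specific BAF model:
#' `rho = (1 - 2 B) / (B (n_A + n_B - 2) - (n_A - 1))`, clipped to
#' `[0, 1]`.
#'
#' @param snp_table switch-corrected snp table (one sample's counts or
#'   filtered with `sample_id`).
#' @param anchor one row of an anchor table (n_A, n_B, chrom, start, end).
#' @param sample_id optional sample filter applied to the counts.
#' @param min_snps minimum SNPs required.
#' @return purity estimate in `[0, 1]`.
#' @export
purity_from_haplotype_baf <- function(snp_table, anchor, sample_id = NULL,
                                      min_snps = 10) {
  cnt <- snp_table$counts
  if (!is.null(sample_id)) cnt <- cnt[cnt$sample_id == sample_id, ]
  cnt <- merge(cnt, snp_table$snps, by = "snp_id")
  in_anchor <- cnt$chrom == anchor$chrom & cnt$pos >= anchor$start &
    cnt$pos < anchor$end
  if (sum(in_anchor) < min_snps)
    stop("anchor has fewer than ", min_snps, " SNPs")
  B <- sum(cnt$a_count[in_anchor]) / sum(cnt$depth[in_anchor])
  denom <- B * (anchor$n_A + anchor$n_B - 2) - (anchor$n_A - 1)
  if (abs(denom) < 1e-9) stop("undefined anchor: BAF denominator ~ 0")
  rho <- (1 - 2 * B) / denom
  min(max(rho, 0), 1)
}

#' Penalized purity/ploidy grid fit
#'
#' Scores each `(rho, psi)` on a grid by the length-weighted distance of
#' implied segment copy numbers to integers, inflated for low
#' cellularity and non-diploid ploidy:
#' `E = sum_s w_s |CN_s - round(CN_s)| / rho^0.5 * (1 + |psi - 2|)^0.5`
#' (both penalty exponents 0.5).  Ties break toward higher purity, then
#' ploidy nearer 2.  A flat profile cannot constrain the fit and returns
#' `rho = 1, psi = 2` with `degenerate = TRUE`.
#'
#' @param seg a `segment_profile` (ratios; CN need not be called).
#' @param rho_grid purity grid (default 0.05..1.00 step 0.01).
#' @param psi_grid ploidy grid (default 1.5..5.0 step 0.05).
#' @return list (rho, psi, score, degenerate).
#' @export
grid_fit_purity_ploidy <- function(seg,
                                   rho_grid = seq(0.05, 1, by = 0.01),
                                   psi_grid = seq(1.5, 5, by = 0.05)) {
  s <- seg$segments
  if (nrow(s) < 5) stop("need >= 5 segments for a grid fit")
  w <- s$n_bins / sum(s$n_bins)
  c_n <- ifelse(is_chrx(s$chrom), 1, 2)
  spread <- sum(w * abs(s$ratio - sum(w * s$ratio)))
  if (spread < 1e-3)
    return(list(rho = 1, psi = 2, score = 0, degenerate = TRUE))
  best <- NULL
  for (psi in psi_grid) for (rho in rho_grid) {
    D <- rho * psi + 2 * (1 - rho)
    cn <- (s$ratio * D - c_n * (1 - rho)) / rho
    err <- sum(w * abs(cn - round(cn))) / sqrt(rho) * sqrt(1 + abs(psi - 2))
    if (is.null(best) || err < best$score - 1e-12 ||
        (err < best$score + 1e-12 &&
         (rho > best$rho + 1e-12 ||
          (abs(rho - best$rho) < 1e-12 &&
           abs(psi - 2) < abs(best$psi - 2))))) {
      best <- list(rho = rho, psi = psi, score = err, degenerate = FALSE)
    }
  }
  best
}

#' Consensus of haplotype-BAF and grid-fit purity
#'
#' Both valid and within 0.1 of each other: their mean.  Both valid but
#' discordant: the haplotype-BAF estimate wins (it is anchored in
#' germline phase information) and the result is flagged.  Otherwise the
#' single valid estimate.
#'
#' @param rho_hapbaf haplotype-BAF purity (NA if invalid).
#' @param rho_grid grid-fit purity (NA if invalid).
#' @param window concordance window (default 0.1).
#' @return list (rho, discordant).
#' @export
consensus_purity <- function(rho_hapbaf, rho_grid, window = 0.1) {
  v1 <- is.finite(rho_hapbaf); v2 <- is.finite(rho_grid)
  if (!v1 && !v2) stop("no valid purity estimate")
  if (v1 && v2) {
    if (abs(rho_hapbaf - rho_grid) <= window)
      list(rho = mean(c(rho_hapbaf, rho_grid)), discordant = FALSE)
    else list(rho = rho_hapbaf, discordant = TRUE)
  } else if (v1) list(rho = rho_hapbaf, discordant = FALSE)
  else list(rho = rho_grid, discordant = FALSE)
}

#' Estimate purity for every sample of a cohort
#'
#' Convenience wrapper tying the anchor pipeline together: switch-error
#' correction against the designated high-purity sample, per-anchor
#' haplotype-BAF purity (median over anchors, valid with >= `min_anchors`),
#' the grid fit on the sample's segmented profile, and their consensus.
#'
#' @param seg_profiles named list of `segment_profile`s (ratio scale).
#' @param snp_table phased SNP table (list with snps/counts).
#' @param anchors anchor table with n_A/n_B annotation.
#' @param high_purity_sample sample id of the haplotype reference.
#' @param min_anchors minimum usable anchors for a valid hapBAF estimate.
#' @return data.frame: sample_id, rho_hapbaf, rho_grid, psi_grid,
#'   rho_consensus, n_anchors_used, discordant.
#' @export
estimate_purity <- function(seg_profiles, snp_table, anchors,
                            high_purity_sample, min_anchors = 3) {
  corrected <- correct_switch_errors(snp_table, high_purity_sample)
  res <- lapply(names(seg_profiles), function(sid) {
    per_anchor <- vapply(seq_len(nrow(anchors)), function(ai) {
      tryCatch(purity_from_haplotype_baf(corrected, anchors[ai, ],
                                         sample_id = sid),
               error = function(e) NA_real_)
    }, numeric(1))
    used <- sum(is.finite(per_anchor))
    rho_hb <- if (used >= min_anchors)
      stats::median(per_anchor, na.rm = TRUE) else NA_real_
    fit <- tryCatch(grid_fit_purity_ploidy(seg_profiles[[sid]]),
                    error = function(e) list(rho = NA_real_, psi = NA_real_))
    cons <- consensus_purity(rho_hb, fit$rho)
    data.frame(sample_id = sid, rho_hapbaf = rho_hb, rho_grid = fit$rho,
               psi_grid = fit$psi, rho_consensus = cons$rho,
               n_anchors_used = used, discordant = cons$discordant,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
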
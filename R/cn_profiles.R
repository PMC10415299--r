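## Binned copy-number profiles: normalization, greedy segmentation,
## absolute copy-number calling, AR copy number and gain status.

#' Binned read-count profile of one sample
#'
#' @param sample_id sample label.
#' @param grid a [bin_grid()].
#' @param count per-bin raw read counts (length `grid$n_bins`).
#' @param ratio optional pre-computed normalized ratios.
#' @return object of class `binned_profile`.
#' @export
binned_profile <- function(sample_id, grid, count, ratio = NULL) {
  stopifnot(length(count) == grid$n_bins)
  if (!is.null(ratio)) stopifnot(length(ratio) == grid$n_bins)
  structure(list(sample_id = sample_id, grid = grid,
                 count = as.numeric(count), ratio = ratio),
            class = "binned_profile")
}

#' @export
print.binned_profile <- function(x, ...) {
  cat("binned_profile:", x$sample_id, "-", x$grid$n_bins, "bins",
      if (!is.null(x$ratio)) "(normalized)" else "(raw)", "\n")
  invisible(x)
}

#' Normalize binned counts to the autosomal median
#'
#' Ratios are `count / median(autosomal counts)`, so the median
#' autosomal ratio is 1 regardless of sequencing depth.
#'
#' @param profile a [binned_profile()].
#' @return the profile with `ratio` filled in.
#' @export
normalize_counts <- function(profile) {
  auto <- !is_chrx(profile$grid$bins$chrom)
  m <- stats::median(profile$count[auto])
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize: autosomal median count is zero")
  profile$ratio <- profile$count / m
  profile
}

#' Greedy segmentation of a normalized profile
#'
#' Walks each chromosome left to right; a bin joins the current segment
#' iff its ratio is within `merge_tol` of the running segment mean.
#' After the greedy pass, adjacent segments whose means are within
#' `merge_tol` are merged (iterated to a fixed point), so the result is
#' idempotent: re-segmenting a segmented profile changes nothing.
#' Segments never cross chromosome boundaries.
#'
#' Isolated single-bin spikes (a bin differing from both neighbours by
#' more than `merge_tol` while the neighbours agree with each other)
#' are smoothed to the neighbour mean before merging when
#' `smooth_outliers` is on; such spikes are read-count noise, not
#' copy-number structure, and would otherwise seed one-bin segments.
#'
#' @param profile a normalized [binned_profile()].
#' @param merge_tol merge tolerance in ratio units (> 0), default 0.3.
#' @param values optional per-bin values to segment instead of
#'   `profile$ratio` (e.g. noiseless expected ratios).
#' @param smooth_outliers smooth isolated single-bin spikes first
#'   (default TRUE).
#' @return object of class `segment_profile`: a segment table (chrom,
#'   start_bin, end_bin, start, end, n_bins, ratio) plus sample
#'   metadata; `purity`, `ploidy` and the `cn` column are filled by
#'   [call_absolute_cn()].
#' @export
segment_profile <- function(profile, merge_tol = 0.3, values = NULL,
                            smooth_outliers = TRUE) {
  if (!is.numeric(merge_tol) || merge_tol <= 0)
    stop("merge_tol must be positive")
  x <- if (!is.null(values)) values else profile$ratio
  if (is.null(x)) stop("profile not normalized; run normalize_counts() first")
  grid <- profile$grid
  seg_list <- lapply(grid$chroms, function(chrom) {
    rows <- chrom_bin_rows(grid, chrom)
    v <- x[rows]
    n <- length(v)
    if (smooth_outliers && n >= 3 && is.finite(merge_tol)) {
      i <- 2:(n - 1)
      spike <- abs(v[i] - v[i - 1]) > merge_tol &
        abs(v[i] - v[i + 1]) > merge_tol &
        abs(v[i - 1] - v[i + 1]) <= merge_tol
      v[i][spike] <- ((v[i - 1] + v[i + 1]) / 2)[spike]
      if (abs(v[1] - v[2]) > merge_tol && abs(v[2] - v[3]) <= merge_tol)
        v[1] <- v[2]
      if (abs(v[n] - v[n - 1]) > merge_tol &&
          abs(v[n - 1] - v[n - 2]) <= merge_tol)
        v[n] <- v[n - 1]
    }
    starts <- integer(0); means <- numeric(0); lens <- integer(0)
    cur_start <- 1L; cur_sum <- v[1]; cur_n <- 1L
    if (n > 1) for (i in 2:n) {
      if (abs(v[i] - cur_sum / cur_n) <= merge_tol) {
        cur_sum <- cur_sum + v[i]; cur_n <- cur_n + 1L
      } else {
        starts <- c(starts, cur_start); means <- c(means, cur_sum / cur_n)
        lens <- c(lens, cur_n)
        cur_start <- i; cur_sum <- v[i]; cur_n <- 1L
      }
    }
    starts <- c(starts, cur_start); means <- c(means, cur_sum / cur_n)
    lens <- c(lens, cur_n)
    ## iterated adjacent merge so neighbours always differ by > merge_tol
    repeat {
      if (length(means) < 2) break
      gap <- abs(diff(means))
      j <- which(gap <= merge_tol)
      if (length(j) == 0) break
      j <- j[1]
      means[j] <- (means[j] * lens[j] + means[j + 1] * lens[j + 1]) /
        (lens[j] + lens[j + 1])
      lens[j] <- lens[j] + lens[j + 1]
      means <- means[-(j + 1)]; lens <- lens[-(j + 1)]
      starts <- starts[-(j + 1)]
    }
    data.frame(chrom = chrom,
               start_bin = starts - 1L,
               end_bin = starts - 1L + lens,
               ratio = means,
               n_bins = lens,
               stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, seg_list)
  seg$start <- seg$start_bin * grid$bin_width
  seg$end <- seg$end_bin * grid$bin_width
  structure(list(sample_id = profile$sample_id, grid = grid,
                 segments = seg[, c("chrom", "start_bin", "end_bin",
                                    "start", "end", "n_bins", "ratio")],
                 purity = NA_real_, ploidy = NA_real_),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat("segment_profile:", x$sample_id, "-", nrow(x$segments), "segments",
      if (!is.na(x$purity)) sprintf("(purity %.2f, ploidy %.2f)",
                                    x$purity, x$ploidy) else "", "\n")
  invisible(x)
}

#' Convert segment ratios to absolute copy number
#'
#' Per segment, `CN = (r * D - c_n (1 - rho)) / rho` with
#' `D = rho * psi_t + 2 (1 - rho)` and `c_n` = 2 on autosomes, 1 on the
#' male chrX.  Negative values are clipped to 0 with a warning.
#'
#' @param seg a `segment_profile`.
#' @param rho tumor purity in (0, 1].
#' @param psi_t tumor ploidy (mean autosomal tumor copies).
#' @return the `segment_profile` with a `cn` column and purity/ploidy
#'   recorded.
#' @export
call_absolute_cn <- function(seg, rho, psi_t) {
  if (!is.numeric(rho) || rho <= 0 || rho > 1)
    stop("rho must be in (0, 1]")
  if (psi_t <= 0) stop("psi_t must be positive")
  D <- rho * psi_t + 2 * (1 - rho)
  c_n <- ifelse(is_chrx(seg$segments$chrom), 1, 2)
  cn <- (seg$segments$ratio * D - c_n * (1 - rho)) / rho
  if (any(cn < 0)) {
    warning(sum(cn < 0), " segment(s) with negative CN clipped to 0")
    cn <- pmax(cn, 0)
  }
  seg$segments$cn <- cn
  seg$purity <- rho
  seg$ploidy <- psi_t
  seg
}

## length-weighted median; averages the two central values when the
## cumulative weight crosses exactly one half
weighted_median <- function(x, w) {
  o <- order(x); x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1]) / 2 else x[i]
}

#' AR copy number from a segmented profile
#'
#' The overlap-length-weighted median absolute copy number of the
#' segment(s) covering the AR interval.
#'
#' @param seg a `segment_profile` with absolute CN called.
#' @param ar_interval data.frame (chrom, start, end) on chrX, e.g.
#'   `default_genome()$ar_interval`.
#' @return numeric AR copy number.
#' @export
ar_copy_number <- function(seg, ar_interval) {
  if (is.null(seg$segments$cn)) stop("call_absolute_cn() first")
  s <- seg$segments
  ov <- pmin(s$end, ar_interval$end) - pmax(s$start, ar_interval$start)
  hit <- s$chrom == ar_interval$chrom & ov > 0
  if (!any(hit)) stop("AR interval not covered by any segment (off grid?)")
  weighted_median(s$cn[hit], ov[hit])
}

#' AR gain classification
#'
#' AR is called gained iff its copy number is >= 2 *and* the gain does
#' not extend over 80% or more of Xq (broad whole-arm gains are not
#' counted as AR-targeted events).
#'
#' @param ar_cn AR copy number.
#' @param gained_fraction_of_Xq fraction of Xq bins with CN >= 2.
#' @return logical.
#' @export
classify_ar_gain <- function(ar_cn, gained_fraction_of_Xq) {
  stopifnot(is.finite(ar_cn), is.finite(gained_fraction_of_Xq))
  ar_cn >= 2 && gained_fraction_of_Xq < 0.80
}

#' Fraction of Xq gained in a sample
#'
#' Helper for [classify_ar_gain()]: the fraction of Xq bins whose
#' absolute copy number is >= `threshold`.
#'
#' @param seg a `segment_profile` with CN called.
#' @param genome genome model (provides the Xq bin set).
#' @param threshold gain threshold (total copies), default 2.
#' @return fraction in `[0, 1]`.
#' @export
xq_gained_fraction <- function(seg, genome, threshold = 2) {
  cn_bins <- segment_cn_per_bin(seg)
  rows <- min(chrom_bin_rows(seg$grid, "chrX")) + genome$xq_bins
  mean(cn_bins[rows] >= threshold)
}

## expand segment CN back to per-bin values
segment_cn_per_bin <- function(seg, column = "cn") {
  s <- seg$segments
  if (is.null(s[[column]])) stop("column ", column, " missing")
  out <- numeric(seg$grid$n_bins)
  for (i in seq_len(nrow(s))) {
    rows0 <- min(chrom_bin_rows(seg$grid, s$chrom[i]))
    out[rows0 + seq.int(s$start_bin[i], s$end_bin[i] - 1L)] <- s[[column]][i]
  }
  out
}

#' Per-bin gain proportion across samples
#'
#' For each chrX bin (or each bin of `chrom_subset`), the fraction of
#' samples whose absolute copy number at that bin is >= `threshold` —
#' the per-bin "skyline" of gains.
#'
#' @param profiles list of `segment_profile`s with CN called.
#' @param threshold gain threshold in total copies (default 2).
#' @param chrom_subset chromosomes to report (default chrX).
#' @return data.frame (chrom, start, end, gain_proportion).
#' @export
bin_gain_proportion <- function(profiles, threshold = 2,
                                chrom_subset = "chrX") {
  if (length(profiles) == 0) stop("need >= 1 profile")
  grid <- profiles[[1]]$grid
  eps <- sqrt(.Machine$double.eps)   # guard: CN is continuous, threshold integer
  gained <- vapply(profiles, function(p)
    segment_cn_per_bin(p) >= threshold - eps, logical(grid$n_bins))
  keep <- grid$bins$chrom %in% chrom_subset
  data.frame(chrom = grid$bins$chrom[keep],
             start = grid$bins$start[keep],
             end = grid$bins$end[keep],
             gain_proportion = rowMeans(gained)[keep],
             stringsAsFactors = FALSE)
}

#' Retain samples with adequate tumor fraction
#'
#' Samples below `min_tf` carry too little tumor signal for reliable
#' copy-number fingerprinting and are excluded; the boundary is
#' inclusive (a purity of exactly `min_tf` is retained).
#'
#' @param samples data.frame with a `purity` column.
#' @param min_tf minimum tumor fraction (default 0.2).
#' @return the retained rows.
#' @export
filter_by_tumor_fraction <- function(samples, min_tf = 0.2) {
  if (nrow(samples) == 0) return(samples)
  if (is.null(samples$purity) || anyNA(samples$purity))
    stop("every sample needs a purity estimate")
  samples[samples$purity >= min_tf, , drop = FALSE]
}
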
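#' Fixed-width genomic bin grid
#'
#' A bin grid tiles each chromosome of a (miniature or real) genome with
#' non-overlapping, half-open, 0-based bins of constant width.  All
#' binned profiles, segmentations and transition points in this package
#' live on such a grid, so boundary positions can be compared exactly
#' across samples without fuzzy matching.
#'
#' @param chrom_bins named integer vector: bins per chromosome, in
#'   genome order.  Names are chromosome names; chromosomes named
#'   `"chrX"`/`"X"` are treated as the male X (normal copy number 1).
#' @param bin_width bin width in bp (default 500 kb).
#' @return an object of class `bin_grid` with per-bin chromosome, start
#'   and end coordinates.
#' @examples
#' g <- bin_grid(c(chr1 = 10, chrX = 5))
#' g$n_bins
#' @export
bin_grid <- function(chrom_bins, bin_width = 5e5) {
  if (is.null(names(chrom_bins)) || any(!nzchar(names(chrom_bins))))
    stop("chrom_bins must be a named vector")
  nm <- names(chrom_bins)
  chrom_bins <- as.integer(chrom_bins)
  names(chrom_bins) <- nm
  if (any(chrom_bins < 1)) stop("each chromosome needs >= 1 bin")
  if (bin_width <= 0) stop("bin_width must be positive")
  chrom <- rep(names(chrom_bins), chrom_bins)
  idx_in_chrom <- unlist(lapply(chrom_bins, function(n) seq_len(n) - 1L),
                         use.names = FALSE)
  bins <- data.frame(
    chrom = chrom,
    start = idx_in_chrom * bin_width,
    end   = (idx_in_chrom + 1L) * bin_width,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      chroms     = names(chrom_bins),
      chrom_bins = chrom_bins,
      bin_width  = bin_width,
      bins       = bins,
      n_bins     = nrow(bins)
    ),
    class = "bin_grid"
  )
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("bin_grid:", length(x$chroms), "chromosomes,", x$n_bins, "bins of",
      x$bin_width, "bp\n")
  invisible(x)
}

is_chrx <- function(chrom) chrom %in% c("chrX", "X")

#' Per-bin normal (germline) copy number for a male genome
#'
#' Autosomal bins have two copies; chrX bins one (the cohort is male).
#'
#' @param grid a [bin_grid()].
#' @return integer vector, one entry per bin.
#' @export
normal_copy <- function(grid) {
  ifelse(is_chrx(grid$bins$chrom), 1L, 2L)
}

#' Default miniature male genome model
#'
#' A desk-scale genome preserving the autosome/chrX asymmetry that the
#' purity and AR analyses rely on: four autosomes of 200 bins each plus
#' a 120-bin chrX at 500 kb per bin.  A designated AR bin and its
#' centromeric enhancer bin sit on Xq (the distal half of chrX here, a
#' stand-in for the q arm), mirroring the real AR locus.
#'
#' @param n_autosomes number of autosomes.
#' @param autosome_bins bins per autosome.
#' @param x_bins bins on chrX.
#' @param bin_width bin width in bp.
#' @return list with elements `grid` (a [bin_grid()]), `ar_bin` and
#'   `enhancer_bin` (0-based bin indices within chrX), `xq_bins`
#'   (0-based chrX bin indices forming the "Xq" arm), and `ar_interval`
#'   (chrom/start/end of the AR bin in bp).
#' @export
default_genome <- function(n_autosomes = 4, autosome_bins = 200,
                           x_bins = 120, bin_width = 5e5) {
  stopifnot(n_autosomes >= 1, autosome_bins >= 2, x_bins >= 10)
  cb <- c(rep(autosome_bins, n_autosomes), x_bins)
  names(cb) <- c(paste0("chr", seq_len(n_autosomes)), "chrX")
  grid <- bin_grid(cb, bin_width)
  xq_start <- as.integer(floor(x_bins / 2))
  ar_bin <- as.integer(xq_start + floor((x_bins - xq_start) / 3))
  enhancer_bin <- ar_bin - 2L  # centromeric to AR
  list(
    grid = grid,
    ar_bin = ar_bin,
    enhancer_bin = enhancer_bin,
    xq_bins = seq.int(xq_start, x_bins - 1L),
    ar_interval = data.frame(
      chrom = "chrX",
      start = ar_bin * bin_width,
      end   = (ar_bin + 1L) * bin_width,
      stringsAsFactors = FALSE
    )
  )
}

## row indices (1-based) of a chromosome's bins within the grid table
chrom_bin_rows <- function(grid, chrom) {
  which(grid$bins$chrom == chrom)
}
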
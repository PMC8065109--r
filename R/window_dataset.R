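#' Default chromosome split
#'
#' The non-sequential split of hg19 autosomes used to assemble training,
#' validation and test sets, chosen so that large and small chromosomes are
#' mixed within each set.
#'
#' @return A list with character vectors `train`, `val` and `test`.
#' @export
chromosome_split <- function() {
  s <- list(
    train = paste0("chr", c(1, 3, 5, 6, 7, 9, 11, 12, 13, 15, 17, 18, 19, 21)),
    val   = paste0("chr", c(2, 8, 10, 22)),
    test  = paste0("chr", c(4, 14, 16, 20))
  )
  stopifnot(length(intersect(s$train, s$val)) == 0,
            length(intersect(s$train, s$test)) == 0,
            length(intersect(s$val, s$test)) == 0)
  s
}

#' hg19 autosome lengths
#'
#' Chromosome sizes (bp) of the hg19/GRCh37 reference autosomes, used for
#' window-count bookkeeping.
#'
#' @return Named numeric vector `chr1` .. `chr22`.
#' @export
hg19_chrom_sizes <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566)
}

#' Diagonal-window counts for a chromosome split
#'
#' Number of diagonal windows per split for given chromosome sizes, window
#' and stride: each chromosome of `N = ceiling(size / resolution)` bins
#' contributes `floor((N - window) / stride) + 1` windows (trailing partial
#' windows are dropped).
#'
#' @param sizes named vector of chromosome lengths in bp.
#' @param split a list like [chromosome_split()].
#' @param window,stride window side and stride in bins.
#' @param resolution bin size in bp.
#' @return Named numeric vector with one count per split.
#' @export
expected_window_counts <- function(sizes = hg19_chrom_sizes(),
                                   split = chromosome_split(),
                                   window = 269, stride = 50,
                                   resolution = 10000) {
  nwin <- function(chroms) {
    n <- ceiling(sizes[chroms] / resolution)
    sum(pmax(0, floor((n - window) / stride) + 1))
  }
  vapply(split, nwin, numeric(1))
}

#' Scale a non-negative matrix to the unit interval
#'
#' Clips entries at the `clip_percentile` quantile of all entries (computed
#' at the chromosome level) and divides by it, so outputs lie in `[0, 1]`
#' and rare extreme counts saturate at 1. An all-zero input maps to an
#' all-zero output.
#'
#' @param matrix non-negative numeric matrix.
#' @param clip_percentile percentile (0-100] used as the clipping value.
#' @return Matrix with entries in `[0, 1]`.
#' @export
scale_unit <- function(matrix, clip_percentile = 99.9) {
  if (any(matrix < 0)) stop("scale_unit expects non-negative entries")
  if (any(!is.finite(matrix))) stop("scale_unit expects finite entries")
  cap <- stats::quantile(matrix, clip_percentile / 100, names = FALSE)
  if (cap == 0) cap <- max(matrix)
  if (cap == 0) return(matrix)
  pmin(matrix / cap, 1)
}

#' Center-crop a square matrix
#'
#' Returns the central `out` x `out` block; the border `(side - out) / 2`
#' must be a whole number of bins.
#'
#' @param matrix square matrix.
#' @param out output side length.
#' @return The cropped matrix.
#' @export
center_crop <- function(matrix, out = 257) {
  side <- nrow(matrix)
  if (ncol(matrix) != side) stop("matrix must be square")
  if (out > side) stop("crop larger than input")
  if ((side - out) %% 2 != 0) stop("side - out must be even")
  b <- (side - out) / 2
  matrix[b + seq_len(out), b + seq_len(out), drop = FALSE]
}

#' Extract paired diagonal windows from two contact maps
#'
#' Slides a `window` x `window` square down the diagonal of a paired
#' low/high-resolution chromosome with the given stride. Start bins are
#' `0, stride, 2*stride, ...` with `start + window <= N`; trailing partial
#' windows are dropped. With the default window 269 and stride 50,
#' consecutive windows overlap by 219 bins, so every contact within 2 Mb of
#' the diagonal (at 10 kb bins) is covered by at least one window.
#'
#' Both maps are scaled to `[0, 1]` chromosome-wide with [scale_unit()]
#' before windowing (disable with `scale = FALSE` if inputs are already
#' unit-scaled).
#'
#' @param low,high [contact_map]s of identical dimension and resolution.
#' @param window window side in bins.
#' @param stride diagonal stride in bins.
#' @param scale scale chromosome maps to `[0, 1]` first?
#' @param clip_percentile passed to [scale_unit()].
#' @return A list of `window_sample` objects, ordered by `start_bin`; each
#'   has fields `chrom`, `start_bin` (0-based), `low` and `high`.
#' @export
extract_diagonal_windows <- function(low, high, window = 269, stride = 50,
                                     scale = TRUE, clip_percentile = 99.9) {
  if (!inherits(low, "contact_map") || !inherits(high, "contact_map"))
    stop("low and high must be contact_map objects")
  n <- nrow(low$matrix)
  if (nrow(high$matrix) != n) stop("low and high must have identical dimension")
  if (low$resolution != high$resolution) stop("resolution mismatch")
  if (n < window) stop("chromosome shorter than window")
  ml <- low$matrix
  mh <- high$matrix
  if (scale) {
    ml <- scale_unit(ml, clip_percentile)
    mh <- scale_unit(mh, clip_percentile)
  }
  starts <- seq(0, n - window, by = stride)
  lapply(starts, function(s) {
    idx <- s + seq_len(window)
    structure(list(chrom = low$chrom, start_bin = as.integer(s),
                   low = ml[idx, idx], high = mh[idx, idx]),
              class = "window_sample")
  })
}

#' @export
print.window_sample <- function(x, ...) {
  cat(sprintf("window_sample: %s @ bin %d, %dx%d, low/high in [%.3f, %.3f]\n",
              x$chrom, x$start_bin, nrow(x$low), ncol(x$low),
              min(x$low, x$high), max(x$low, x$high)))
  invisible(x)
}

#' Build a windowed training dataset from paired chromosome maps
#'
#' Convenience wrapper: extracts diagonal windows per chromosome and groups
#' them by split. Chromosome labels absent from `split` are ignored.
#'
#' @param lows,highs named lists of [contact_map]s keyed by chromosome.
#' @param split list with `train`/`val`/`test` chromosome vectors.
#' @param window,stride,scale passed to [extract_diagonal_windows()].
#' @return A list with `train`, `val`, `test` lists of window samples.
#' @export
build_window_dataset <- function(lows, highs, split = chromosome_split(),
                                 window = 269, stride = 50, scale = TRUE) {
  grab <- function(chroms) {
    out <- list()
    for (ch in chroms) {
      if (is.null(lows[[ch]])) next
      out <- c(out, extract_diagonal_windows(lows[[ch]], highs[[ch]],
                                             window, stride, scale))
    }
    out
  }
  lapply(split, grab)
}

#' @rdname build_window_dataset
#' @param dataset a dataset list produced by [build_window_dataset()].
#' @param path file path for the serialized dataset.
#' @export
write_window_dataset <- function(dataset, path) {
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname build_window_dataset
#' @export
read_window_dataset <- function(path) readRDS(path)
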
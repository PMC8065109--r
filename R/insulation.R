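#' Insulation-score parameters
#'
#' Parameters of the insulation-score TAD procedure: the side of the square
#' sliding window (20 bins = 200 kb at 10 kb resolution), the half-width of
#' the delta pseudo-derivative (10 bins = 100 kb), and the minimum boundary
#' strength.
#'
#' @param window_bins even integer >= 2; side of the insulation square.
#' @param delta_bins integer >= 1; bins averaged up/downstream for the delta.
#' @param strength_threshold minimum boundary strength (>= 0).
#' @return An object of class `insulation_params`.
#' @export
insulation_params <- function(window_bins = 20, delta_bins = 10,
                              strength_threshold = 0.1) {
  if (window_bins < 2 || window_bins %% 2 != 0)
    stop("window_bins must be an even integer >= 2")
  if (delta_bins < 1) stop("delta_bins must be >= 1")
  if (strength_threshold < 0) stop("strength_threshold must be >= 0")
  structure(list(window_bins = as.integer(window_bins),
                 delta_bins = as.integer(delta_bins),
                 strength_threshold = strength_threshold),
            class = "insulation_params")
}

# summed-area table: block sums of all w x w diagonal squares.
# raw[j] = sum(M[j:(j+w-1), j:(j+w-1)]), j = 1 .. N-w+1 reduced below.
.diag_block_sums <- function(m, w) {
  n <- nrow(m)
  s <- matrix(0, n + 1, n + 1)
  s[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum)) # s[i+1,j+1] = sum m[1:i,1:j]
  j <- seq_len(n - w)                                # interior placements only
  s[cbind(j + w, j + w)] - s[cbind(j, j + w)] - s[cbind(j + w, j)] + s[cbind(j, j)]
}

#' Insulation vector of a contact map
#'
#' Slides a `window_bins` x `window_bins` square along the diagonal and sums
#' the signal it covers; the raw score of bin `i` uses the square spanning
#' bins `[i - w/2, i + w/2)` on both axes, so only bins where the square
#' fits contribute, giving a vector of length `N - window_bins`. Scores are
#' normalized as `log2(raw / mean(raw))`, which makes the vector invariant
#' to rescaling the whole map.
#'
#' @param matrix square contact matrix (dense, non-negative).
#' @param params an [insulation_params].
#' @return Numeric vector of normalized insulation scores.
#' @export
insulation_vector <- function(matrix, params = insulation_params()) {
  n <- nrow(matrix)
  w <- params$window_bins
  if (n < w + 2 * params$delta_bins)
    stop("axis shorter than insulation support")
  raw <- .diag_block_sums(matrix, w)
  log2(raw / mean(raw))
}

#' Delta (pseudo-derivative) of an insulation vector
#'
#' `delta[i]` contrasts the mean insulation over the `delta_bins` bins
#' downstream of `i` with the mean over the `delta_bins` bins ending at `i`
#' (the trailing window includes `i` itself). Composed with
#' [insulation_vector()], the output length obeys
#' `N - window_bins - (2 * delta_bins - 1)`.
#'
#' @param insulation numeric insulation vector.
#' @param params an [insulation_params].
#' @return Numeric delta vector; negative-to-positive zero crossings mark
#'   insulation valleys.
#' @export
delta_vector <- function(insulation, params = insulation_params()) {
  d <- params$delta_bins
  len <- length(insulation)
  if (len <= 2 * d - 1) stop("insulation vector shorter than delta support")
  cs <- c(0, cumsum(insulation))
  j <- seq.int(d, len - d)                      # centers (1-based)
  down <- (cs[j + d + 1] - cs[j + 1]) / d       # mean over (j+1) .. (j+d)
  up <- (cs[j + 1] - cs[j - d + 1]) / d         # mean over (j-d+1) .. j
  down - up
}

# first index (scanning in `dir`) that is a local extremum; series ends count
.scan_extremum <- function(x, from, dir, what = c("max", "min")) {
  what <- match.arg(what)
  n <- length(x)
  cmp <- if (what == "max") `>=` else `<=`
  i <- from
  repeat {
    lo <- if (i > 1) x[i - 1] else x[i]
    hi <- if (i < n) x[i + 1] else x[i]
    if (cmp(x[i], lo) && cmp(x[i], hi)) return(i)
    i <- i + dir
    if (i < 1) return(1L)
    if (i > n) return(n)
  }
}

#' Call TAD boundaries from a delta vector
#'
#' Boundaries sit where the delta vector crosses zero from negative to
#' positive (an insulation valley); the interpolated crossing is assigned to
#' the nearer bin. The strength of a boundary is the amplitude of the delta
#' swing through the crossing: the nearest local maximum to the right minus
#' the nearest local minimum to the left (series ends count as extrema).
#' Boundaries are kept iff strength exceeds `strength_threshold`.
#'
#' @param delta numeric delta vector (finite).
#' @param params an [insulation_params].
#' @param offset index (0-based map bin) of the first delta element; when
#'   the delta comes from the composed pipeline this is
#'   `delta_bins + window_bins / 2 - 1`, and the returned `bin` column then
#'   refers to matrix bins. Default 0 reports positions within the vector.
#' @return A data.frame with columns `bin` (0-based) and `strength`, sorted
#'   by `bin`; zero rows when no boundary passes.
#' @export
call_boundaries <- function(delta, params = insulation_params(), offset = 0) {
  if (any(!is.finite(delta))) stop("delta must be finite")
  n <- length(delta)
  bins <- integer(0); strengths <- numeric(0)
  if (n >= 2) {
    for (k in which(delta[-n] < 0 & delta[-1] >= 0)) {
      t <- -delta[k] / (delta[k + 1] - delta[k])
      pos <- if (t < 0.5) k else k + 1L
      lmin <- .scan_extremum(delta, pos, -1L, "min")
      rmax <- .scan_extremum(delta, min(pos + 1L, n), +1L, "max")
      s <- delta[rmax] - delta[lmin]
      if (s > params$strength_threshold) {
        bins <- c(bins, pos - 1L)
        strengths <- c(strengths, s)
      }
    }
  }
  out <- data.frame(bin = bins + as.integer(offset), strength = strengths)
  out[order(out$bin), , drop = FALSE]
}

#' Insulation-based TAD boundaries of a contact map
#'
#' Full pipeline: insulation vector, delta vector, boundary calling, with
#' boundary positions mapped back to matrix bins (0-based).
#'
#' @param matrix square contact matrix.
#' @param params an [insulation_params].
#' @return A data.frame of boundaries as in [call_boundaries()].
#' @examples
#' spec <- toy_hic_spec(120, tads = list(c(0, 60, 4), c(60, 120, 4)), noise = FALSE)
#' tad_boundaries(generate_hic(spec)$matrix)
#' @export
tad_boundaries <- function(matrix, params = insulation_params()) {
  delta <- delta_vector(insulation_vector(matrix, params), params)
  off <- params$delta_bins + params$window_bins / 2 - 1
  call_boundaries(delta, params, offset = off)
}

#' Differentiable delta-vector operator
#'
#' The same map-to-delta-vector computation as
#' `delta_vector(insulation_vector(m))`, expressed end-to-end from smooth
#' primitives (sliding block sums, log2 with an additive guard
#' `eps = 1e-8`, mean differences) so that the gradient with respect to
#' every matrix entry is defined — the operator used inside the insulation
#' training loss.
#'
#' @param matrix square contact matrix.
#' @param params an [insulation_params].
#' @param eps additive guard inside the logarithm.
#' @return Numeric delta vector, equal to the plain pipeline within 1e-5 on
#'   positive maps.
#' @export
differentiable_delta <- function(matrix, params = insulation_params(),
                                 eps = 1e-8) {
  n <- nrow(matrix)
  w <- params$window_bins
  if (n < w + 2 * params$delta_bins)
    stop("axis shorter than insulation support")
  raw <- .diag_block_sums(matrix, w)
  norm <- log2((raw + eps) / (mean(raw) + eps))
  delta_vector(norm, params)
}

# gradient of sum(gdelta * differentiable_delta(m)) with respect to m
.diff_delta_bw <- function(matrix, gdelta, params = insulation_params(),
                           eps = 1e-8) {
  n <- nrow(matrix)
  w <- params$window_bins
  d <- params$delta_bins
  raw <- .diag_block_sums(matrix, w)
  len <- length(raw)
  # delta -> norm
  gnorm <- numeric(len)
  centers <- seq.int(d, len - d)
  for (q in seq_along(centers)) {
    j <- centers[q]
    g <- gdelta[q] / d
    gnorm[(j + 1):(j + d)] <- gnorm[(j + 1):(j + d)] + g
    gnorm[(j - d + 1):j] <- gnorm[(j - d + 1):j] - g
  }
  # norm -> raw: norm_i = (log(raw_i + eps) - log(mean(raw) + eps)) / log(2)
  graw <- (gnorm / (raw + eps) - sum(gnorm) / len / (mean(raw) + eps)) / log(2)
  # raw -> matrix: raw_j covers block [j, j+w-1]^2
  gm <- matrix(0, n, n)
  for (j in seq_len(len)) {
    idx <- j:(j + w - 1)
    gm[idx, idx] <- gm[idx, idx] + graw[j]
  }
  gm
}

#' Insulation loss between an enhanced and a target map
#'
#' Mean absolute difference between the differentiable delta vectors of the
#' two maps; zero iff the vectors are equal. This is the topology-aware term
#' of the composite training objective.
#'
#' @param enhanced,target square matrices of identical dimension.
#' @param params an [insulation_params].
#' @return Non-negative scalar.
#' @export
insulation_loss <- function(enhanced, target, params = insulation_params()) {
  if (!all(dim(enhanced) == dim(target))) stop("shape mismatch")
  de <- differentiable_delta(enhanced, params)
  dt <- differentiable_delta(target, params)
  mean(abs(de - dt))
}

# gradient of insulation_loss with respect to `enhanced`
.insulation_loss_bw <- function(enhanced, target, params = insulation_params()) {
  de <- differentiable_delta(enhanced, params)
  dt <- differentiable_delta(target, params)
  gdelta <- sign(de - dt) / length(de)
  .diff_delta_bw(enhanced, gdelta, params)
}

#' L2 distance between delta vectors of two maps
#'
#' Euclidean norm of the difference between the (plain pipeline) delta
#' insulation vectors of two maps — the dissimilarity used to score how well
#' an enhanced map retrieves TAD structure. Symmetric in its arguments.
#'
#' @param map_a,map_b square matrices of identical dimension.
#' @param params an [insulation_params].
#' @return Non-negative scalar; 0 for identical maps.
#' @export
delta_l2 <- function(map_a, map_b, params = insulation_params()) {
  if (!all(dim(map_a) == dim(map_b))) stop("shape mismatch")
  da <- delta_vector(insulation_vector(map_a, params), params)
  db <- delta_vector(insulation_vector(map_b, params), params)
  sqrt(sum((da - db)^2))
}

#' Export TAD boundaries as BED
#'
#' One record per boundary: 0-based half-open bin interval, boundary name,
#' and the strength in the score column.
#'
#' @param boundaries data.frame from [tad_boundaries()].
#' @param path output file.
#' @param chrom chromosome label.
#' @param resolution bin size in bp.
#' @return `path`, invisibly.
#' @export
write_boundaries_bed <- function(boundaries, path, chrom = "chr1",
                                 resolution = 10000) {
  df <- data.frame(
    chrom = chrom,
    start = boundaries$bin * resolution,
    end = (boundaries$bin + 1) * resolution,
    name = sprintf("boundary_%d", seq_len(nrow(boundaries))),
    score = boundaries$strength
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
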
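#' Standard evaluation metrics for map pairs
#'
#' Five image-analysis metrics used to score an enhanced map `x` against a
#' reference map `y`: Pearson correlation (PCC), Spearman correlation (SPC),
#' per-bin mean squared error (MSE), signal-to-noise ratio (SNR), and the
#' structural similarity index (SSIM).
#'
#' @name metrics
NULL

#' @rdname metrics
#' @param x,y numeric matrices (or vectors) of identical shape.
#' @return `pcc`/`spc`: correlation in `[-1, 1]`; constant input is an error.
#' @export
pcc <- function(x, y) {
  if (!all(dim(x) == dim(y))) stop("shape mismatch")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  stats::cor(as.vector(x), as.vector(y))
}

#' @rdname metrics
#' @export
spc <- function(x, y) {
  if (!all(dim(x) == dim(y))) stop("shape mismatch")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  stats::cor(as.vector(x), as.vector(y), method = "spearman")
}

#' @rdname metrics
#' @return `mse_metric`: mean of squared entry differences (>= 0).
#' @export
mse_metric <- function(x, y) {
  if (!all(dim(x) == dim(y))) stop("shape mismatch")
  mean((x - y)^2)
}

#' @rdname metrics
#' @return `snr`: `sum(y) / sqrt(sum((x - y)^2))`; `Inf` when `x == y`.
#' @export
snr <- function(x, y) {
  if (!all(dim(x) == dim(y))) stop("shape mismatch")
  denom <- sqrt(sum((x - y)^2))
  if (denom == 0) return(Inf)
  sum(y) / denom
}

# gaussian weighting window, normalized to sum 1
.gauss_window <- function(win, sigma) {
  r <- (win - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' @rdname metrics
#' @param win side of the sliding sub-window (SSIM).
#' @param sigma standard deviation of the Gaussian weighting.
#' @param data_range dynamic range `L` of the inputs; stabilizers are
#'   `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`.
#' @return `ssi`: mean structural similarity over all fully covered window
#'   placements, in `[-1, 1]`; 1 iff the maps are identical.
#' @export
ssi <- function(x, y, win = 11, sigma = 3, data_range = 1) {
  if (!all(dim(x) == dim(y))) stop("shape mismatch")
  if (nrow(x) < win || ncol(x) < win) stop("map smaller than SSIM window")
  k <- .gauss_window(win, sigma)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  conv <- function(m) {
    a <- array(m, c(nrow(m), ncol(m), 1, 1))
    kk <- array(k, c(win, win, 1, 1))
    drop(.conv2d_fw(a, kk, 0, 1L, 0L))
  }
  mx <- conv(x); my <- conv(y)
  sxx <- conv(x * x) - mx * mx
  syy <- conv(y * y) - my * my
  sxy <- conv(x * y) - mx * my
  smap <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx * mx + my * my + c1) * (sxx + syy + c2))
  mean(smap)
}

#' @rdname metrics
#' @return `map_metrics`: a one-row data.frame with all five metrics.
#' @export
map_metrics <- function(x, y, win = 11, sigma = 3) {
  data.frame(pcc = pcc(x, y), spc = spc(x, y), mse = mse_metric(x, y),
             snr = snr(x, y), ssi = ssi(x, y, win, sigma))
}
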
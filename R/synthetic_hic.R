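#' Specification for a synthetic Hi-C contact map
#'
#' Describes a toy intra-chromosomal map with the structural features the
#' enhancement losses are sensitive to: power-law distance decay, enriched
#' TAD blocks on the diagonal, corner loops, architectural stripes, and
#' Poisson count noise. The expected contact between bins `i` and `j` is
#'
#'   `lambda_ij = count_scale * (1 + |i - j|)^(-decay_exponent) * enrich_ij + bumps`
#'
#' where `enrich_ij` multiplies pairs lying inside a common TAD interval and
#' `bumps` are additive loop/stripe terms. With `noise = TRUE` counts are
#' drawn `Poisson(lambda_ij)` on the upper triangle and mirrored.
#'
#' @param n_bins number of bins (matrix side).
#' @param decay_exponent power-law decay exponent `alpha > 0`; the field's
#'   canonical intra-chromosomal decay is close to 1.
#' @param tads list of `c(start_bin, end_bin, enrichment)` triplets
#'   (0-based, half-open, enrichment > 1).
#' @param loops list of `c(bin_i, bin_j, strength)` triplets; a loop adds a
#'   small Gaussian bump of height `strength * count_scale` at `(i, j)`.
#' @param stripes list of `c(anchor_bin, extent, strength)` triplets; a
#'   stripe adds decaying signal along `(anchor, anchor + t)`, `t <= extent`.
#' @param count_scale expected count at the diagonal.
#' @param noise draw Poisson counts (`TRUE`) or return the expectation.
#' @param seed RNG seed used by [generate_hic()].
#' @return An object of class `toy_hic_spec`.
#' @export
toy_hic_spec <- function(n_bins, decay_exponent = 1, tads = list(),
                         loops = list(), stripes = list(),
                         count_scale = 300, noise = TRUE, seed = 1) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (decay_exponent <= 0) stop("decay_exponent must be positive")
  for (t in tads) {
    if (length(t) != 3 || t[1] < 0 || t[2] > n_bins || t[2] <= t[1] || t[3] <= 1)
      stop("each TAD must be c(start_bin, end_bin, enrichment>1) within range")
  }
  for (l in loops) {
    if (length(l) != 3 || any(l[1:2] < 0) || any(l[1:2] >= n_bins) || l[3] < 0)
      stop("each loop must be c(bin_i, bin_j, strength>=0) within range")
  }
  for (s in stripes) {
    if (length(s) != 3 || s[1] < 0 || s[1] >= n_bins || s[2] < 1 || s[3] < 0)
      stop("each stripe must be c(anchor_bin, extent, strength>=0) within range")
  }
  structure(list(n_bins = as.integer(n_bins), decay_exponent = decay_exponent,
                 tads = tads, loops = loops, stripes = stripes,
                 count_scale = count_scale, noise = isTRUE(noise),
                 seed = as.integer(seed)),
            class = "toy_hic_spec")
}

#' Generate a synthetic Hi-C contact map
#'
#' Realizes a [toy_hic_spec] as a [contact_map]. Deterministic for a given
#' spec (the spec's `seed` is used for the Poisson draw).
#'
#' @param spec a [toy_hic_spec].
#' @return A [contact_map] with integer counts when `noise = TRUE`, or the
#'   expected (real-valued) map otherwise.
#' @examples
#' cm <- generate_hic(toy_hic_spec(80, tads = list(c(10, 40, 3)), noise = FALSE))
#' @export
generate_hic <- function(spec) {
  if (!inherits(spec, "toy_hic_spec")) stop("spec must be a toy_hic_spec")
  n <- spec$n_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  lam <- spec$count_scale * (1 + d)^(-spec$decay_exponent)
  for (t in spec$tads) {
    idx <- (t[1] + 1):t[2]
    lam[idx, idx] <- lam[idx, idx] * t[3]
  }
  for (l in spec$loops) {
    i0 <- l[1]; j0 <- l[2]
    ii <- pmax(1, pmin(n, i0 + (-1:1) + 1))
    jj <- pmax(1, pmin(n, j0 + (-1:1) + 1))
    for (a in seq_along(ii)) for (b in seq_along(jj)) {
      w <- exp(-((a - 2)^2 + (b - 2)^2) / 2)
      lam[ii[a], jj[b]] <- lam[ii[a], jj[b]] + l[3] * spec$count_scale * w
      lam[jj[b], ii[a]] <- lam[ii[a], jj[b]]
    }
  }
  for (s in spec$stripes) {
    a0 <- s[1] + 1
    ts <- seq_len(min(s[2], n - a0))
    for (t in ts) {
      add <- s[3] * spec$count_scale * (1 + t)^(-spec$decay_exponent / 2)
      lam[a0, a0 + t] <- lam[a0, a0 + t] + add
      lam[a0 + t, a0] <- lam[a0, a0 + t]
    }
  }
  lam <- (lam + t(lam)) / 2
  if (spec$noise) {
    old <- .save_seed()
    on.exit(.restore_seed(old))
    set.seed(spec$seed)
    up <- upper.tri(lam, diag = TRUE)
    m <- lam * 0
    m[up] <- stats::rpois(sum(up), lam[up])
    m <- m + t(m) - diag(diag(m))
  } else {
    m <- lam
  }
  contact_map(m, chrom = "chrS", resolution = 10000)
}

#' Binomially downsample a contact map
#'
#' Emulates a lower-coverage experiment by thinning each count
#' `c -> Binomial(c, keep_fraction)`. The upper triangle (with diagonal) is
#' sampled and mirrored, preserving symmetry. The expected total signal is
#' `keep_fraction` times the original total.
#'
#' @param cm a [contact_map] with (near-)integer counts; values are rounded.
#' @param keep_fraction retention probability in `(0, 1]`; `1/16` emulates
#'   the coverage gap between deep and shallow sequencing runs.
#' @param seed RNG seed.
#' @return A downsampled [contact_map].
#' @export
downsample <- function(cm, keep_fraction, seed = 1) {
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  m <- round(cm$matrix)
  if (keep_fraction == 1)
    return(contact_map(m, cm$chrom, cm$resolution, cm$balanced))
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  up <- upper.tri(m, diag = TRUE)
  out <- m * 0
  out[up] <- stats::rbinom(sum(up), size = as.integer(m[up]), prob = keep_fraction)
  out <- out + t(out) - diag(diag(out))
  contact_map(out, cm$chrom, cm$resolution, cm$balanced)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
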
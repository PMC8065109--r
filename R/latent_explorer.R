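#' Principal component analysis of latent codes
#'
#' Fits a PCA to the posterior means of training windows, giving a
#' low-dimensional, user-tunable parameterization of the generative latent
#' space. Components are orthonormal, ordered by explained variance, and
#' sign-fixed so that each component's largest-magnitude coordinate is
#' positive (sweeps are therefore reproducible).
#'
#' @param latents matrix of latent codes: one `latent_dim`-vector per row,
#'   or the `latent_dim` x n matrix returned by [vae_encode()] (auto-detected
#'   via `latent_dim`).
#' @param latent_dim latent dimensionality (defaults to `ncol(latents)`).
#' @return An object of class `latent_pca`: `rotation` (columns =
#'   components), `center`, `sdev`, `var_ratio`.
#' @export
fit_pca <- function(latents, latent_dim = NULL) {
  if (!is.matrix(latents)) stop("latents must be a matrix")
  if (!is.null(latent_dim) && ncol(latents) != latent_dim &&
      nrow(latents) == latent_dim)
    latents <- t(latents)
  if (nrow(latents) < 2) stop("need at least 2 latent codes")
  p <- stats::prcomp(latents, center = TRUE, scale. = FALSE)
  rot <- p$rotation
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(rotation = rot, center = p$center, sdev = p$sdev,
                 var_ratio = p$sdev^2 / sum(p$sdev^2)),
            class = "latent_pca")
}

#' @export
print.latent_pca <- function(x, ...) {
  cat(sprintf("latent_pca: %d components over %d latent dims\n",
              ncol(x$rotation), nrow(x$rotation)))
  k <- min(5, length(x$var_ratio))
  cat("  leading variance ratios:",
      paste(sprintf("%.3f", x$var_ratio[1:k]), collapse = ", "), "\n")
  invisible(x)
}

#' Project latent codes onto principal components
#'
#' @param pca a [fit_pca()] model.
#' @param latents matrix of codes, one per row.
#' @return Matrix of component scores (one row per code).
#' @export
pca_transform <- function(pca, latents) {
  sweep(latents, 2, pca$center) %*% pca$rotation
}

#' @rdname pca_transform
#' @param scores matrix (or vector) of component scores.
#' @return `pca_inverse`: latent codes, one per row.
#' @export
pca_inverse <- function(pca, scores) {
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1)
  k <- ncol(scores)
  sweep(scores %*% t(pca$rotation[, seq_len(k), drop = FALSE]), 2,
        pca$center, `+`)
}

#' Generate a contact-map window from principal-component values
#'
#' Builds a component-score vector with the user's values at the chosen
#' indices and the dataset average (zero, since scores are centered) at all
#' others, maps it back to latent space through the PCA reverse transform,
#' and decodes it with the trained decoder. Deterministic: the same values
#' always give the same map.
#'
#' @param values named numeric vector or list mapping component index
#'   (1-based, as `"1"`, `"5"`, ...) to a score value; empty means "decode
#'   the dataset-average latent vector".
#' @param pca a [fit_pca()] model.
#' @param vae a trained [hic_vae].
#' @param num_components how many leading components are tunable (indices
#'   beyond this are an error); mirrors the explorer's slider count.
#' @return A window matrix with entries in `(0, 1)`.
#' @examples
#' \dontrun{
#' map <- generate_from_components(c("1" = 2, "3" = -1), pca, vae)
#' }
#' @export
generate_from_components <- function(values = numeric(), pca, vae,
                                     num_components = 15) {
  rank <- ncol(pca$rotation)
  k <- min(num_components, rank)
  scores <- numeric(rank)
  if (length(values)) {
    idx <- as.integer(names(values))
    if (is.null(names(values)) || any(is.na(idx)))
      stop("values must be named by component index")
    if (any(idx < 1 | idx > k))
      stop(sprintf("component index out of range 1..%d", k))
    scores[idx] <- as.numeric(unlist(values))
  }
  z <- drop(pca_inverse(pca, matrix(scores, nrow = 1)))
  vae_decode(vae, z)
}

#' Sweep one principal component and summarize the decoded maps
#'
#' Helper for inspecting what a component controls: decodes maps along a
#' grid of values for one component (others at the dataset mean) and
#' reports a TAD-linked summary, the depth of the deepest insulation
#' valley (minimum of the insulation vector; more negative = stronger
#' boundary).
#'
#' @param component component index.
#' @param grid numeric vector of score values.
#' @param pca,vae as in [generate_from_components()].
#' @param params an [insulation_params()] (window support must fit the
#'   decoded side).
#' @return data.frame with `value` and `valley_depth`.
#' @export
sweep_component <- function(component, grid, pca, vae,
                            params = insulation_params()) {
  depth <- vapply(grid, function(v) {
    vals <- stats::setNames(v, as.character(component))
    m <- generate_from_components(vals, pca, vae,
                                  num_components = max(component, 15))
    min(insulation_vector(m, params))
  }, numeric(1))
  data.frame(value = grid, valley_depth = depth)
}
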
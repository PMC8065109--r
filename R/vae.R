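#' Variational autoencoder configuration
#'
#' Architecture and training hyper-parameters of the Hi-C variational
#' autoencoder. The encoder stacks strided convolutions (kernel 3, stride 2,
#' pad 1), each followed by leaky ReLU and batch normalization, then two
#' parallel affine heads produce the posterior mean and log-variance. The
#' decoder mirrors it with transposed convolutions and ends in a 1x1 output
#' projection with a sigmoid, so reconstructions lie in `(0, 1)` and have
#' exactly the input dimension.
#'
#' With kernel 3 / stride 2 / pad 1 a side `s` maps to `(s + 1) / 2`, so the
#' input side must stay odd at every layer: valid sides are
#' `2^L * m + 1` for `L` layers. The default 257 works for the printed
#' 7-layer channel ladder (257 -> 129 -> 65 -> 33 -> 17 -> 9 -> 5 -> 3).
#'
#' @param input_size window side in bins (default 257, the center crop of a
#'   269-bin window).
#' @param latent_dim latent dimensionality.
#' @param encoder_channels,decoder_channels per-layer filter counts.
#' @param learning_rate Adam step size.
#' @param epochs,batch_size training schedule.
#' @param kl_weight weight of the KL term at the end of annealing.
#' @param kl_anneal_epochs epochs over which the KL weight ramps 0 -> target.
#' @param seed RNG seed controlling initialization and sampling.
#' @return An object of class `vae_config`.
#' @export
vae_config <- function(input_size = 257, latent_dim = 128,
                       encoder_channels = c(32, 64, 128, 256, 256, 512, 512),
                       decoder_channels = c(512, 512, 256, 256, 128, 64, 32),
                       learning_rate = 1e-3, epochs = 40, batch_size = 8,
                       kl_weight = 1, kl_anneal_epochs = ceiling(epochs / 2),
                       seed = 1) {
  if (latent_dim < 2) stop("latent_dim must be >= 2")
  L <- length(encoder_channels)
  if (length(decoder_channels) != L)
    stop("encoder and decoder must have the same number of layers")
  sides <- input_size
  s <- input_size
  for (i in seq_len(L)) {
    if (s %% 2 == 0)
      stop(sprintf("layer %d input side %d is even; side must be 2^L*m + 1", i, s))
    s <- (s + 1) / 2
    sides <- c(sides, s)
  }
  structure(list(input_size = as.integer(input_size),
                 latent_dim = as.integer(latent_dim),
                 encoder_channels = encoder_channels,
                 decoder_channels = decoder_channels,
                 sides = as.integer(sides),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), kl_weight = kl_weight,
                 kl_anneal_epochs = as.integer(kl_anneal_epochs),
                 seed = as.integer(seed)),
            class = "vae_config")
}

# instantiate all layers; RNG must be seeded by the caller
.build_vae <- function(config) {
  ec <- config$encoder_channels
  dc <- config$decoder_channels
  L <- length(ec)
  enc <- list()
  cin <- 1
  for (i in seq_len(L)) {
    enc <- c(enc, list(nn_conv(cin, ec[i], 3L, 2L, 1L),
                       nn_act("lrelu"), nn_bn(ec[i])))
    cin <- ec[i]
  }
  enc <- c(enc, list(nn_flatten()))
  s0 <- config$sides[L + 1]
  flat <- s0 * s0 * ec[L]
  mu_head <- nn_linear(flat, config$latent_dim)
  logvar_head <- nn_linear(flat, config$latent_dim)
  dec <- list(nn_linear(config$latent_dim, s0 * s0 * dc[1]),
              nn_reshape(s0, s0, dc[1]))
  cin <- dc[1]
  for (i in seq_len(L)) {
    dec <- c(dec, list(nn_convt(cin, dc[i], 3L, 2L, 1L),
                       nn_act("lrelu"), nn_bn(dc[i])))
    cin <- dc[i]
  }
  dec <- c(dec, list(nn_conv(cin, 1L, 1L, 1L, 0L), nn_act("sigmoid")))
  list(enc = enc, mu_head = mu_head, logvar_head = logvar_head, dec = dec)
}

.as_batch <- function(x, side) {
  if (is.matrix(x)) x <- list(x)
  if (is.array(x) && length(dim(x)) == 3)
    x <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  if (!is.list(x)) stop("expected a matrix, list of matrices, or 3-d array")
  if (length(x) == 0) stop("empty dataset")
  for (m in x) {
    if (!is.matrix(m) || nrow(m) != side || ncol(m) != side)
      stop(sprintf("expected %dx%d matrices", side, side))
  }
  array(unlist(x), dim = c(side, side, 1, length(x)))
}

.vae_encode_fw <- function(vae, xb, train = FALSE) {
  h <- seq_fw(vae$net$enc, xb, train)
  list(mu = vae$net$mu_head$fw(h, train),
       logvar = vae$net$logvar_head$fw(h, train))
}

#' Encode contact-map windows into the latent space
#'
#' Deterministic forward pass through the trained encoder, returning the
#' posterior mean and log-variance per window.
#'
#' @param vae a trained [hic_vae] model (from [train_vae()]).
#' @param x one matrix, a list of matrices, or a 3-d array of windows with
#'   side `input_size`, values in `[0, 1]`.
#' @return List with matrices `mu` and `logvar` (`latent_dim` x n).
#' @export
vae_encode <- function(vae, x) {
  xb <- .as_batch(x, vae$config$input_size)
  out <- .vae_encode_fw(vae, xb, train = FALSE)
  out
}

#' Decode latent vectors into contact-map windows
#'
#' @param vae a trained [hic_vae] model.
#' @param z latent vector (length `latent_dim`) or matrix (`latent_dim` x n).
#' @return A window matrix for a single code, else a 3-d array
#'   (side x side x n). Entries are strictly inside `(0, 1)`.
#' @export
vae_decode <- function(vae, z) {
  if (is.vector(z)) z <- matrix(z, ncol = 1)
  if (any(!is.finite(z))) stop("latent code must be finite")
  if (nrow(z) != vae$config$latent_dim) stop("latent dimension mismatch")
  y <- seq_fw(vae$net$dec, z, train = FALSE)
  if (dim(y)[4] == 1) y[, , 1, 1] else y[, , 1, ]
}

#' Sample a latent code from the posterior of a window
#'
#' Reparameterized draw `z = mu + exp(logvar / 2) * eps` with recorded seed.
#'
#' @param vae a trained [hic_vae].
#' @param x a window matrix.
#' @param seed RNG seed for the draw.
#' @return List with `mu`, `logvar` and the sample `z`.
#' @export
latent_code <- function(vae, x, seed = 1) {
  enc <- vae_encode(vae, x)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  eps <- stats::rnorm(length(enc$mu))
  z <- enc$mu + exp(enc$logvar / 2) * eps
  list(mu = drop(enc$mu), logvar = drop(enc$logvar), z = drop(z))
}

#' KL divergence between a diagonal Gaussian posterior and the unit prior
#'
#' Closed form `-0.5 * sum(1 + logvar - mu^2 - exp(logvar))`; non-negative,
#' and zero iff `mu = 0`, `logvar = 0`. For matrix input (one code per
#' column) the per-column divergences are averaged.
#'
#' @param mu,logvar numeric vectors, or matrices with one code per column.
#' @return Non-negative scalar.
#' @examples
#' kl_divergence(c(1, 1), c(0, 0)) # == 1
#' @export
kl_divergence <- function(mu, logvar) {
  per <- -0.5 * (1 + logvar - mu^2 - exp(logvar))
  if (is.matrix(mu)) mean(colSums(per)) else sum(per)
}

#' Variational-autoencoder training objective
#'
#' Reconstruction term (per-sample sum of bin-wise squared errors, the
#' tractable surrogate for the decoder log-likelihood) plus
#' `kl_weight` times the KL divergence of the posterior from the unit
#' Gaussian prior; averaged over samples.
#'
#' @param x,x_recon input and reconstruction (matrices or batches of equal
#'   shape).
#' @param mu,logvar posterior parameters.
#' @param kl_weight KL coefficient; 0 reduces to pure reconstruction error.
#' @return Finite scalar.
#' @export
vae_objective <- function(x, x_recon, mu, logvar, kl_weight = 1) {
  if (!all(dim(x) == dim(x_recon))) stop("shape mismatch")
  n <- if (is.matrix(mu)) ncol(mu) else 1
  sum((x - x_recon)^2) / n + kl_weight * kl_divergence(mu, logvar)
}

#' Train the variational autoencoder
#'
#' Trains encoder and decoder on high-resolution windows (used as both input
#' and label) with Adam, reparameterized sampling, and a KL weight annealed
#' linearly from 0 to `kl_weight` over `kl_anneal_epochs`. Fully
#' reproducible for a fixed `config$seed`.
#'
#' @param dataset windows with side `config$input_size`: a list of matrices
#'   or a 3-d array, values in `[0, 1]`.
#' @param config a [vae_config].
#' @param verbose print the per-epoch objective?
#' @return An object of class `hic_vae`: the trained network, the config and
#'   a `history` data.frame (epoch, objective, reconstruction, kl).
#' @export
train_vae <- function(dataset, config = vae_config(), verbose = FALSE) {
  xb_all <- .as_batch(dataset, config$input_size)
  m <- dim(xb_all)[4]
  if (m < 1) stop("empty dataset")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  net <- .build_vae(config)
  vae <- structure(list(net = net, config = config, history = NULL),
                   class = "hic_vae")
  layers <- c(net$enc, list(net$mu_head, net$logvar_head), net$dec)
  step <- 0
  hist <- NULL
  for (epoch in seq_len(config$epochs)) {
    kw <- config$kl_weight *
      min(1, epoch / max(1, config$kl_anneal_epochs))
    perm <- sample.int(m)
    tot <- rec_tot <- kl_tot <- 0
    for (b in split(perm, ceiling(seq_along(perm) / config$batch_size))) {
      nb <- length(b)
      xb <- xb_all[, , , b, drop = FALSE]
      enc <- .vae_encode_fw(vae, xb, train = TRUE)
      mu <- enc$mu; logvar <- pmin(pmax(enc$logvar, -8), 8)
      eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
      sd <- exp(logvar / 2)
      z <- mu + sd * eps
      xr <- seq_fw(net$dec, z, train = TRUE)
      rec <- sum((xb - xr)^2) / nb
      kl <- kl_divergence(mu, logvar)
      tot <- tot + (rec + kw * kl) * nb
      rec_tot <- rec_tot + rec * nb; kl_tot <- kl_tot + kl * nb
      # backward
      gxr <- 2 * (xr - xb) / nb
      gz <- seq_bw(net$dec, gxr)
      gmu <- gz + kw * mu / nb
      glogvar <- gz * eps * sd / 2 + kw * (exp(logvar) - 1) / (2 * nb)
      glogvar[enc$logvar < -8 | enc$logvar > 8] <- 0
      gh <- net$mu_head$bw(gmu) + net$logvar_head$bw(glogvar)
      seq_bw(net$enc, gh)
      step <- step + 1
      adam_step(layers, config$learning_rate, step)
      zero_grads(layers)
    }
    hist <- rbind(hist, data.frame(epoch = epoch, objective = tot / m,
                                   reconstruction = rec_tot / m,
                                   kl = kl_tot / m, kl_weight = kw))
    if (verbose)
      message(sprintf("epoch %d: objective %.4f (rec %.4f, kl %.2f, kw %.3f)",
                      epoch, tot / m, rec_tot / m, kl_tot / m, kw))
  }
  vae$history <- hist
  vae
}

#' @export
print.hic_vae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("hic_vae: %dx%d windows -> %d latent dims\n",
              cfg$input_size, cfg$input_size, cfg$latent_dim))
  cat(sprintf("  encoder channels: %s\n",
              paste(cfg$encoder_channels, collapse = ", ")))
  cat(sprintf("  decoder channels: %s\n",
              paste(cfg$decoder_channels, collapse = ", ")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; final objective %.4f\n",
                nrow(x$history), x$history$objective[nrow(x$history)]))
  invisible(x)
}

#' @export
predict.hic_vae <- function(object, x,
                            type = c("latent", "reconstruction"), ...) {
  type <- match.arg(type)
  enc <- vae_encode(object, x)
  if (type == "latent") return(enc$mu)
  vae_decode(object, enc$mu)
}

#' Variational feature loss between an enhanced and a target window
#'
#' Mean absolute difference between the latent posterior means of the two
#' windows under the trained (frozen) encoder; zero when the windows are
#' identical, and symmetric in its arguments.
#'
#' @param enhanced,target window matrices with the VAE's input side.
#' @param vae a trained [hic_vae].
#' @return Non-negative scalar.
#' @export
variational_loss <- function(enhanced, target, vae) {
  if (!all(dim(enhanced) == dim(target))) stop("shape mismatch")
  mu_e <- vae_encode(vae, enhanced)$mu
  mu_t <- vae_encode(vae, target)$mu
  mean(abs(mu_e - mu_t))
}

# gradient of the batch-mean variational loss with respect to the enhanced
# batch; target batch is a constant
.variational_loss_bw <- function(vae, enhanced_b, target_b) {
  mu_t <- .vae_encode_fw(vae, target_b, train = FALSE)$mu
  enc <- .vae_encode_fw(vae, enhanced_b, train = "frozen")
  nb <- ncol(enc$mu)
  gmu <- sign(enc$mu - mu_t) / (nrow(enc$mu) * nb)
  gh <- vae$net$mu_head$bw(gmu)
  gx <- seq_bw(vae$net$enc, gh)
  loss <- mean(colSums(abs(enc$mu - mu_t)) / nrow(enc$mu))
  zero_grads(c(vae$net$enc, list(vae$net$mu_head)))
  list(loss = loss, gx = gx)
}
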
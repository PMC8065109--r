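#' Loss weights of the composite objective
#'
#' The four lambda coefficients weighting the adversarial, bin-wise MSE,
#' variational-feature and insulation terms of the generator objective.
#'
#' @param lambda_adv,lambda_mse,lambda_vae,lambda_ins non-negative weights;
#'   defaults are the published operating point.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_adv = 0.0025, lambda_mse = 1,
                         lambda_vae = 0.01, lambda_ins = 1) {
  w <- c(adv = lambda_adv, mse = lambda_mse, vae = lambda_vae, ins = lambda_ins)
  if (any(w < 0)) stop("loss weights must be non-negative")
  structure(as.list(w), class = "loss_weights")
}

#' Generator architecture specification
#'
#' A residual super-resolution generator: a valid (unpadded) 3x3 input
#' convolution, `n_res_blocks` residual blocks of two padded 3x3
#' convolutions with batch normalization, a valid post-residual convolution
#' whose output is summed with the (cropped) head features, four valid 3x3
#' convolutions, and a padded 1-channel output convolution with a sigmoid so
#' outputs lie in `[0, 1]`. The six valid convolutions shrink each side by
#' 12 bins in total, so an `N` x `N` input yields an `N - 12` output.
#'
#' @param n_res_blocks number of residual blocks.
#' @param filters convolutional filters per layer.
#' @return An object of class `generator_spec` (field `shrink_bins` = 12).
#' @export
generator_spec <- function(n_res_blocks = 15, filters = 64) {
  if (n_res_blocks < 1 || filters < 1) stop("invalid generator spec")
  structure(list(n_res_blocks = as.integer(n_res_blocks),
                 filters = as.integer(filters),
                 output_activation = "sigmoid", shrink_bins = 12L),
            class = "generator_spec")
}

#' Build the enhancement generator
#'
#' @param spec a [generator_spec].
#' @param seed RNG seed for weight initialization.
#' @return An object of class `hic_generator`.
#' @export
build_generator <- function(spec = generator_spec(), seed = 1) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  f <- spec$filters
  g <- new.env(parent = emptyenv())
  g$spec <- spec
  g$head_conv <- nn_conv(1L, f, 3L, 1L, 0L)
  g$head_act <- nn_act("lrelu")
  g$blocks <- lapply(seq_len(spec$n_res_blocks), function(i) {
    list(c1 = nn_conv(f, f, 3L, 1L, 1L), b1 = nn_bn(f), a1 = nn_act("relu"),
         c2 = nn_conv(f, f, 3L, 1L, 1L), b2 = nn_bn(f))
  })
  g$mid_conv <- nn_conv(f, f, 3L, 1L, 0L)
  g$mid_bn <- nn_bn(f)
  g$tail <- lapply(1:4, function(i)
    list(conv = nn_conv(f, f, 3L, 1L, 0L), act = nn_act("lrelu")))
  g$out_conv <- nn_conv(f, 1L, 3L, 1L, 1L)
  g$out_act <- nn_act("sigmoid")
  class(g) <- "hic_generator"
  g
}

.gen_layers <- function(g) {
  blk <- unlist(lapply(g$blocks, function(b) unname(b)), recursive = FALSE)
  tl <- unlist(lapply(g$tail, function(t) unname(t)), recursive = FALSE)
  c(list(g$head_conv, g$head_act), blk, list(g$mid_conv, g$mid_bn),
    tl, list(g$out_conv, g$out_act))
}

.crop4 <- function(x, border) {
  d <- dim(x)
  x[border + seq_len(d[1] - 2 * border), border + seq_len(d[2] - 2 * border), ,
    , drop = FALSE]
}

.pad4 <- function(x, border, side) {
  d <- dim(x)
  out <- array(0, c(side, side, d[3], d[4]))
  out[border + seq_len(d[1]), border + seq_len(d[2]), , ] <- x
  out
}

.gen_forward <- function(g, x, train = FALSE) {
  if (dim(x)[1] <= g$spec$shrink_bins + 1)
    stop("input smaller than the generator's receptive shrink")
  h0 <- g$head_act$fw(g$head_conv$fw(x, train), train)
  h <- h0
  for (b in g$blocks) {
    r <- b$b2$fw(b$c2$fw(b$a1$fw(b$b1$fw(b$c1$fw(h, train), train), train),
                         train), train)
    h <- h + r
  }
  m <- g$mid_bn$fw(g$mid_conv$fw(h, train), train)
  u <- m + .crop4(h0, 1L)
  for (t in g$tail) u <- t$act$fw(t$conv$fw(u, train), train)
  g$out_act$fw(g$out_conv$fw(u, train), train)
}

.gen_backward <- function(g, gy) {
  gu <- g$out_conv$bw(g$out_act$bw(gy))
  for (t in rev(g$tail)) gu <- t$conv$bw(t$act$bw(gu))
  # global skip: u = mid(h) + crop(h0)
  gh <- g$mid_conv$bw(g$mid_bn$bw(gu))
  gh0_skip <- .pad4(gu, 1L, dim(gh)[1])
  for (b in rev(g$blocks)) {
    gr <- b$c1$bw(b$b1$bw(b$a1$bw(b$c2$bw(b$b2$bw(gh)))))
    gh <- gh + gr
  }
  g$head_conv$bw(g$head_act$bw(gh + gh0_skip))
}

#' Enhance low-resolution windows with a generator
#'
#' Forward pass in inference mode; an `N` x `N` window maps to an
#' `N - 12` x `N - 12` enhanced window with entries in `[0, 1]`.
#'
#' @param gen an [build_generator()] object (or a trained `vehicle_model`'s
#'   `$generator`).
#' @param x a window matrix, list of matrices, or 3-d array, values in
#'   `[0, 1]`.
#' @return One matrix, or a 3-d array for several windows.
#' @export
enhance_windows <- function(gen, x) {
  if (is.matrix(x)) x <- list(x)
  if (is.array(x) && length(dim(x)) == 3)
    x <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  side <- nrow(x[[1]])
  xb <- array(unlist(x), dim = c(side, side, 1, length(x)))
  y <- .gen_forward(gen, xb, train = FALSE)
  if (dim(y)[4] == 1) y[, , 1, 1] else y[, , 1, ]
}

#' Build the discriminator
#'
#' A fully convolutional classifier with ReLU activations and batch
#' normalization: three strided 3x3 convolutions (32, 64, 128 filters), a
#' 1-channel convolution, global average pooling and a sigmoid, giving one
#' probability-like score per map.
#'
#' @param seed RNG seed for weight initialization.
#' @return An object of class `hic_discriminator`.
#' @export
build_discriminator <- function(seed = 1) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  d <- new.env(parent = emptyenv())
  d$layers <- list(
    nn_conv(1L, 32L, 3L, 2L, 1L), nn_act("relu"),
    nn_conv(32L, 64L, 3L, 2L, 1L), nn_bn(64L), nn_act("relu"),
    nn_conv(64L, 128L, 3L, 2L, 1L), nn_bn(128L), nn_act("relu"),
    nn_conv(128L, 1L, 3L, 1L, 1L)
  )
  class(d) <- "hic_discriminator"
  d
}

.disc_forward <- function(d, x, train = FALSE) {
  h <- seq_fw(d$layers, x, train)
  d$hdim <- dim(h)
  s <- apply(h, 4, mean)
  score <- 1 / (1 + exp(-s))
  if (!isFALSE(train)) d$score <- score
  score
}

.disc_backward <- function(d, gscore) {
  gs <- gscore * d$score * (1 - d$score)
  hd <- d$hdim
  gh <- array(rep(gs, each = prod(hd[1:3])) / prod(hd[1:2]), dim = hd)
  seq_bw(d$layers, gh)
}

#' Discriminator scores for a batch of maps
#'
#' @param disc an [build_discriminator()] object.
#' @param x matrix, list of matrices, or 3-d array.
#' @return Numeric vector of scores in `(0, 1)`.
#' @export
discriminator_scores <- function(disc, x) {
  if (is.matrix(x)) x <- list(x)
  if (is.array(x) && length(dim(x)) == 3)
    x <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  side <- nrow(x[[1]])
  xb <- array(unlist(x), dim = c(side, side, 1, length(x)))
  .disc_forward(disc, xb, train = FALSE)
}

#' GAN loss functions
#'
#' `adversarial_loss` is the generator's non-saturating objective
#' `sum(-log D(G(x)))` over a batch of discriminator scores;
#' `discriminator_loss` is the binary cross-entropy
#' `-mean(log D(real)) - mean(log(1 - D(fake)))`. Logs are guarded by
#' `eps = 1e-12`.
#'
#' @param scores,real_scores,fake_scores discriminator outputs in `(0, 1)`.
#' @param eps log guard.
#' @return Scalar loss.
#' @examples
#' adversarial_loss(0.5) # -log(0.5) = 0.693...
#' @export
adversarial_loss <- function(scores, eps = 1e-12) {
  sum(-log(scores + eps))
}

#' @rdname adversarial_loss
#' @export
discriminator_loss <- function(real_scores, fake_scores, eps = 1e-12) {
  -mean(log(real_scores + eps)) - mean(log(1 - fake_scores + eps))
}

#' Bin-wise mean squared error loss
#'
#' `sum((enhanced - target)^2) / n^2` for `n` x `n` maps (squared form); the
#' absolute-value reading `sum(|diff|) / n^2` is available via `form`.
#'
#' @param enhanced,target matrices of identical shape.
#' @param form `"squared"` (default) or `"absolute"`.
#' @return Non-negative scalar; 0 iff the maps are equal.
#' @export
mse_loss <- function(enhanced, target, form = c("squared", "absolute")) {
  form <- match.arg(form)
  if (!all(dim(enhanced) == dim(target))) stop("shape mismatch")
  d <- enhanced - target
  if (form == "squared") mean(d^2) else mean(abs(d))
}

#' Composite generator objective
#'
#' `lambda_adv * adv + lambda_mse * mse + lambda_vae * vae + lambda_ins * ins`.
#'
#' @param adv,mse,vae,ins finite component losses.
#' @param weights a [loss_weights()].
#' @return Scalar.
#' @examples
#' composite_loss(1, 1, 1, 1) # 2.0125 with the default weights
#' @export
composite_loss <- function(adv, mse, vae, ins, weights = loss_weights()) {
  weights$adv * adv + weights$mse * mse + weights$vae * vae + weights$ins * ins
}

#' Training configuration for the adversarial enhancer
#'
#' @param window input window side in bins; the enhanced output and the VAE
#'   input side is `window - 12`.
#' @param generator a [generator_spec()].
#' @param insulation an [insulation_params()].
#' @param epochs,batch_size training schedule.
#' @param lr_g,lr_d Adam step sizes for generator and discriminator.
#' @param lr_decay_every halve both learning rates every this many epochs
#'   (0 disables the step decay).
#' @param mse_form passed to [mse_loss()].
#' @param seed RNG seed.
#' @return An object of class `vehicle_config`.
#' @export
vehicle_config <- function(window = 269, generator = generator_spec(),
                           insulation = insulation_params(),
                           epochs = 30, batch_size = 4,
                           lr_g = 1e-4, lr_d = 1e-4, lr_decay_every = 0,
                           mse_form = "squared", seed = 1) {
  structure(list(window = as.integer(window), generator = generator,
                 insulation = insulation, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_g = lr_g, lr_d = lr_d,
                 lr_decay_every = as.integer(lr_decay_every),
                 mse_form = mse_form, seed = as.integer(seed)),
            class = "vehicle_config")
}

#' Train the adversarial Hi-C enhancement model
#'
#' Second phase of the two-phase schedule: with the variational autoencoder
#' already trained on the same chromosomes, the generator and discriminator
#' are updated alternately (1:1). The discriminator minimizes binary
#' cross-entropy between real high-resolution crops and enhanced outputs;
#' the generator minimizes the composite objective combining adversarial,
#' bin-wise MSE, variational-feature and insulation terms (the adversarial
#' term enters the gradient as a batch mean so the operating point does not
#' depend on batch size).
#'
#' @param dataset list of window samples (fields `low`, `high`, side
#'   `config$window`, values in `[0, 1]`), e.g. from
#'   [extract_diagonal_windows()].
#' @param vae a trained [hic_vae] whose `input_size` equals
#'   `config$window - 12`; required whenever `weights$vae > 0`.
#' @param weights a [loss_weights()].
#' @param config a [vehicle_config()].
#' @param verbose print per-epoch losses?
#' @return An object of class `vehicle_model` with fields `generator`,
#'   `discriminator`, `vae`, `weights`, `config` and a per-epoch `history`.
#' @export
train_vehicle <- function(dataset, vae = NULL, weights = loss_weights(),
                          config = vehicle_config(), verbose = FALSE) {
  if (length(dataset) == 0) stop("empty dataset")
  S <- config$window
  Sp <- S - config$generator$shrink_bins
  if (weights$vae > 0) {
    if (is.null(vae)) stop("a trained VAE is required when lambda_vae > 0")
    if (vae$config$input_size != Sp)
      stop(sprintf("VAE input side %d does not match enhanced side %d",
                   vae$config$input_size, Sp))
  }
  if (weights$ins > 0 &&
      Sp <= config$insulation$window_bins + 2 * config$insulation$delta_bins)
    stop("enhanced side too small for the insulation loss support")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$seed)
  gen <- build_generator(config$generator, seed = config$seed)
  disc <- build_discriminator(seed = config$seed + 1)
  gen_layers <- .gen_layers(gen)
  m <- length(dataset)
  low_all <- array(unlist(lapply(dataset, `[[`, "low")), c(S, S, 1, m))
  high_all <- array(unlist(lapply(dataset, function(s)
    center_crop(s$high, Sp))), c(Sp, Sp, 1, m))
  eps <- 1e-12
  hist <- NULL
  step_g <- step_d <- 0
  for (epoch in seq_len(config$epochs)) {
    decay <- if (config$lr_decay_every > 0)
      0.5^((epoch - 1) %/% config$lr_decay_every) else 1
    lr_g <- config$lr_g * decay
    lr_d <- config$lr_d * decay
    perm <- sample.int(m)
    comp <- c(adv = 0, mse = 0, vae = 0, ins = 0, total = 0, d = 0)
    for (b in split(perm, ceiling(seq_along(perm) / config$batch_size))) {
      nb <- length(b)
      xl <- low_all[, , , b, drop = FALSE]
      xt <- high_all[, , , b, drop = FALSE]
      out <- .gen_forward(gen, xl, train = TRUE)

      # --- discriminator update (enhanced batch treated as constant)
      r_sc <- .disc_forward(disc, xt, train = TRUE)
      .disc_backward(disc, -1 / (nb * (r_sc + eps)))
      f_sc <- .disc_forward(disc, out, train = TRUE)
      .disc_backward(disc, 1 / (nb * (1 - f_sc + eps)))
      step_d <- step_d + 1
      adam_step(disc$layers, lr_d, step_d)
      zero_grads(disc$layers)
      d_loss <- discriminator_loss(r_sc, f_sc)

      # --- generator update through the composite objective
      gO <- array(0, dim(out))
      f2 <- .disc_forward(disc, out, train = TRUE)
      adv <- mean(-log(f2 + eps))
      if (weights$adv > 0) {
        gO <- gO + weights$adv * .disc_backward(disc, -1 / (nb * (f2 + eps)))
        zero_grads(disc$layers)
      }
      mse <- mean((out - xt)^2)
      if (weights$mse > 0)
        gO <- gO + weights$mse * 2 * (out - xt) / (length(out) / nb) / nb
      vloss <- 0
      if (weights$vae > 0) {
        vb <- .variational_loss_bw(vae, out, xt)
        vloss <- vb$loss
        gO <- gO + weights$vae * vb$gx
      }
      ins <- 0
      if (weights$ins > 0) {
        for (s in seq_len(nb)) {
          e_s <- out[, , 1, s]; t_s <- xt[, , 1, s]
          ins <- ins + insulation_loss(e_s, t_s, config$insulation) / nb
          gO[, , 1, s] <- gO[, , 1, s] +
            weights$ins * .insulation_loss_bw(e_s, t_s, config$insulation) / nb
        }
      }
      .gen_backward(gen, gO)
      step_g <- step_g + 1
      adam_step(gen_layers, lr_g, step_g)
      zero_grads(gen_layers)

      tot <- composite_loss(adv, mse, vloss, ins, weights)
      comp <- comp + nb * c(adv = adv, mse = mse, vae = vloss, ins = ins,
                            total = tot, d = d_loss)
    }
    comp <- comp / m
    hist <- rbind(hist, data.frame(epoch = epoch, t(comp)))
    if (verbose)
      message(sprintf(
        "epoch %d: total %.5f (adv %.3f, mse %.5f, vae %.4f, ins %.4f) d %.4f",
        epoch, comp["total"], comp["adv"], comp["mse"], comp["vae"],
        comp["ins"], comp["d"]))
  }
  structure(list(generator = gen, discriminator = disc, vae = vae,
                 weights = weights, config = config, history = hist),
            class = "vehicle_model")
}

#' @export
print.vehicle_model <- function(x, ...) {
  cat(sprintf("vehicle_model: %d-bin windows -> %d-bin enhanced output\n",
              x$config$window, x$config$window - x$config$generator$shrink_bins))
  cat(sprintf("  generator: %d residual blocks, %d filters\n",
              x$config$generator$n_res_blocks, x$config$generator$filters))
  cat(sprintf("  loss weights: adv %g, mse %g, vae %g, ins %g\n",
              x$weights$adv, x$weights$mse, x$weights$vae, x$weights$ins))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs; final composite loss %.5f\n",
                nrow(x$history), x$history$total[nrow(x$history)]))
  invisible(x)
}

#' @export
summary.vehicle_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nloss trajectory (first/last epochs):\n")
    h <- object$history
    print(h[unique(c(1, nrow(h))), ], row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.vehicle_model <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  graphics::plot(h$epoch, h$total, type = "b", xlab = "epoch",
                 ylab = "composite loss", main = "training trajectory", ...)
  invisible(x)
}

#' @export
predict.vehicle_model <- function(object, newdata, ...) {
  if (inherits(newdata, "contact_map"))
    return(enhance_chromosome(newdata, object, ...))
  enhance_windows(object$generator, newdata)
}

#' Enhance a whole chromosome
#'
#' Slides diagonal windows over the (unit-scaled) low-resolution map,
#' enhances each with the generator, places each output at diagonal offset
#' `start + 6` (half the 12-bin shrink), averages overlapping predictions
#' entrywise, and symmetrizes. Bin pairs never covered by a window (far from
#' the diagonal, or at the chromosome edge) are `NA` in the result and have
#' coverage 0 — they are flagged, not fabricated.
#'
#' @param low a low-coverage [contact_map].
#' @param model a `vehicle_model`, a bare `hic_generator`, or a plain
#'   function mapping a window matrix to a smaller enhanced matrix (useful
#'   for testing the reassembly, e.g. a center crop).
#' @param window,stride windowing geometry (defaults from the model config).
#' @param scale scale the chromosome to `[0, 1]` first?
#' @return An object of class `enhanced_map`: fields `matrix` (with `NA`
#'   outside coverage), `coverage`, `chrom`, `resolution`.
#' @export
enhance_chromosome <- function(low, model, window = NULL, stride = 50,
                               scale = TRUE) {
  if (is.null(window))
    window <- if (inherits(model, "vehicle_model")) model$config$window else 269L
  predict_window <- if (is.function(model)) {
    model # any window -> smaller window map, e.g. a center crop
  } else {
    gen <- if (inherits(model, "vehicle_model")) model$generator else model
    function(w) enhance_windows(gen, w)
  }
  n <- nrow(low$matrix)
  if (n < window) stop("chromosome shorter than window")
  m <- low$matrix
  if (scale) m <- scale_unit(m)
  out_side <- nrow(predict_window(m[seq_len(window), seq_len(window)]))
  if ((window - out_side) %% 2 != 0) stop("window shrink must be even")
  border <- (window - out_side) / 2
  acc <- matrix(0, n, n)
  cov <- matrix(0L, n, n)
  for (s in seq(0, n - window, by = stride)) {
    idx <- s + seq_len(window)
    y <- predict_window(m[idx, idx])
    oidx <- s + border + seq_len(out_side)
    acc[oidx, oidx] <- acc[oidx, oidx] + y
    cov[oidx, oidx] <- cov[oidx, oidx] + 1L
  }
  out <- acc / ifelse(cov > 0, cov, NA)
  out <- (out + t(out)) / 2
  structure(list(matrix = out, coverage = cov, chrom = low$chrom,
                 resolution = low$resolution),
            class = "enhanced_map")
}

#' @export
print.enhanced_map <- function(x, ...) {
  n <- nrow(x$matrix)
  cat(sprintf("enhanced_map: %s, %d bins; %.1f%% of bin pairs covered\n",
              x$chrom, n, 100 * mean(x$coverage > 0)))
  invisible(x)
}
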
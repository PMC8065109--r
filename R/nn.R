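# Minimal convolutional-network engine used by the VAE and GAN models.
#
# Layers are environments holding parameters, gradients and Adam state; each
# exposes fw(x, train) and bw(gy). The `train` argument takes three values:
# TRUE (training statistics, cache for backward), FALSE (inference, no cache),
# and "frozen" (inference statistics but cached, for backpropagating through
# a frozen network such as the trained encoder inside the composite loss). Activations live in 4-d arrays dim
# (H, W, C, N); dense layers use matrices dim (D, N). The convolution
# forward/backward kernels are compiled (see src/nn_ops.cpp); everything
# element-wise stays vectorized R.

new_layer <- function(type, par = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$par <- par
  e$grad <- lapply(par, function(p) p * 0) # keep each parameter's exact shape
  e$opt <- NULL
  class(e) <- "vehicle_layer"
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zero_grads <- function(layers) {
  for (l in layers) {
    for (nm in names(l$grad)) l$grad[[nm]][] <- 0
  }
  invisible(NULL)
}

# He-style initialization; relies on the caller having seeded the RNG.
init_weights <- function(d, fan_in) {
  array(stats::rnorm(prod(d), sd = sqrt(2 / fan_in)), dim = d)
}

nn_conv <- function(cin, cout, k = 3L, stride = 1L, pad = 0L) {
  l <- new_layer("conv", list(
    w = init_weights(c(k, k, cin, cout), k * k * cin),
    b = numeric(cout)
  ))
  l$k <- k; l$stride <- stride; l$pad <- pad
  l$fw <- function(x, train = TRUE) {
    if (!isFALSE(train)) l$x <- x
    .conv2d_fw(x, l$par$w, l$par$b, l$stride, l$pad)
  }
  l$bw <- function(gy) {
    g <- .conv2d_bw(l$x, l$par$w, gy, l$stride, l$pad)
    l$grad$w <- l$grad$w + g$gw
    l$grad$b <- l$grad$b + g$gb
    g$gx
  }
  l
}

nn_convt <- function(cin, cout, k = 3L, stride = 2L, pad = 1L) {
  l <- new_layer("convt", list(
    w = init_weights(c(k, k, cout, cin), k * k * cin),
    b = numeric(cout)
  ))
  l$k <- k; l$stride <- stride; l$pad <- pad
  l$fw <- function(x, train = TRUE) {
    if (!isFALSE(train)) l$x <- x
    .convt2d_fw(x, l$par$w, l$par$b, l$stride, l$pad)
  }
  l$bw <- function(gy) {
    g <- .convt2d_bw(l$x, l$par$w, gy, l$stride, l$pad)
    l$grad$w <- l$grad$w + g$gw
    l$grad$b <- l$grad$b + g$gb
    g$gx
  }
  l
}

# Batch normalization over (H, W, N) per channel, with running statistics
# for eval mode. Broadcasting exploits column-major layout: a length-C
# vector repeated each = H*W recycles correctly across the batch.
nn_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("bn", list(gamma = rep(1, c), beta = numeric(c)))
  l$rm <- numeric(c); l$rv <- rep(1, c)
  l$momentum <- momentum; l$eps <- eps; l$c <- c
  bc <- function(v, d) rep(v, each = d[1] * d[2]) # recycled over N
  l$fw <- function(x, train = TRUE) {
    d <- dim(x)
    if (isTRUE(train)) {
      m <- apply(x, 3, mean)
      xm <- x - bc(m, d)
      v <- apply(xm * xm, 3, mean)
      istd <- 1 / sqrt(v + l$eps)
      xhat <- xm * bc(istd, d)
      l$rm <- (1 - l$momentum) * l$rm + l$momentum * m
      l$rv <- (1 - l$momentum) * l$rv + l$momentum * v
      l$xm <- xm; l$istd <- istd; l$xhat <- xhat; l$train_mode <- TRUE
      xhat * bc(l$par$gamma, d) + bc(l$par$beta, d)
    } else {
      istd <- 1 / sqrt(l$rv + l$eps)
      xhat <- (x - bc(l$rm, d)) * bc(istd, d)
      if (!isFALSE(train)) {
        l$istd_eval <- istd; l$xhat <- xhat; l$train_mode <- FALSE
      }
      xhat * bc(l$par$gamma, d) + bc(l$par$beta, d)
    }
  }
  l$bw <- function(gy) {
    d <- dim(gy)
    if (isTRUE(l$train_mode)) {
      nc <- d[1] * d[2] * d[4]
      gxhat <- gy * bc(l$par$gamma, d)
      l$grad$gamma <- l$grad$gamma + apply(gy * l$xhat, 3, sum)
      l$grad$beta <- l$grad$beta + apply(gy, 3, sum)
      s1 <- apply(gxhat, 3, sum)
      s2 <- apply(gxhat * l$xhat, 3, sum)
      (gxhat - bc(s1 / nc, d) - l$xhat * bc(s2 / nc, d)) * bc(l$istd, d)
    } else {
      # frozen statistics: plain affine map
      l$grad$gamma <- l$grad$gamma + apply(gy * l$xhat, 3, sum)
      l$grad$beta <- l$grad$beta + apply(gy, 3, sum)
      gy * bc(l$par$gamma * l$istd_eval, d)
    }
  }
  l
}

nn_act <- function(kind = c("lrelu", "relu", "sigmoid"), slope = 0.2) {
  kind <- match.arg(kind)
  l <- new_layer(paste0("act_", kind))
  l$kind <- kind; l$slope <- slope
  l$fw <- function(x, train = TRUE) {
    if (kind == "sigmoid") {
      y <- 1 / (1 + exp(-x))
      if (!isFALSE(train)) l$y <- y
      return(y)
    }
    neg <- x < 0
    y <- x
    y[neg] <- if (kind == "lrelu") slope * x[neg] else 0
    if (!isFALSE(train)) l$neg <- neg
    y
  }
  l$bw <- function(gy) {
    if (kind == "sigmoid") return(gy * l$y * (1 - l$y))
    g <- gy
    g[l$neg] <- if (kind == "lrelu") slope * gy[l$neg] else 0
    g
  }
  l
}

nn_linear <- function(din, dout) {
  l <- new_layer("linear", list(
    w = init_weights(c(dout, din), din),
    b = numeric(dout)
  ))
  l$fw <- function(x, train = TRUE) {
    if (!isFALSE(train)) l$x <- x
    l$par$w %*% x + l$par$b
  }
  l$bw <- function(gy) {
    l$grad$w <- l$grad$w + gy %*% t(l$x)
    l$grad$b <- l$grad$b + rowSums(gy)
    t(l$par$w) %*% gy
  }
  l
}

# (H, W, C, N) <-> (H*W*C, N)
nn_flatten <- function() {
  l <- new_layer("flatten")
  l$fw <- function(x, train = TRUE) {
    l$d <- dim(x)
    matrix(x, nrow = prod(l$d[1:3]), ncol = l$d[4])
  }
  l$bw <- function(gy) array(gy, dim = l$d)
  l
}

nn_reshape <- function(h, w, c) {
  l <- new_layer("reshape")
  l$h <- h; l$w <- w; l$c <- c
  l$fw <- function(x, train = TRUE) {
    l$n <- ncol(x)
    array(x, dim = c(l$h, l$w, l$c, l$n))
  }
  l$bw <- function(gy) matrix(gy, nrow = l$h * l$w * l$c, ncol = l$n)
  l
}

seq_fw <- function(layers, x, train = TRUE) {
  for (l in layers) x <- l$fw(x, train)
  x
}

seq_bw <- function(layers, gy) {
  for (l in rev(layers)) gy <- l$bw(gy)
  gy
}

# Adam over every parameter of every layer; t is the global step counter.
adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    if (length(l$par) == 0) next
    if (is.null(l$opt)) {
      l$opt <- list(m = lapply(l$par, function(p) p * 0),
                    v = lapply(l$par, function(p) p * 0))
    }
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      l$opt$m[[nm]] <- beta1 * l$opt$m[[nm]] + (1 - beta1) * g
      l$opt$v[[nm]] <- beta2 * l$opt$v[[nm]] + (1 - beta2) * g * g
      mhat <- l$opt$m[[nm]] / (1 - beta1^t)
      vhat <- l$opt$v[[nm]] / (1 - beta2^t)
      l$par[[nm]] <- l$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

# Deterministic fingerprint of all parameters (seeded-reproducibility tests).
params_checksum <- function(layers) {
  s <- 0
  for (l in layers) for (p in l$par) s <- s + sum(p * seq_along(p))
  s
}

collect_params <- function(layers) lapply(layers, function(l) l$par)

restore_params <- function(layers, saved) {
  for (i in seq_along(layers)) layers[[i]]$par <- saved[[i]]
  invisible(NULL)
}
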
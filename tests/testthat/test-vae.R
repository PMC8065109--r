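tiny_vae_cfg <- function(epochs = 6, seed = 7)
  vae_config(input_size = 33, latent_dim = 8,
             encoder_channels = c(8, 8, 16), decoder_channels = c(16, 8, 8),
             learning_rate = 1e-3, epochs = epochs, batch_size = 4,
             kl_weight = 0.05, seed = seed)

tiny_windows <- function(n = 16, side = 33, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cm <- generate_hic(toy_hic_spec(side, tads = list(c(5, 25, 2 + i %% 3)),
                                    count_scale = 50, seed = seed * 100 + i))
    scale_unit(cm$matrix)
  })
}

test_that("geometry is validated and encode/decode round-trip shapes hold", {
  expect_error(vae_config(input_size = 32), "even")
  cfg <- vae_config() # 257-bin default with the 7-layer channel ladder
  expect_identical(cfg$sides, c(257L, 129L, 65L, 33L, 17L, 9L, 5L, 3L))
  expect_identical(cfg$encoder_channels, c(32, 64, 128, 256, 256, 512, 512))
  expect_identical(cfg$decoder_channels, c(512, 512, 256, 256, 128, 64, 32))

  cfg2 <- tiny_vae_cfg()
  set.seed(cfg2$seed)
  v <- structure(list(net = vehicle:::.build_vae(cfg2), config = cfg2),
                 class = "hic_vae")
  x <- tiny_windows(1)[[1]]
  enc <- vae_encode(v, x)
  expect_identical(dim(enc$mu), c(8L, 1L))
  expect_identical(dim(enc$logvar), c(8L, 1L))
  expect_identical(vae_encode(v, x)$mu, enc$mu) # deterministic in eval mode

  y <- vae_decode(v, stats::rnorm(8))
  expect_identical(dim(y), c(33L, 33L))
  expect_true(all(y > 0 & y < 1)) # sigmoid range
  expect_identical(dim(vae_decode(v, drop(enc$mu))), dim(x))
  expect_error(vae_decode(v, c(NaN, stats::rnorm(7))), "finite")
  expect_error(vae_encode(v, matrix(0.5, 20, 20)), "expected")
})

test_that("encoder output responds to single-pixel perturbations", {
  cfg <- tiny_vae_cfg()
  set.seed(cfg$seed)
  v <- structure(list(net = vehicle:::.build_vae(cfg), config = cfg),
                 class = "hic_vae")
  x <- tiny_windows(1)[[1]]
  mu0 <- vae_encode(v, x)$mu
  xp <- x; xp[17, 17] <- min(1, xp[17, 17] + 1e-3)
  expect_gt(max(abs(vae_encode(v, xp)$mu - mu0)), 0)
})

test_that("KL divergence matches its closed form and is non-negative", {
  expect_equal(kl_divergence(c(0, 0), c(0, 0)), 0)
  expect_equal(kl_divergence(c(1, 1), c(0, 0)), 1)
  set.seed(5)
  for (i in 1:1000) {
    mu <- stats::rnorm(4); lv <- stats::rnorm(4)
    expect_gte(kl_divergence(mu, lv), 0)
  }
})

test_that("KL closed form agrees with a Monte-Carlo estimate", {
  set.seed(42)
  mu <- c(0.5, -1, 0.25); lv <- c(0.3, -0.4, 0)
  n <- 1e6
  z <- matrix(stats::rnorm(3 * n, mean = mu, sd = exp(lv / 2)), nrow = 3)
  logq <- colSums(stats::dnorm(z, mu, exp(lv / 2), log = TRUE))
  logp <- colSums(stats::dnorm(z, 0, 1, log = TRUE))
  mc <- mean(logq - logp)
  expect_equal(kl_divergence(mu, lv), mc, tolerance = 0.01)
})

test_that("vae objective decomposes into reconstruction and weighted KL", {
  x <- sym_map(33, 3)
  expect_equal(vae_objective(x, x, rep(0, 8), rep(0, 8)), 0)
  xr <- sym_map(33, 4)
  mu <- stats::rnorm(8); lv <- stats::rnorm(8)
  expect_equal(vae_objective(x, xr, mu, lv, kl_weight = 0), sum((x - xr)^2))
  expect_equal(vae_objective(x, xr, mu, lv, kl_weight = 2),
               sum((x - xr)^2) + 2 * kl_divergence(mu, lv))
})

test_that("training lowers the objective and is seed-reproducible", {
  ws <- tiny_windows(16)
  v1 <- train_vae(ws, tiny_vae_cfg())
  expect_lt(v1$history$objective[nrow(v1$history)], v1$history$objective[1])
  v2 <- train_vae(ws, tiny_vae_cfg())
  expect_equal(v1$history, v2$history, tolerance = 1e-12)
  expect_equal(vehicle:::params_checksum(c(v1$net$enc, v1$net$dec)),
               vehicle:::params_checksum(c(v2$net$enc, v2$net$dec)))
  expect_error(train_vae(list(), tiny_vae_cfg()), "empty|expected")
})

test_that("near-duplicate windows have closer latent codes than strangers", {
  fx <- desk_models()
  base <- fx$highs[[1]]
  dup <- base + stats::rnorm(length(base), sd = 0.01)
  dup[] <- pmin(1, pmax(0, dup)) # clamp in place, keeping matrix shape
  stranger <- fx$highs[[length(fx$highs)]]
  mu <- function(m) drop(vae_encode(fx$vae, m)$mu)
  d_dup <- sqrt(sum((mu(base) - mu(dup))^2))
  d_str <- sqrt(sum((mu(base) - mu(stranger))^2))
  expect_lt(d_dup, d_str)
})

test_that("with the KL weight annealed to full strength the aggregate posterior nears the prior", {
  set.seed(1)
  ws <- lapply(1:24, function(i) {
    cm <- generate_hic(toy_hic_spec(33, tads = list(c(5, 25, 2 + i %% 3)),
                                    count_scale = 50, seed = 100 + i))
    scale_unit(cm$matrix)
  })
  cfg <- vae_config(input_size = 33, latent_dim = 8,
                    encoder_channels = c(8, 8, 16),
                    decoder_channels = c(16, 8, 8),
                    learning_rate = 1e-3, epochs = 25, batch_size = 8,
                    kl_weight = 1, kl_anneal_epochs = 10, seed = 9)
  v <- train_vae(ws, cfg)
  enc <- vae_encode(v, ws)
  set.seed(3)
  eps <- matrix(stats::rnorm(length(enc$mu)), nrow(enc$mu))
  z <- enc$mu + exp(enc$logvar / 2) * eps
  expect_lt(abs(mean(z)), 0.3)
  expect_lt(abs(stats::sd(as.vector(z)) - 1), 0.3)
})

test_that("variational loss is a symmetric mean latent-mean difference", {
  fx <- desk_models()
  a <- fx$highs[[2]]; b <- fx$highs[[3]]
  expect_equal(variational_loss(a, a, fx$vae), 0)
  expect_equal(variational_loss(a, b, fx$vae), variational_loss(b, a, fx$vae))
  mu_a <- vae_encode(fx$vae, a)$mu; mu_b <- vae_encode(fx$vae, b)$mu
  expect_equal(variational_loss(a, b, fx$vae), mean(abs(mu_a - mu_b)))
  expect_error(variational_loss(a, sym_map(20, 1), fx$vae), "mismatch")
})

test_that("latent_code draws the reparameterized sample with its seed", {
  fx <- desk_models()
  lc1 <- latent_code(fx$vae, fx$highs[[1]], seed = 5)
  lc2 <- latent_code(fx$vae, fx$highs[[1]], seed = 5)
  expect_identical(lc1$z, lc2$z)
  set.seed(5)
  eps <- stats::rnorm(length(lc1$mu))
  expect_equal(lc1$z, lc1$mu + exp(lc1$logvar / 2) * eps)
})
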
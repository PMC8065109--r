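test_that("generator output side is the input side minus twelve", {
  g <- build_generator(generator_spec(n_res_blocks = 1, filters = 4), seed = 1)
  for (side in c(21, 33, 69)) {
    y <- enhance_windows(g, matrix(stats::runif(side^2), side, side))
    expect_equal(nrow(y), side - 12)
    expect_true(all(y >= 0 & y <= 1)) # sigmoid range
  }
  expect_error(enhance_windows(g, matrix(0.5, 13, 13)), "smaller")
})

test_that("discriminator scores are probabilities with usable gradients", {
  d <- build_discriminator(seed = 2)
  x <- sym_map(33, 3)
  s1 <- discriminator_scores(d, x)
  expect_true(s1 > 0 && s1 < 1)
  expect_identical(discriminator_scores(d, x), s1) # deterministic in eval

  # finite-difference: the score moves when the input moves
  xb <- array(x, c(33, 33, 1, 1))
  s <- vehicle:::.disc_forward(d, xb, train = TRUE)
  g <- vehicle:::.disc_backward(d, 1)
  vehicle:::zero_grads(d$layers)
  expect_gt(max(abs(g)), 0)
  i <- which.max(abs(g))
  eps <- 1e-4
  xp <- xb; xp[i] <- xp[i] + eps
  fd <- (vehicle:::.disc_forward(d, xp, FALSE) -
           vehicle:::.disc_forward(d, xb, FALSE)) / eps
  expect_gt(abs(fd), 0)
})

test_that("adversarial and discriminator losses match their closed forms", {
  expect_equal(adversarial_loss(1), 0, tolerance = 1e-10)
  expect_equal(adversarial_loss(0.5), -log(0.5), tolerance = 1e-10)
  expect_equal(adversarial_loss(c(1, 0.5)),
               adversarial_loss(1) + adversarial_loss(0.5))
  expect_true(is.finite(adversarial_loss(0))) # eps-guarded

  expect_equal(discriminator_loss(1, 0), 0, tolerance = 1e-10)
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(2), tolerance = 1e-10)
  expect_lt(discriminator_loss(0.9, 0.3), discriminator_loss(0.6, 0.3))
})

test_that("mse loss follows the bin-wise formulas", {
  x <- sym_map(25, 1); y <- sym_map(25, 2)
  expect_equal(mse_loss(x, x), 0)
  expect_equal(mse_loss(x + 0.1, x), 0.01)
  expect_equal(mse_loss(x, y), sum((x - y)^2) / 25^2)
  expect_equal(mse_loss(x, y, form = "absolute"), sum(abs(x - y)) / 25^2)
  expect_error(mse_loss(x, sym_map(20, 1)), "mismatch")
})

test_that("composite loss is the weighted sum of its components", {
  expect_equal(composite_loss(0, 0, 0, 0), 0)
  expect_equal(composite_loss(1, 1, 1, 1), 2.0125)
  set.seed(6)
  for (i in 1:100) {
    v <- stats::runif(4); w <- loss_weights(stats::runif(1), stats::runif(1),
                                            stats::runif(1), stats::runif(1))
    expect_equal(composite_loss(v[1], v[2], v[3], v[4], w),
                 w$adv * v[1] + w$mse * v[2] + w$vae * v[3] + w$ins * v[4])
    expect_equal(composite_loss(2 * v[1], 2 * v[2], 2 * v[3], 2 * v[4], w),
                 2 * composite_loss(v[1], v[2], v[3], v[4], w))
  }
  expect_error(loss_weights(lambda_adv = -1), "non-negative")
})

test_that("loss weight defaults are the published operating point", {
  w <- loss_weights()
  expect_equal(unlist(w), c(adv = 0.0025, mse = 1, vae = 0.01, ins = 1))
})

test_that("chromosome reassembly averages to identity for a cropping model", {
  cm <- generate_hic(toy_hic_spec(160, tads = list(c(30, 90, 3)), seed = 9))
  crop_model <- function(w) center_crop(w, nrow(w) - 12)
  em <- enhance_chromosome(cm, crop_model, window = 69, stride = 15,
                           scale = TRUE)
  scaled <- scale_unit(cm$matrix)
  cov <- em$coverage > 0
  expect_gt(sum(cov), 0)
  expect_lt(max(abs(em$matrix[cov] - scaled[cov])), 1e-6)
  # symmetric where defined
  d <- em$matrix - t(em$matrix)
  expect_lt(max(abs(d[!is.na(d)])), 1e-6)
  # every bin pair within 2 Mb of the diagonal (interior) is covered;
  # scaled geometry: crop 57, stride 15 -> guaranteed band of 42 bins
  n <- 160
  interior <- 7:150
  for (i in interior) for (j in interior) {
    if (abs(i - j) <= 42) expect_gt(em$coverage[i, j], 0)
  }
})

test_that("gan training is seed-reproducible and lowers the composite loss", {
  samples <- desk_window_pairs(desk$train_seeds[1])[1:6]
  cfg <- vehicle_config(window = desk$window,
                        generator = generator_spec(n_res_blocks = 1,
                                                   filters = 8),
                        epochs = 3, batch_size = 3, lr_g = 1e-3, lr_d = 1e-3,
                        seed = 21)
  vcfg <- vae_config(input_size = desk$crop, latent_dim = 8,
                     encoder_channels = c(8, 8, 8),
                     decoder_channels = c(8, 8, 8),
                     epochs = 3, batch_size = 4, kl_weight = 0.05, seed = 22)
  vae <- train_vae(lapply(samples, function(s) center_crop(s$high, desk$crop)),
                   vcfg)
  m1 <- train_vehicle(samples, vae, loss_weights(), cfg)
  m2 <- train_vehicle(samples, vae, loss_weights(), cfg)
  expect_equal(vehicle:::params_checksum(vehicle:::.gen_layers(m1$generator)),
               vehicle:::params_checksum(vehicle:::.gen_layers(m2$generator)))
  expect_equal(m1$history, m2$history, tolerance = 1e-12)
  expect_error(train_vehicle(samples, NULL, loss_weights(), cfg), "VAE")
  expect_error(train_vehicle(list(), vae, loss_weights(), cfg), "empty")
})

test_that("two-phase training improves held-out enhancement quality", {
  fx <- desk_models()
  h <- fx$model$history
  expect_lt(mean(h$total[(nrow(h) - 4):nrow(h)]), h$total[1])
  ev <- desk_eval()
  expect_gt(ev["pcc_enh"], ev["pcc_low"])
  expect_gt(ev["ssi_enh"], ev["ssi_low"])
})
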
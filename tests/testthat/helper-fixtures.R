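# Shared fixtures. Everything is generated in code at test time; the
# expensive two-phase training harness runs once per session and is cached.

sym_map <- function(n, seed = 1, lo = 0.05, hi = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, lo, hi), n, n)
  (m + t(m)) / 2
}

# desk-scale study conditions: 300-bin synthetic chromosomes at 10 kb with
# random TAD segmentation, loops and stripes; 1/16 binomial downsampling;
# 69-bin windows (57-bin enhanced crop) at stride 15
desk <- list(window = 69L, crop = 57L, stride = 15L, keep = 1 / 16,
             n_bins = 300L, count_scale = 60,
             train_seeds = c(101L, 102L, 103L), test_seed = 201L)

make_toy_chrom <- function(seed, n_bins = desk$n_bins,
                           count_scale = desk$count_scale) {
  set.seed(seed)
  b <- 0; tads <- list()
  while (b < n_bins - 25) {
    len <- sample(25:60, 1)
    end <- min(n_bins, b + len)
    tads <- c(tads, list(c(b, end, stats::runif(1, 2.5, 4))))
    b <- end
  }
  loops <- list(); stripes <- list()
  for (t in tads) {
    if (t[2] - t[1] > 30 && stats::runif(1) < 0.7)
      loops <- c(loops, list(c(t[1] + 2, t[2] - 2, stats::runif(1, 2, 4))))
    if (stats::runif(1) < 0.4)
      stripes <- c(stripes, list(c(t[1], round((t[2] - t[1]) * 0.8),
                                   stats::runif(1, 0.5, 1.5))))
  }
  generate_hic(toy_hic_spec(n_bins, decay_exponent = 1, tads = tads,
                            loops = loops, stripes = stripes,
                            count_scale = count_scale, noise = TRUE,
                            seed = seed))
}

desk_window_pairs <- function(seed) {
  hi <- make_toy_chrom(seed)
  lo <- downsample(hi, desk$keep, seed = seed + 1)
  extract_diagonal_windows(lo, hi, window = desk$window, stride = desk$stride)
}

.fixtures <- new.env(parent = emptyenv())

# two-phase training at the desk-scale conditions; cached across test files
desk_models <- function() {
  if (!is.null(.fixtures$models)) return(.fixtures$models)
  train_samples <- do.call(c, lapply(desk$train_seeds, desk_window_pairs))
  highs <- lapply(train_samples, function(s) center_crop(s$high, desk$crop))
  vcfg <- vae_config(input_size = desk$crop, latent_dim = 16,
                     encoder_channels = c(8, 16, 16),
                     decoder_channels = c(16, 16, 8),
                     learning_rate = 1e-3, epochs = 20, batch_size = 8,
                     kl_weight = 0.05, seed = 11)
  vae <- train_vae(highs, vcfg)
  gcfg <- vehicle_config(window = desk$window,
                         generator = generator_spec(n_res_blocks = 2,
                                                    filters = 16),
                         epochs = 40, batch_size = 4,
                         lr_g = 1e-3, lr_d = 1e-3, seed = 12)
  model <- train_vehicle(train_samples, vae, loss_weights(), gcfg)
  .fixtures$models <- list(vae = vae, model = model,
                           train_samples = train_samples, highs = highs)
  .fixtures$models
}

# held-out evaluation: per-window metrics against the clean target
desk_eval <- function() {
  if (!is.null(.fixtures$eval)) return(.fixtures$eval)
  fx <- desk_models()
  test_samples <- desk_window_pairs(desk$test_seed)
  ev <- sapply(test_samples, function(s) {
    tgt <- center_crop(s$high, desk$crop)
    low <- center_crop(s$low, desk$crop)
    enh <- enhance_windows(fx$model$generator, s$low)
    c(pcc_low = pcc(low, tgt), pcc_enh = pcc(enh, tgt),
      ssi_low = ssi(low, tgt), ssi_enh = ssi(enh, tgt),
      dl2_low = delta_l2(low, tgt), dl2_enh = delta_l2(enh, tgt))
  })
  .fixtures$eval <- rowMeans(ev)
  .fixtures$eval
}
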
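test_that("encoder produces correctly shaped latent state and obeys the trick", {
  db <- tiny_db(2)
  cfg <- small_config(db, latent_dim = 16)
  params <- init_params(cfg, seed = 2)
  x <- encode_profiles(toy_profile())
  eps0 <- matrix(0, 1, 16)
  lat <- vae_encode(params, x, eps0)
  expect_equal(dim(lat$mu), c(1, 16))
  expect_equal(dim(lat$log_var), c(1, 16))
  # eps = 0 collapses z onto mu
  expect_equal(lat$z, lat$mu)
  # z = mu + exp(log_var/2) * eps elementwise
  eps <- matrix(rnorm(16), 1)
  lat2 <- vae_encode(params, x, eps)
  expect_equal(lat2$z, lat2$mu + exp(0.5 * lat2$log_var) * eps)
  # deterministic under fixed eps
  expect_identical(lat2$z, vae_encode(params, x, eps)$z)
  expect_error(vae_encode(params, cbind(x, 0)), class = "dietvae_contract_error")
})

test_that("full-scale configuration defaults match the reference architecture", {
  cfg <- model_config(vocab_size = 100)
  expect_equal(cfg$encoder_hidden, 256)
  expect_equal(cfg$latent_dim, 256)
  expect_equal(cfg$decoder_layers, 2)
  expect_equal(cfg$decoder_hidden, 512)
  expect_equal(cfg$n_slots, 6)
})

test_that("decoder emits six masked probability rows that sum to one", {
  db <- tiny_db(3)
  cfg <- small_config(db)
  params <- init_params(cfg, seed = 4)
  masks <- slot_masks(db)
  z <- matrix(rnorm(2 * cfg$latent_dim), 2)
  tr <- vae_decode(params, z, masks, cfg)
  expect_length(tr$probs, 6)
  for (t in 1:6) {
    p <- tr$probs[[t]]
    expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
    # masked classes get probability exactly 0
    expect_true(all(p[, !masks[[t]]] == 0))
    # selections come from the slot pool
    expect_true(all(tr$y_hat[, t] %in% db$slot_index[[meal_slots()[t]]]))
  }
  expect_equal(tr$ei_hat, rowSums(tr$ei_steps))
  expect_equal(dim(tr$nutr_hat), c(2, 4))
  # empty admissible set is a generation error
  bad_masks <- masks; bad_masks[[2]][] <- FALSE
  expect_error(vae_decode(params, z, bad_masks, cfg),
               class = "dietvae_generation_error")
})

test_that("a single admissible meal forces the choice with full mass", {
  db <- one_per_slot_db()
  cfg <- small_config(db)
  params <- init_params(cfg, seed = 5)
  tr <- vae_decode(params, matrix(rnorm(cfg$latent_dim), 1), slot_masks(db), cfg)
  for (t in 1:6) {
    only <- db$slot_index[[meal_slots()[t]]]
    expect_equal(tr$y_hat[1, t], only)
    expect_equal(tr$probs[[t]][1, only], 1)
  }
})

test_that("forward is a deterministic pure function given eps, stochastic without", {
  db <- tiny_db(3)
  cfg <- small_config(db)
  params <- init_params(cfg, seed = 6)
  masks <- slot_masks(db)
  x <- encode_profiles(dplyr::bind_rows(toy_profile("A"), toy_profile("B", weight = 95)))
  eps <- matrix(rnorm(2 * cfg$latent_dim), 2)
  f1 <- vae_forward(params, x, masks, cfg, eps = eps)
  f2 <- vae_forward(params, x, masks, cfg, eps = eps)
  expect_identical(f1$trace$y_hat, f2$trace$y_hat)
  expect_identical(f1$trace$ei_hat, f2$trace$ei_hat)
  # batched shapes
  expect_equal(dim(f1$trace$y_hat), c(2, 6))
  expect_equal(dim(f1$trace$probs[[1]]), c(2, db$n_meals))
  # two fresh eps draws generally give different z
  set.seed(1)
  g1 <- vae_forward(params, x, masks, cfg)
  g2 <- vae_forward(params, x, masks, cfg)
  expect_false(identical(g1$latent$z, g2$latent$z))
})

test_that("checkpoints round-trip and enforce vocabulary compatibility", {
  db <- tiny_db(2)
  cfg <- small_config(db)
  params <- init_params(cfg, seed = 7)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(path, params, cfg, db)
  ck <- load_checkpoint(path, db)
  expect_equal(ck$params$enc_W, params$enc_W)
  other <- tiny_db(3)
  expect_error(load_checkpoint(path, other), class = "dietvae_checkpoint_error")
})
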
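# The generative model: a VAE whose encoder maps the length-10 profile vector
# to a Gaussian latent space and whose decoder is a multi-layer GRU unrolled
# over the six meal slots, with three heads per step: a shared meal classifier
# (masked to the slot's admissible meals before softmax), a slot-energy head
# whose step outputs sum to the predicted energy intake, and a slot-nutrient
# head whose step outputs sum to the predicted macronutrient vector.
#
# Parameters are a flat named list of matrices/vectors; gradients mirror the
# structure (see backprop.R). All math is plain double-precision matrix
# algebra, so a fixed epsilon makes every forward pass a pure function of
# (x, params).

#' Model configuration
#'
#' Defaults are the full-scale architecture (256-unit encoder layer, 256-dim
#' latent space, 2-layer GRU with 512 hidden units); tests and desk-scale
#' experiments pass smaller dims.
#'
#' @param vocab_size Number of meals M in the vocabulary.
#' @param input_dim Length of the profile vector (10).
#' @param encoder_hidden Width of the encoder's fully connected layer.
#' @param latent_dim Dimension d of the latent space.
#' @param decoder_layers Number of GRU layers.
#' @param decoder_hidden GRU hidden units per layer.
#' @param n_slots Decoder time steps (6 meal slots).
#' @return A `model_config` list.
#' @export
model_config <- function(vocab_size, input_dim = 10, encoder_hidden = 256,
                         latent_dim = 256, decoder_layers = 2,
                         decoder_hidden = 512, n_slots = 6) {
  stopifnot(vocab_size >= 1, input_dim >= 1, encoder_hidden >= 1,
            latent_dim >= 1, decoder_layers >= 1, decoder_hidden >= 1,
            n_slots == 6)
  structure(list(vocab_size = as.integer(vocab_size),
                 input_dim = as.integer(input_dim),
                 encoder_hidden = as.integer(encoder_hidden),
                 latent_dim = as.integer(latent_dim),
                 decoder_layers = as.integer(decoder_layers),
                 decoder_hidden = as.integer(decoder_hidden),
                 n_slots = as.integer(n_slots)),
            class = "model_config")
}

unif_init <- function(nr, nc, fan_in) {
  b <- 1 / sqrt(fan_in)
  matrix(runif(nr * nc, -b, b), nr, nc)
}

#' Initialize model parameters
#'
#' Uniform fan-in initialization for all affine maps and GRU gates.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return Named list of parameter arrays.
#' @export
init_params <- function(config, seed = 1) {
  set.seed(seed)
  u <- config$input_dim; he <- config$encoder_hidden
  d <- config$latent_dim; H <- config$decoder_hidden
  M <- config$vocab_size; L <- config$decoder_layers
  p <- list(
    enc_W = unif_init(he, u, u), enc_b = runif(he, -1, 1) / sqrt(u),
    mu_W = unif_init(d, he, he), mu_b = runif(d, -1, 1) / sqrt(he),
    lv_W = unif_init(d, he, he), lv_b = runif(d, -1, 1) / sqrt(he),
    zin_W = unif_init(H, d, d), zin_b = runif(H, -1, 1) / sqrt(d),
    cls_W = unif_init(M, H, H), cls_b = runif(M, -1, 1) / sqrt(H),
    ei_W = runif(H, -1, 1) / sqrt(H), ei_b = 0,
    nutr_W = unif_init(4, H, H), nutr_b = runif(4, -1, 1) / sqrt(H)
  )
  for (l in seq_len(L)) {
    p[[paste0("gru_Wi_", l)]] <- unif_init(3 * H, H, H)
    p[[paste0("gru_Wh_", l)]] <- unif_init(3 * H, H, H)
    p[[paste0("gru_bi_", l)]] <- runif(3 * H, -1, 1) / sqrt(H)
    p[[paste0("gru_bh_", l)]] <- runif(3 * H, -1, 1) / sqrt(H)
  }
  p
}

linfwd <- function(x, W, b) {
  x %*% t(W) + matrix(b, nrow(x), length(b), byrow = TRUE)
}

#' Slot-type masks for a meal database
#'
#' @param db A [meal_db()].
#' @return List of 6 logical vectors (length M): which meals are admissible
#'   in each slot.
#' @export
slot_masks <- function(db) {
  lapply(setNames(meal_slots(), meal_slots()), function(s) {
    seq_len(db$n_meals) %in% db$slot_index[[s]]
  })
}

#' Encode profiles into the latent space
#'
#' A fully connected layer with ReLU maps the profile vector to the encoder
#' feature space; two affine heads produce the mean and log-variance of the
#' latent Gaussian, and the reparameterization trick gives
#' `z = mu + exp(log_var / 2) * eps` with externally supplied or sampled
#' `eps ~ N(0, 1)`.
#'
#' @param params Parameters from [init_params()].
#' @param x Profile matrix (B x input_dim), e.g. from [encode_profiles()].
#' @param eps Noise matrix (B x latent_dim); sampled if `NULL`.
#' @return List (`latent_state`): `mu`, `log_var`, `eps`, `z` (all B x d),
#'   plus the hidden activation cache used by backprop.
#' @export
vae_encode <- function(params, x, eps = NULL) {
  x <- rbind(x) # promote a single profile vector to a 1-row matrix
  if (ncol(x) != ncol(params$enc_W)) {
    rlang::abort(sprintf("profile vector length %d != input_dim %d",
                         ncol(x), ncol(params$enc_W)),
                 class = "dietvae_contract_error")
  }
  he_pre <- linfwd(x, params$enc_W, params$enc_b)
  he <- pmax(he_pre, 0)
  mu <- linfwd(he, params$mu_W, params$mu_b)
  log_var <- linfwd(he, params$lv_W, params$lv_b)
  if (is.null(eps)) {
    eps <- matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
  }
  stopifnot(all(dim(eps) == dim(mu)))
  sd <- exp(0.5 * log_var)
  structure(list(mu = mu, log_var = log_var, eps = eps, z = mu + sd * eps,
                 sd = sd, he = he, relu_mask = he_pre > 0, x = x),
            class = "latent_state")
}

#' Decode a latent vector into a daily meal-plan trace
#'
#' Runs the GRU for six steps: step 1 consumes an affine projection of `z`,
#' later steps consume the previous top-layer hidden state. Per step, the
#' shared classifier's logits are masked to the slot's admissible meals
#' (masked logits set to `-Inf`) before the softmax; the energy and nutrient
#' heads are evaluated per step and summed over steps.
#'
#' @param params Parameters from [init_params()].
#' @param z Latent matrix (B x d) or vector.
#' @param masks List of `n_slots` logical vectors from [slot_masks()].
#' @param config The [model_config()] (for layer count).
#' @param keep_cache Retain activations needed for backprop.
#' @return A `decoder_trace`: `probs` (list of T B x M matrices), `y_hat`
#'   (B x T meal indices), `ei_steps` (B x T), `ei_hat` (B), `nutr_hat`
#'   (B x 4), `h_top` (list of T B x H), and `cache` when requested.
#' @export
vae_decode <- function(params, z, masks, config, keep_cache = FALSE) {
  z <- rbind(z)
  H <- config$decoder_hidden; L <- config$decoder_layers
  T_ <- config$n_slots; M <- config$vocab_size; B <- nrow(z)
  if (length(masks) != T_) {
    rlang::abort("need one admissibility mask per slot", class = "dietvae_contract_error")
  }
  if (any(vapply(masks, sum, numeric(1)) == 0)) {
    rlang::abort("a slot has an empty admissible meal set",
                 class = "dietvae_generation_error")
  }
  g0 <- linfwd(z, params$zin_W, params$zin_b)
  h <- lapply(seq_len(L), function(l) matrix(0, B, H))
  probs <- vector("list", T_); h_top <- vector("list", T_)
  cache <- if (keep_cache) vector("list", T_) else NULL
  y_hat <- matrix(0L, B, T_)
  ei_steps <- matrix(0, B, T_)
  nutr_hat <- matrix(0, B, 4)
  xin <- g0
  for (t in seq_len(T_)) {
    step_cache <- if (keep_cache) vector("list", L) else NULL
    a <- xin
    for (l in seq_len(L)) {
      Wi <- params[[paste0("gru_Wi_", l)]]; Wh <- params[[paste0("gru_Wh_", l)]]
      bi <- params[[paste0("gru_bi_", l)]]; bh <- params[[paste0("gru_bh_", l)]]
      h_prev <- h[[l]]
      gi <- linfwd(a, Wi, bi)
      gh <- linfwd(h_prev, Wh, bh)
      idx_r <- 1:H; idx_u <- (H + 1):(2 * H); idx_n <- (2 * H + 1):(3 * H)
      r <- sigmoid(gi[, idx_r, drop = FALSE] + gh[, idx_r, drop = FALSE])
      ug <- sigmoid(gi[, idx_u, drop = FALSE] + gh[, idx_u, drop = FALSE])
      q <- gh[, idx_n, drop = FALSE]
      n <- tanh(gi[, idx_n, drop = FALSE] + r * q)
      h_new <- (1 - ug) * n + ug * h_prev
      if (keep_cache) {
        step_cache[[l]] <- list(a = a, h_prev = h_prev, r = r, u = ug, n = n, q = q)
      }
      h[[l]] <- h_new
      a <- h_new
    }
    ht <- h[[L]]
    h_top[[t]] <- ht
    logits <- linfwd(ht, params$cls_W, params$cls_b)
    logits[, !masks[[t]]] <- -Inf
    p <- softmax_rows(logits)
    probs[[t]] <- p
    y_hat[, t] <- max.col(p, ties.method = "first")
    ei_steps[, t] <- drop(ht %*% params$ei_W) + params$ei_b
    nutr_hat <- nutr_hat + linfwd(ht, params$nutr_W, params$nutr_b)
    if (keep_cache) cache[[t]] <- step_cache
    xin <- ht
  }
  structure(list(probs = probs, y_hat = y_hat, ei_steps = ei_steps,
                 ei_hat = rowSums(ei_steps), nutr_hat = nutr_hat,
                 h_top = h_top, g0 = g0, z = z, cache = cache),
            class = "decoder_trace")
}

#' Full forward pass: encode then decode
#'
#' @inheritParams vae_encode
#' @inheritParams vae_decode
#' @return List with `latent` ([vae_encode()] output) and `trace`
#'   ([vae_decode()] output).
#' @export
vae_forward <- function(params, x, masks, config, eps = NULL,
                        keep_cache = FALSE) {
  latent <- vae_encode(params, x, eps)
  trace <- vae_decode(params, latent$z, masks, config, keep_cache = keep_cache)
  list(latent = latent, trace = trace)
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the parameter arrays, the [model_config()], the
#' normalization bounds and a vocabulary fingerprint; loading against a
#' database with a different vocabulary fails.
#'
#' @param params,config,bounds Model state.
#' @param db The [meal_db()] the model was trained on.
#' @param path File path (RDS).
#' @return `path` invisibly (save); the checkpoint list (load).
#' @export
save_checkpoint <- function(path, params, config, db, bounds = default_bounds()) {
  saveRDS(list(params = params, config = config, bounds = bounds,
               vocab_hash = vocab_hash(db), n_meals = db$n_meals,
               package_version = as.character(utils::packageVersion("dietvae"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, db = NULL) {
  ck <- readRDS(path)
  need <- c("params", "config", "bounds", "vocab_hash")
  if (!all(need %in% names(ck))) {
    rlang::abort("not a dietvae checkpoint", class = "dietvae_checkpoint_error")
  }
  if (!is.null(db) && !identical(ck$vocab_hash, vocab_hash(db))) {
    rlang::abort("checkpoint vocabulary does not match the meal database",
                 class = "dietvae_checkpoint_error")
  }
  ck
}
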
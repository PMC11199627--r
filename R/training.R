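# Reproducible training loop wiring the model, losses and data.

#' Training configuration
#'
#' Defaults follow the reference training regime: Adam, learning rate 1e-4,
#' batch size 64, 500 epochs, 80/20 split; tests and desk-scale runs lower
#' `epochs`.
#'
#' @param learning_rate,batch_size,epochs,train_fraction,seed Hyperparameters.
#' @param weights Loss-term weights (see [total_loss()]).
#' @param energy_scale Energy normalization constant inside the loss (kcal).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 64, epochs = 500,
                         train_fraction = 0.8, seed = 1,
                         weights = c(mc = 1, kld = 1, ei = 1, macro = 1),
                         energy_scale = 1000) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1,
            train_fraction > 0, train_fraction < 1, energy_scale > 0)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), train_fraction = train_fraction,
                 seed = seed, weights = weights, energy_scale = energy_scale),
            class = "train_config")
}

#' Split plans into train and test sets by profile
#'
#' All of a user's plans land on one side of the split, preventing leakage of
#' a profile between train and test.
#'
#' @param plans Plan tibble from [assemble_truth_plans()].
#' @param train_fraction Fraction of profiles assigned to training.
#' @param seed Integer seed (seed-stable split).
#' @return List with `train` and `test` plan tibbles and the profile id
#'   vectors `train_ids`, `test_ids`.
#' @export
split_dataset <- function(plans, train_fraction = 0.8, seed = 1) {
  ids <- unique(plans$user_id)
  if (length(ids) < 2) {
    rlang::abort("need at least 2 profiles to split", class = "dietvae_contract_error")
  }
  set.seed(seed)
  n_train <- max(1, round(train_fraction * length(ids)))
  n_train <- min(n_train, length(ids) - 1)
  train_ids <- sort(sample(ids, n_train))
  test_ids <- setdiff(ids, train_ids)
  list(train = plans[plans$user_id %in% train_ids, ],
       test = plans[plans$user_id %in% test_ids, ],
       train_ids = train_ids, test_ids = test_ids)
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Precompute encoder inputs and per-plan targets for a plan table.
build_training_arrays <- function(plans, profiles, db, bounds, guidelines) {
  x_all <- encode_profiles(profiles, bounds)
  prof_idx <- match(plans$user_id, profiles$user_id)
  if (anyNA(prof_idx)) {
    rlang::abort("plans reference unknown profiles", class = "dietvae_contract_error")
  }
  tm <- as.matrix(plans[, c("m1", "m2", "m3", "m4", "m5", "m6")])
  if (max(tm) > db$n_meals || min(tm) < 1) {
    rlang::abort("plan meal ids outside the database vocabulary",
                 class = "dietvae_contract_error")
  }
  targets <- lapply(seq_len(nrow(profiles)), function(i) {
    derive_macro_targets(profiles$target_ei[i], profiles$group[i], guidelines)
  })
  macro_min <- t(vapply(targets, function(tt) tt$min_g, numeric(4)))
  macro_max <- t(vapply(targets, function(tt) tt$max_g, numeric(4)))
  list(x = x_all[prof_idx, , drop = FALSE], true_meals = tm,
       ei_target = profiles$target_ei[prof_idx],
       macro_min = macro_min[prof_idx, , drop = FALSE],
       macro_max = macro_max[prof_idx, , drop = FALSE])
}

epoch_eval <- function(params, arrays, masks, config, weights, energy_scale,
                       batch_size = 256) {
  # loss terms without gradient bookkeeping, batched for memory
  n <- nrow(arrays$x)
  terms <- c(mc = 0, kld = 0, ei = 0, macro = 0)
  done <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    eps <- matrix(0, length(idx), config$latent_dim) # posterior mean eval
    fw <- vae_forward(params, arrays$x[idx, , drop = FALSE], masks, config, eps = eps)
    terms["mc"] <- terms["mc"] +
      meal_cross_entropy(fw$trace$probs, arrays$true_meals[idx, , drop = FALSE]) * length(idx)
    terms["kld"] <- terms["kld"] + kld(fw$latent$mu, fw$latent$log_var) * length(idx)
    terms["ei"] <- terms["ei"] +
      energy_loss(fw$trace$ei_hat, arrays$ei_target[idx] / energy_scale) * length(idx)
    terms["macro"] <- terms["macro"] +
      macro_penalty(fw$trace$nutr_hat, arrays$macro_min[idx, , drop = FALSE],
                    arrays$macro_max[idx, , drop = FALSE]) * length(idx)
    done <- done + length(idx)
  }
  terms / done
}

#' Train the meal-plan VAE
#'
#' Minibatch Adam on the four-term total loss. Logs all four terms (and their
#' weighted sum) per epoch; keeps the parameters with the best validation
#' meal cross-entropy when validation data is given (checkpointing is
#' additive: the final parameters are also returned).
#'
#' @param profiles Profile tibble covering every `user_id` in `plans`.
#' @param plans Training plans ([assemble_truth_plans()] rows).
#' @param db The [meal_db()] the plan meal ids index into.
#' @param model_cfg A [model_config()] (its `vocab_size` must equal
#'   `db$n_meals`).
#' @param config A [train_config()].
#' @param val_plans Optional held-out plans for checkpoint selection.
#' @param bounds,guidelines Normalization bounds and guideline policy.
#' @param verbose Print per-epoch losses.
#' @return List with `params` (final), `best_params`, `log` (per-epoch loss
#'   tibble), `checkpoint` (list in [save_checkpoint()] layout, built from
#'   `best_params`).
#' @export
train_model <- function(profiles, plans, db, model_cfg,
                        config = train_config(), val_plans = NULL,
                        bounds = default_bounds(),
                        guidelines = default_guidelines(), verbose = FALSE) {
  stopifnot(inherits(model_cfg, "model_config"), inherits(config, "train_config"))
  if (model_cfg$vocab_size != db$n_meals) {
    rlang::abort("model vocab_size must equal the database size",
                 class = "dietvae_contract_error")
  }
  masks <- slot_masks(db)
  arrays <- build_training_arrays(plans, profiles, db, bounds, guidelines)
  val_arrays <- if (!is.null(val_plans)) {
    build_training_arrays(val_plans, profiles, db, bounds, guidelines)
  }
  params <- init_params(model_cfg, seed = derive_seed(config$seed, "init"))
  opt <- adam_init(params)
  n <- nrow(arrays$x)
  log_rows <- vector("list", config$epochs)
  best_val <- Inf; best_params <- params
  set.seed(derive_seed(config$seed, "epochs"))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    sums <- c(mc = 0, kld = 0, ei = 0, macro = 0, total = 0)
    seen <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      batch <- make_batch(arrays$x[idx, , drop = FALSE],
                          arrays$true_meals[idx, , drop = FALSE],
                          arrays$ei_target[idx],
                          arrays$macro_min[idx, , drop = FALSE],
                          arrays$macro_max[idx, , drop = FALSE])
      eps <- matrix(rnorm(length(idx) * model_cfg$latent_dim), length(idx))
      lg <- loss_and_grads(params, batch, masks, model_cfg, eps = eps,
                           weights = config$weights,
                           energy_scale = config$energy_scale)
      if (!is.finite(lg$loss$total)) {
        bad <- c(mc = lg$loss$l_mc, kld = lg$loss$l_kld, ei = lg$loss$l_ei,
                 macro = lg$loss$l_macro)
        rlang::abort(paste0("non-finite loss at epoch ", epoch, "; terms: ",
                            paste(names(bad), signif(bad, 4), sep = "=",
                                  collapse = ", ")),
                     class = "dietvae_training_error")
      }
      st <- adam_step(params, lg$grads, opt, config$learning_rate)
      params <- st$params; opt <- st$state
      w <- length(idx)
      sums <- sums + w * c(mc = lg$loss$l_mc, kld = lg$loss$l_kld,
                           ei = lg$loss$l_ei, macro = lg$loss$l_macro,
                           total = lg$loss$total)
      seen <- seen + w
    }
    avg <- sums / seen
    val_mc <- NA_real_
    if (!is.null(val_arrays)) {
      val_mc <- epoch_eval(params, val_arrays, masks, model_cfg,
                           config$weights, config$energy_scale)[["mc"]]
      if (val_mc < best_val) { best_val <- val_mc; best_params <- params }
    } else {
      best_params <- params
    }
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, l_mc = avg[["mc"]], l_kld = avg[["kld"]],
      l_ei = avg[["ei"]], l_macro = avg[["macro"]], total = avg[["total"]],
      val_mc = val_mc)
    if (verbose) {
      message(sprintf("epoch %3d  total %.4f  mc %.4f  kld %.4f  ei %.4f  macro %.4f",
                      epoch, avg[["total"]], avg[["mc"]], avg[["kld"]],
                      avg[["ei"]], avg[["macro"]]))
    }
  }
  log <- dplyr::bind_rows(log_rows)
  checkpoint <- list(params = best_params, config = model_cfg, bounds = bounds,
                     vocab_hash = vocab_hash(db), n_meals = db$n_meals)
  list(params = params, best_params = best_params, log = log,
       checkpoint = checkpoint)
}
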
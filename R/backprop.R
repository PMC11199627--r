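# Reverse-mode gradients of the total training loss, written by hand against
# the forward pass in model.R. Conventions: for y = x W^T + b with W (out x in)
# and batch-major x (B x in): dW = dY^T x, db = colSums(dY), dx = dY W.
# Correctness is pinned by a central finite-difference oracle in the tests.

zeros_like <- function(p) {
  lapply(p, function(v) if (is.matrix(v)) matrix(0, nrow(v), ncol(v)) else numeric(length(v)))
}

# Assemble per-batch training targets from plan rows.
# batch: list with x (B x u), true_meals (B x T), ei_target (B, kcal),
#        macro_min / macro_max (B x 4, grams)
make_batch <- function(x, true_meals, ei_target, macro_min, macro_max) {
  list(x = rbind(x), true_meals = rbind(true_meals), ei_target = ei_target,
       macro_min = rbind(macro_min), macro_max = rbind(macro_max))
}

#' Training loss and analytic gradients for one minibatch
#'
#' Runs the full forward pass (with supplied noise `eps` for determinism),
#' evaluates the four loss terms, and backpropagates through the heads, the
#' unrolled GRU, the latent projection, the reparameterization and the
#' encoder. Losses are batch means; energies enter in normalized units
#' (`kcal / energy_scale`).
#'
#' @param params Parameter list from [init_params()].
#' @param batch List with `x` (B x u), `true_meals` (B x T), `ei_target`
#'   (kcal, length B), `macro_min`, `macro_max` (B x 4 grams).
#' @param masks Slot masks from [slot_masks()].
#' @param config [model_config()].
#' @param eps Noise matrix (B x d); sampled when `NULL`.
#' @param weights Loss-term weights (see [total_loss()]).
#' @param energy_scale Normalization constant for energies (default 1000 kcal).
#' @return List with `loss` (a `loss_bundle`), `grads` (same shape as
#'   `params`) and `forward` (the forward-pass output).
#' @export
loss_and_grads <- function(params, batch, masks, config, eps = NULL,
                           weights = c(mc = 1, kld = 1, ei = 1, macro = 1),
                           energy_scale = 1000) {
  fw <- vae_forward(params, batch$x, masks, config, eps = eps, keep_cache = TRUE)
  latent <- fw$latent; trace <- fw$trace
  B <- nrow(batch$x); T_ <- config$n_slots
  H <- config$decoder_hidden; L <- config$decoder_layers

  ei_tgt_n <- batch$ei_target / energy_scale
  l_mc <- meal_cross_entropy(trace$probs, batch$true_meals)
  l_kld <- kld(latent$mu, latent$log_var)
  l_ei <- energy_loss(trace$ei_hat, ei_tgt_n)
  l_macro <- macro_penalty(trace$nutr_hat, batch$macro_min, batch$macro_max)
  loss <- total_loss(l_mc, l_kld, l_ei, l_macro, weights)

  g <- zeros_like(params)

  # ---- head-level output gradients
  dei <- weights[["ei"]] * 2 * (trace$ei_hat - ei_tgt_n) / B           # B
  dnutr <- weights[["macro"]] / (4 * B) *
    (sign(trace$nutr_hat - batch$macro_min) +
       sign(trace$nutr_hat - batch$macro_max))                          # B x 4
  dhtop <- vector("list", T_)
  for (t in seq_len(T_)) {
    p <- trace$probs[[t]]
    dlog <- p
    dlog[cbind(seq_len(B), batch$true_meals[, t])] <-
      dlog[cbind(seq_len(B), batch$true_meals[, t])] - 1
    dlog <- weights[["mc"]] * dlog / B
    ht <- trace$h_top[[t]]
    g$cls_W <- g$cls_W + t(dlog) %*% ht
    g$cls_b <- g$cls_b + colSums(dlog)
    g$ei_W <- g$ei_W + drop(t(ht) %*% dei)
    g$ei_b <- g$ei_b + sum(dei)
    g$nutr_W <- g$nutr_W + t(dnutr) %*% ht
    g$nutr_b <- g$nutr_b + colSums(dnutr)
    dhtop[[t]] <- dlog %*% params$cls_W + outer(dei, params$ei_W) +
      dnutr %*% params$nutr_W
  }

  # ---- backward through time and layers
  carry <- lapply(seq_len(L), function(l) matrix(0, B, H))
  dxin_next <- matrix(0, B, H)
  da <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    d_from_above <- NULL
    for (l in rev(seq_len(L))) {
      dh_total <- carry[[l]] +
        if (l == L) dhtop[[t]] + dxin_next else d_from_above
      cc <- trace$cache[[t]][[l]]
      du <- dh_total * (cc$h_prev - cc$n)
      dn <- dh_total * (1 - cc$u)
      dh_prev <- dh_total * cc$u
      dn_pre <- dn * (1 - cc$n^2)
      dr <- dn_pre * cc$q
      dq <- dn_pre * cc$r
      du_pre <- du * cc$u * (1 - cc$u)
      dr_pre <- dr * cc$r * (1 - cc$r)
      d_gi <- cbind(dr_pre, du_pre, dn_pre)
      d_gh <- cbind(dr_pre, du_pre, dq)
      wi <- paste0("gru_Wi_", l); wh <- paste0("gru_Wh_", l)
      bi <- paste0("gru_bi_", l); bh <- paste0("gru_bh_", l)
      g[[wi]] <- g[[wi]] + t(d_gi) %*% cc$a
      g[[bi]] <- g[[bi]] + colSums(d_gi)
      g[[wh]] <- g[[wh]] + t(d_gh) %*% cc$h_prev
      g[[bh]] <- g[[bh]] + colSums(d_gh)
      da <- d_gi %*% params[[wi]]
      dh_prev <- dh_prev + d_gh %*% params[[wh]]
      carry[[l]] <- dh_prev
      d_from_above <- da
    }
    dxin_next <- da # input of layer 1 at time t is h_top(t-1) (or g0 at t=1)
  }

  # ---- latent projection, reparameterization, KLD, encoder
  dg0 <- dxin_next
  g$zin_W <- t(dg0) %*% trace$z
  g$zin_b <- colSums(dg0)
  dz <- dg0 %*% params$zin_W
  dmu <- dz + weights[["kld"]] / B * latent$mu
  dlv <- dz * latent$eps * 0.5 * latent$sd +
    weights[["kld"]] / B * 0.5 * (exp(latent$log_var) - 1)
  g$mu_W <- t(dmu) %*% latent$he
  g$mu_b <- colSums(dmu)
  g$lv_W <- t(dlv) %*% latent$he
  g$lv_b <- colSums(dlv)
  dhe <- dmu %*% params$mu_W + dlv %*% params$lv_W
  dhe_pre <- dhe * latent$relu_mask
  g$enc_W <- t(dhe_pre) %*% latent$x
  g$enc_b <- colSums(dhe_pre)

  list(loss = loss, grads = g, forward = fw)
}

# Flatten/unflatten parameter lists (finite-difference oracle, Adam state).
flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(v, template) {
  out <- template
  pos <- 1L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    piece <- v[pos:(pos + n - 1L)]
    out[[nm]] <- if (is.matrix(template[[nm]])) {
      matrix(piece, nrow(template[[nm]]), ncol(template[[nm]]))
    } else piece
    pos <- pos + n
  }
  out
}
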
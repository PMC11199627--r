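# The four training loss terms and their sum. Op-level functions below work on
# single examples or batches and are shared by the training loop; the training
# gradients live in backprop.R.

#' Macronutrient range penalty
#'
#' `(1/N) * sum_i (|min_i - n_i| + |max_i - n_i|)` over the N = 4 targeted
#' macronutrients. Inside the target box the penalty is constant and equals
#' the mean range width; outside it grows linearly with distance.
#'
#' @param n_hat Numeric vector of predicted grams per nutrient, or a B x N
#'   matrix for a batch.
#' @param min_g,max_g Numeric vectors (length N) of the range bounds, or
#'   B x N matrices; alternatively pass `targets`.
#' @param targets Optional tibble from [derive_macro_targets()] (overrides
#'   `min_g`/`max_g`).
#' @return Scalar penalty (batch mean for matrix input).
#' @examples
#' macro_penalty(75, min_g = 50, max_g = 100) # 50 = range width
#' @export
macro_penalty <- function(n_hat, min_g = NULL, max_g = NULL, targets = NULL) {
  if (!is.null(targets)) {
    min_g <- targets$min_g
    max_g <- targets$max_g
  }
  n_hat <- rbind(n_hat)
  if (!is.matrix(min_g)) min_g <- matrix(min_g, nrow(n_hat), ncol(n_hat), byrow = TRUE)
  if (!is.matrix(max_g)) max_g <- matrix(max_g, nrow(n_hat), ncol(n_hat), byrow = TRUE)
  per_sample <- rowMeans(abs(min_g - n_hat) + abs(max_g - n_hat))
  mean(per_sample)
}

#' Energy-intake loss
#'
#' Mean squared error between predicted and target energy intake over a batch.
#' During training both sides are in normalized energy units (kcal / 1000) so
#' the term does not dominate the unweighted total loss.
#'
#' @param ei_hat,ei_target Numeric vectors of equal length.
#' @return Scalar MSE.
#' @export
energy_loss <- function(ei_hat, ei_target) {
  if (length(ei_hat) == 0 || length(ei_hat) != length(ei_target)) {
    rlang::abort("ei_hat and ei_target must be equal-length, non-empty",
                 class = "dietvae_contract_error")
  }
  mean((ei_target - ei_hat)^2)
}

#' Kullback-Leibler divergence to the standard normal
#'
#' `-(1/2) * sum_j (1 + log sigma_j^2 - mu_j^2 - sigma_j^2)`, the closed-form
#' KL of a diagonal Gaussian from N(0, I), summed over latent dimensions. For
#' matrix input (one row per sample) the batch mean is returned.
#'
#' @param mu,log_var Numeric vectors (length J) or B x J matrices.
#' @return Scalar divergence (always >= 0).
#' @examples
#' kld(0, 0)    # standard normal: 0
#' kld(1, 0)    # one dimension, mu = 1, sigma = 1: 0.5
#' @export
kld <- function(mu, log_var) {
  mu <- rbind(mu); log_var <- rbind(log_var)
  stopifnot(all(dim(mu) == dim(log_var)))
  per_sample <- -0.5 * rowSums(1 + log_var - mu^2 - exp(log_var))
  mean(per_sample)
}

#' Meal-classification cross-entropy
#'
#' `-sum_t log p_t[true_t]` over the six slots (the one-hot target collapses
#' the inner class sum). Probabilities are floored at `p_floor` before the log.
#' For a batch, `probs` is a list of T B x M matrices and `true_meals` a
#' B x T index matrix; the batch mean is returned.
#'
#' @param probs T x M matrix of per-slot class probabilities (rows sum to 1),
#'   or a list of T B x M matrices.
#' @param true_meals Integer vector of T ground-truth meal ids (1-based), or
#'   B x T matrix.
#' @param p_floor Clamp for zero probabilities (default 1e-12).
#' @return Scalar loss.
#' @export
meal_cross_entropy <- function(probs, true_meals, p_floor = 1e-12) {
  if (is.matrix(probs)) {
    probs <- lapply(seq_len(nrow(probs)), function(t) rbind(probs[t, ]))
    true_meals <- rbind(true_meals)
  }
  true_meals <- rbind(true_meals)
  T_ <- length(probs); B <- nrow(true_meals)
  stopifnot(ncol(true_meals) == T_)
  total <- numeric(B)
  clamped <- FALSE
  for (t in seq_len(T_)) {
    p_true <- probs[[t]][cbind(seq_len(B), true_meals[, t])]
    if (any(p_true < p_floor)) {
      clamped <- TRUE
      p_true <- pmax(p_true, p_floor)
    }
    total <- total - log(p_true)
  }
  if (clamped) rlang::warn("true-class probability clamped at floor")
  mean(total)
}

#' Combine the four loss terms
#'
#' The total training loss is the weighted sum of the meal cross-entropy, the
#' KL divergence, the energy-intake loss and the macronutrient penalty;
#' default weights are all 1, matching the plain sum used in training.
#'
#' @param l_mc,l_kld,l_ei,l_macro Scalar loss terms.
#' @param weights Named numeric vector with entries `mc`, `kld`, `ei`,
#'   `macro`.
#' @return A `loss_bundle` list with the four terms, `weights` and `total`.
#' @export
total_loss <- function(l_mc, l_kld, l_ei, l_macro,
                       weights = c(mc = 1, kld = 1, ei = 1, macro = 1)) {
  stopifnot(all(c("mc", "kld", "ei", "macro") %in% names(weights)))
  structure(list(l_mc = l_mc, l_kld = l_kld, l_ei = l_ei, l_macro = l_macro,
                 weights = weights,
                 total = weights[["mc"]] * l_mc + weights[["kld"]] * l_kld +
                   weights[["ei"]] * l_ei + weights[["macro"]] * l_macro),
            class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf("<loss_bundle> total %.6f (mc %.4f, kld %.4f, ei %.4f, macro %.4f)\n",
              x$total, x$l_mc, x$l_kld, x$l_ei, x$l_macro))
  invisible(x)
}
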
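# Internal numeric helpers shared across modules.

#' The six daily meal slots, in canonical order
#'
#' Breakfast through supper; the decoder's six time steps.
#' @return Character vector of length 6.
#' @export
meal_slots <- function() {
  c("breakfast", "morning snack", "lunch", "afternoon snack", "dinner", "supper")
}

# Row-wise numerically stable softmax; -Inf entries get probability exactly 0.
softmax_rows <- function(logits) {
  finite_max <- apply(logits, 1L, function(r) max(r[is.finite(r)]))
  if (any(!is.finite(finite_max))) {
    stop("softmax_rows: a row has no finite logits (empty admissible set)")
  }
  e <- exp(logits - finite_max)
  e[!is.finite(logits)] <- 0
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Sample from a normal(mean, sd) truncated below at `lower` via inverse CDF.
rtrunc_norm <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  p_lo <- pnorm(lower, mean, sd)
  qnorm(runif(n, p_lo, 1), mean, sd)
}

# Mean and sd of a normal(mu, sigma) truncated below at `lower`.
truncnorm_moments <- function(mu, sigma, lower = 0) {
  a <- (lower - mu) / sigma
  lambda <- dnorm(a) / (1 - pnorm(a)) # hazard of the standard normal at a
  m <- mu + sigma * lambda
  v <- sigma^2 * (1 + a * lambda - lambda^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Find parent (mu, sigma) such that the lower-truncated normal has the target
# mean/sd. Infeasible when target sd/mean is too large (the truncated family's
# coefficient of variation is bounded by 1); returns NULL then.
match_truncnorm <- function(target_mean, target_sd, lower = 0) {
  if (target_sd <= 0 || target_mean <= lower) return(NULL)
  obj <- function(par) {
    mom <- truncnorm_moments(par[1], exp(par[2]), lower)
    (mom["mean"] - target_mean)^2 + (mom["sd"] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  mom <- truncnorm_moments(fit$par[1], exp(fit$par[2]), lower)
  rel_err <- max(abs(mom["mean"] - target_mean) / target_mean,
                 abs(mom["sd"] - target_sd) / target_sd)
  if (!is.finite(rel_err) || rel_err > 1e-3) return(NULL)
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Largest-remainder apportionment of n across proportions p (sums exactly to n).
apportion <- function(n, p) {
  p <- p / sum(p)
  raw <- n * p
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[idx] <- base[idx] + 1L
  }
  as.integer(base)
}

# Derive a 32-bit sub-seed from a base seed and a stream label.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
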
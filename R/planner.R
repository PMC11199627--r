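# Inference: sample daily plans from the latent prior of a profile, assemble
# weekly plans with an anti-repetition mask, and rescale portions so that plan
# energy matches the user's target exactly.

new_daily_plan <- function(meal_ids, db, portion_factor = 1) {
  rows <- db$meals[match(meal_ids, db$meals$meal_id), ]
  nut <- colSums(rbind(as.matrix(rows[, macro_nutrients()])))
  ei_raw <- sum(rows$calories)
  structure(list(
    meal_ids = meal_ids,
    meals = tibble::tibble(slot = meal_slots(), meal_id = meal_ids,
                           name = rows$name, calories = rows$calories),
    portion_factor = portion_factor,
    ei_raw = ei_raw,
    ei_adjusted = portion_factor * ei_raw,
    nutrients_raw = nut,
    nutrients_adjusted = portion_factor * nut
  ), class = "daily_plan")
}

#' @export
print.daily_plan <- function(x, ...) {
  cat(sprintf("<daily_plan> %.0f kcal (portion factor %.3f)\n",
              x$ei_adjusted, x$portion_factor))
  for (i in seq_len(6)) {
    cat(sprintf("  %-16s %s (%.0f kcal)\n", x$meals$slot[i], x$meals$name[i],
                x$meals$calories[i] * x$portion_factor))
  }
  invisible(x)
}

profile_input <- function(profile, bounds) {
  encode_profiles(tibble::as_tibble(profile), bounds)
}

# Weekly mask state: per-slot multiplicative weights on meal probabilities.
new_mask_state <- function(db, lambda = 0) {
  list(weights = rep(1, db$n_meals), lambda = lambda,
       used = lapply(setNames(meal_slots(), meal_slots()), function(s) integer(0)))
}

# Downweight meals chosen today; reset a slot's mask (least-recently-used
# meals restored first, i.e. fully reset) when its unused pool empties.
update_mask_state <- function(state, meal_ids, db) {
  for (i in seq_along(meal_ids)) {
    state$used[[i]] <- c(state$used[[i]], meal_ids[i])
    state$weights[meal_ids[i]] <- state$weights[meal_ids[i]] * state$lambda
  }
  for (s in seq_along(meal_slots())) {
    pool <- db$slot_index[[s]]
    if (all(state$weights[pool] == 0)) {
      state$weights[pool] <- 1
      state$used[[s]] <- integer(0)
    }
  }
  state
}

select_meals <- function(probs, masks, weights) {
  vapply(seq_along(probs), function(t) {
    w <- probs[[t]][1, ] * weights
    w[!masks[[t]]] <- 0
    if (all(w == 0)) { # weekly mask removed every admissible meal: drop it
      w <- probs[[t]][1, ]
      w[!masks[[t]]] <- 0
    }
    which.max(w)
  }, integer(1))
}

#' Generate a daily meal plan
#'
#' Encodes the profile, samples a latent vector from the variational
#' distribution, decodes with slot-type masks (optionally combined with a
#' weekly anti-repetition mask), takes the most probable admissible meal per
#' slot, and computes plan energy/nutrients from the database records of the
#' selected meals (not from the network heads, so the portion optimizer can be
#' exact).
#'
#' @param profile One-row profile tibble.
#' @param checkpoint A checkpoint list ([load_checkpoint()] /
#'   [train_model()]`$checkpoint`).
#' @param db The [meal_db()] (must match the checkpoint vocabulary).
#' @param seed Integer seed for the latent draw.
#' @param mask_state Internal weekly mask state; `NULL` for a fresh day.
#' @return A `daily_plan`.
#' @export
generate_daily <- function(profile, checkpoint, db, seed = 1, mask_state = NULL) {
  if (!identical(checkpoint$vocab_hash, vocab_hash(db))) {
    rlang::abort("checkpoint vocabulary does not match the meal database",
                 class = "dietvae_checkpoint_error")
  }
  x <- profile_input(profile, checkpoint$bounds)
  set.seed(seed)
  eps <- matrix(rnorm(checkpoint$config$latent_dim), 1)
  latent <- vae_encode(checkpoint$params, x, eps)
  masks <- slot_masks(db)
  trace <- vae_decode(checkpoint$params, latent$z, masks, checkpoint$config)
  weights <- if (is.null(mask_state)) rep(1, db$n_meals) else mask_state$weights
  meal_ids <- select_meals(trace$probs, masks, weights)
  new_daily_plan(meal_ids, db)
}

#' Generate a weekly meal plan
#'
#' Seven daily plans from seven independent latent draws. After each day the
#' selected meals' probabilities are multiplied by `lambda` for the rest of
#' the week (`lambda = 0` removes them, guaranteeing within-week slot
#' uniqueness while the slot pool lasts; `lambda = 1` disables masking). When
#' a slot's pool is exhausted mid-week its mask resets. Each plan is then
#' portion-optimized to the profile's target energy intake.
#'
#' @inheritParams generate_daily
#' @param lambda Mask strength in `[0, 1]`; default 0 (hard removal).
#' @param optimize Apply [optimize_portions()] to each day (default `TRUE`).
#' @return A `weekly_plan`: list with `days` (7 `daily_plan`s), `profile`,
#'   `lambda`.
#' @export
generate_weekly <- function(profile, checkpoint, db, seed = 1, lambda = 0,
                            optimize = TRUE) {
  state <- new_mask_state(db, lambda)
  days <- vector("list", 7)
  for (d in seq_len(7)) {
    plan <- generate_daily(profile, checkpoint, db,
                           seed = derive_seed(seed, paste0("day", d)),
                           mask_state = state)
    if (optimize) plan <- optimize_portions(plan, profile$target_ei)
    state <- update_mask_state(state, plan$meal_ids, db)
    days[[d]] <- plan
  }
  structure(list(days = days, profile = profile, lambda = lambda),
            class = "weekly_plan")
}

#' @export
print.weekly_plan <- function(x, ...) {
  cat(sprintf("<weekly_plan> user %s, 7 days, lambda = %g\n",
              x$profile$user_id, x$lambda))
  for (d in seq_len(7)) {
    cat(sprintf("  day %d: %s (%.0f kcal)\n", d,
                paste(x$days[[d]]$meals$name, collapse = " | "),
                x$days[[d]]$ei_adjusted))
  }
  invisible(x)
}

#' Rescale meal portions to match the target energy intake exactly
#'
#' Computes the fractional caloric difference
#' `d = (EI_target - EI_plan) / EI_plan` and multiplies every meal portion by
#' `(1 + d)`, so adjusted plan energy equals the target up to floating-point
#' rounding. All nutrients scale by the same factor (linear nutrient-portion
#' response).
#'
#' @param plan A `daily_plan`.
#' @param ei_target Target energy intake, kcal.
#' @return The adjusted `daily_plan` (with `portion_factor`, `ei_adjusted`,
#'   `nutrients_adjusted` updated and `diff_frac` recorded).
#' @examples
#' \dontrun{optimize_portions(plan, 2000)}
#' @export
optimize_portions <- function(plan, ei_target) {
  stopifnot(inherits(plan, "daily_plan"))
  if (plan$ei_raw <= 0) {
    rlang::abort("plan has non-positive energy; cannot scale portions",
                 class = "dietvae_degenerate_plan_error")
  }
  diff_frac <- (ei_target - plan$ei_raw) / plan$ei_raw
  plan$diff_frac <- diff_frac
  plan$portion_factor <- 1 + diff_frac
  plan$ei_adjusted <- plan$portion_factor * plan$ei_raw
  plan$nutrients_adjusted <- plan$portion_factor * plan$nutrients_raw
  plan
}

#' Export a weekly plan as a plain list (JSON-ready)
#'
#' @param week A `weekly_plan`.
#' @return A nested list with one entry per day: slot, meal name, portion
#'   factor, calories.
#' @export
weekly_plan_export <- function(week) {
  stopifnot(inherits(week, "weekly_plan"))
  list(
    user_id = week$profile$user_id,
    target_ei = week$profile$target_ei,
    lambda = week$lambda,
    days = lapply(week$days, function(p) {
      list(portion_factor = p$portion_factor,
           energy_kcal = p$ei_adjusted,
           meals = lapply(seq_len(6), function(i) {
             list(slot = p$meals$slot[i], name = p$meals$name[i],
                  meal_id = p$meals$meal_id[i],
                  calories = p$meals$calories[i] * p$portion_factor)
           }))
    })
  )
}
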
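# Synthetic stand-in for the expert-curated meal-plan study data: a virtual
# cohort across the ten population groups, a meal database whose per-slot
# energy/macronutrient marginals match published summary statistics, and
# guideline-respecting ground-truth daily plans usable as training labels.

# Per-slot marginal statistics (mean/sd) of the emulated meal database and the
# per-slot meal counts. These ARE the study conditions; change them only to
# emulate a different database.
default_meal_stats <- function() {
  tibble::tribble(
    ~slot, ~n_meals, ~cal_m, ~cal_s, ~prot_m, ~prot_s, ~carb_m, ~carb_s, ~fat_m, ~fat_s, ~sfa_m, ~sfa_s,
    "breakfast",       286L, 423.75, 157.87, 20.07,  9.45, 56.95, 23.50, 14.53,  9.49, 4.24, 3.31,
    "morning snack",   258L, 169.16, 136.85,  7.03,  8.11, 27.22, 22.11,  4.45,  5.84, 1.28, 2.20,
    "lunch",           255L, 543.52, 166.30, 34.85, 16.63, 60.88, 23.51, 18.37,  9.46, 4.64, 3.77,
    "afternoon snack", 253L, 211.94, 144.87,  8.36,  8.22, 31.67, 22.73,  6.67,  7.07, 2.07, 2.83,
    "dinner",          238L, 600.19, 259.45, 37.53, 19.39, 75.58, 49.71, 21.65, 12.38, 6.38, 4.89,
    "supper",           59L, 189.93, 103.24, 10.70,  7.65, 21.21, 15.30,  7.35,  6.60, 2.09, 2.07
  )
}

#' Meal-database simulation spec
#'
#' Per-slot meal counts and mean/sd of calories and each macronutrient.
#' Defaults emulate the reference database (1349 meals:
#' 286/258/255/253/238/59 per slot; e.g. breakfast 423.75 +/- 157.87 kcal).
#'
#' @param stats Tibble in the shape of the default (see source); columns
#'   `slot`, `n_meals`, and `<field>_m`/`<field>_s` for cal/prot/carb/fat/sfa.
#' @param derive_calories Re-derive calories as `4P + 4C + 9F` plus noise
#'   instead of drawing them marginally (default `FALSE`).
#' @param seed Integer seed.
#' @return A `meal_dist_spec` list.
#' @export
meal_dist_spec <- function(stats = default_meal_stats(), derive_calories = FALSE,
                           seed = 1) {
  stopifnot(all(stats$n_meals >= 1),
            all(as.matrix(stats[grep("_s$", names(stats))]) >= 0),
            setequal(stats$slot, meal_slots()))
  structure(list(stats = stats, derive_calories = derive_calories, seed = seed),
            class = "meal_dist_spec")
}

# Draw n values whose truncated-at-0 distribution has approximately the target
# mean/sd: parent parameters are moment-matched where the truncated-normal
# family can achieve them, else fall back to parent = target (mean then biased
# upward; only affects fields with printed CV near or above 1).
draw_matched <- function(n, m, s) {
  if (s <= 0) return(rep(m, n))
  par <- match_truncnorm(m, s)
  if (is.null(par)) rtrunc_norm(n, m, s) else rtrunc_norm(n, par$mu, par$sigma)
}

#' Simulate a meal database
#'
#' Per-slot draws of calories and macronutrients from zero-truncated normals
#' whose post-truncation moments match the spec (see [meal_dist_spec()]);
#' SFA is clipped to total fat; names are auto-generated.
#'
#' @param spec A [meal_dist_spec()].
#' @param n_per_slot Optional scalar or vector overriding the per-slot meal
#'   counts (used by scaled-down experiments).
#' @return A [meal_db()].
#' @export
simulate_meal_db <- function(spec = meal_dist_spec(), n_per_slot = NULL) {
  stopifnot(inherits(spec, "meal_dist_spec"))
  set.seed(spec$seed)
  st <- spec$stats[match(meal_slots(), spec$stats$slot), ]
  counts <- if (is.null(n_per_slot)) st$n_meals else rep(n_per_slot, length.out = 6)
  rows <- lapply(seq_len(6), function(i) {
    n <- counts[i]
    prot <- draw_matched(n, st$prot_m[i], st$prot_s[i])
    carb <- draw_matched(n, st$carb_m[i], st$carb_s[i])
    fat <- draw_matched(n, st$fat_m[i], st$fat_s[i])
    sfa <- pmin(draw_matched(n, st$sfa_m[i], st$sfa_s[i]), fat)
    cal <- if (spec$derive_calories) {
      pmax(0, 4 * prot + 4 * carb + 9 * fat + rnorm(n, 0, 20))
    } else {
      draw_matched(n, st$cal_m[i], st$cal_s[i])
    }
    tibble::tibble(
      name = sprintf("%s %03d", gsub("\\b(\\w)", "\\U\\1", st$slot[i], perl = TRUE),
                     seq_len(n)),
      slot = st$slot[i], calories = cal, protein = prot, carbohydrate = carb,
      fat = fat, sfa = sfa, iron = pmax(0, rnorm(n, 2.5, 1.5)),
      vitamin_c = pmax(0, rnorm(n, 15, 12)), fibre = pmax(0, rnorm(n, 4, 2.5)),
      n_fruits = stats::rbinom(n, 2, 0.25), n_vegetables = stats::rbinom(n, 3, 0.3)
    )
  })
  meal_db(dplyr::bind_rows(rows))
}

#' Cohort simulation spec
#'
#' Group proportions default to the reference cohort's composition
#' (85/158/131/103/92/635/706/766/231/93 over 3000, in [user_groups()]
#' order); anthropometric ranges stay within the population bounds (weight
#' 46-180 kg, height 1.60-2.0 m, ages group-appropriate: adolescents 15-19,
#' older adults 65-88, otherwise 20-88).
#'
#' @param n_users Cohort size.
#' @param group_counts Named (or ordered) integer/numeric vector over
#'   [user_groups()]; interpreted as proportions.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_users = 3000,
                        group_counts = c(85, 158, 131, 103, 92, 635, 706, 766, 231, 93),
                        seed = 1) {
  stopifnot(n_users >= 1, length(group_counts) == 10, all(group_counts >= 0))
  structure(list(n_users = as.integer(n_users),
                 group_props = group_counts / sum(group_counts), seed = seed),
            class = "cohort_spec")
}

group_profile_ranges <- function() {
  # age, PAL and BMI sampling ranges per group; only overweight/obese carry a
  # hard BMI constraint, the rest are plausible defaults.
  tibble::tibble(
    group = user_groups(),
    age_lo = c(20, 15, 65, 20, 20, 20, 20, 20, 20, 20),
    age_hi = c(64, 19, 88, 45, 88, 88, 88, 88, 88, 88),
    pal_lo = c(1.2, 1.3, 1.2, 1.7, 1.2, 1.2, 1.2, 1.2, 1.2, 1.2),
    pal_hi = c(1.6, 1.7, 1.5, 2.2, 1.5, 1.5, 1.5, 1.5, 1.6, 1.6),
    bmi_lo = c(18.5, 16, 18.5, 15, 25, 30, 20, 20, 18.5, 18.5),
    bmi_hi = c(24.9, 24.9, 33, 27, 29.9, 55, 55, 55, 35, 35)
  )
}

#' Simulate a virtual cohort
#'
#' Groups are apportioned exactly by largest remainder (so the default spec at
#' n = 3000 reproduces the reference group counts exactly), sexes alternate
#' within groups for an even split, height is uniform within the population
#' range, BMI is drawn in a group-appropriate range and converted to weight
#' (clipped to 46-180 kg and BMI recomputed), BMR is Mifflin-St Jeor, and the
#' target energy intake follows [compute_energy_target()].
#'
#' @param spec A [cohort_spec()].
#' @param rule An [energy_rule()].
#' @return A validated profile tibble.
#' @export
simulate_profiles <- function(spec = cohort_spec(), rule = energy_rule()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  counts <- apportion(spec$n_users, spec$group_props)
  rng <- group_profile_ranges()
  rows <- lapply(seq_len(10), function(gi) {
    n <- counts[gi]
    if (n == 0) return(NULL)
    g <- rng[gi, ]
    height <- runif(n, 1.60, 2.0)
    bmi_draw <- runif(n, g$bmi_lo, g$bmi_hi)
    weight <- pmin(180, pmax(46, bmi_draw * height^2))
    age <- round(runif(n, g$age_lo, g$age_hi))
    pal <- runif(n, g$pal_lo, g$pal_hi)
    sex <- rep(c("male", "female"), length.out = n)
    flags <- group_flags(g$group)
    tibble::tibble(
      group = g$group, weight = weight, height = height, age = age,
      sex = sex, pal = pal,
      has_cvd = flags$has_cvd, has_t2d = flags$has_t2d,
      has_iron_def = flags$has_iron_def
    )
  })
  out <- dplyr::bind_rows(rows)
  out$user_id <- sprintf("U%04d", seq_len(nrow(out)))
  out$bmi <- compute_bmi(out$weight, out$height)
  out$bmr <- mifflin_st_jeor(out$weight, out$height, out$age, out$sex)
  out$target_ei <- compute_energy_target(out$bmr, out$pal, out$bmi, rule)
  out <- out[, c("user_id", "weight", "height", "age", "sex", "bmr", "pal",
                 "bmi", "group", "has_cvd", "has_t2d", "has_iron_def",
                 "target_ei")]
  validate_profiles(out)
  out
}

#' Assemble ground-truth daily plans
#'
#' A randomized greedy search standing in for expert-built plans: the target
#' energy is split across slots in proportion to the slot mean calories; per
#' slot, the best of a random candidate subset (closest calories to the slot
#' budget) is picked; a plan is accepted when its energy is within
#' `tol` of the target. Labels therefore correlate with the profile's energy
#' target by construction, giving the model a learnable signal.
#'
#' @param profiles Profile tibble.
#' @param db A [meal_db()].
#' @param days_per_user Plans per profile (default 28: 7 days x 4 weeks).
#' @param seed Integer seed.
#' @param tol Relative energy tolerance for acceptance (default 0.10).
#' @param max_tries Retries per plan before keeping the best effort.
#' @param n_candidates Candidate subset size per slot per try.
#' @return Tibble with columns `user_id`, `day`, `m1`..`m6` (meal ids in slot
#'   order), `kcal`, `rel_err`, `accepted`.
#' @export
assemble_truth_plans <- function(profiles, db, days_per_user = 28, seed = 1,
                                 tol = 0.10, max_tries = 20, n_candidates = 12) {
  stopifnot(inherits(db, "meal_db"))
  set.seed(seed)
  shares <- default_meal_stats()$cal_m
  shares <- shares / sum(shares)
  cal <- db$meals$calories
  pools <- db$slot_index
  n_prof <- nrow(profiles)
  res <- vector("list", n_prof * days_per_user)
  k <- 0L
  for (i in seq_len(n_prof)) {
    ei <- profiles$target_ei[i]
    budgets <- ei * shares
    for (day in seq_len(days_per_user)) {
      best <- NULL; best_err <- Inf
      for (try in seq_len(max_tries)) {
        ids <- integer(6)
        for (t in 1:6) {
          pool <- pools[[t]]
          cand <- if (length(pool) > n_candidates) {
            pool[sample.int(length(pool), n_candidates)]
          } else pool
          ids[t] <- cand[which.min(abs(cal[cand] - budgets[t]))]
        }
        err <- abs(sum(cal[ids]) - ei) / ei
        if (err < best_err) { best <- ids; best_err <- err }
        if (best_err <= tol) break
      }
      k <- k + 1L
      res[[k]] <- c(i, day, best, sum(cal[best]), best_err)
    }
  }
  m <- do.call(rbind, res)
  tibble::tibble(
    user_id = profiles$user_id[m[, 1]], day = as.integer(m[, 2]),
    m1 = as.integer(m[, 3]), m2 = as.integer(m[, 4]), m3 = as.integer(m[, 5]),
    m4 = as.integer(m[, 6]), m5 = as.integer(m[, 7]), m6 = as.integer(m[, 8]),
    kcal = m[, 9], rel_err = m[, 10], accepted = m[, 10] <= tol
  )
}
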
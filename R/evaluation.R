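# Evaluation surface: caloric difference, macronutrient accuracy, weekly
# variability, and the latent-space export with a cluster-separation score.

#' Absolute percent caloric difference
#'
#' `100 * |target - plan_energy| / target`. Zero iff the plan matches the
#' target exactly — which [optimize_portions()] guarantees.
#'
#' @param plan_energy,target kcal (vectorized).
#' @return Percent difference (>= 0).
#' @export
caloric_difference <- function(plan_energy, target) {
  stopifnot(all(target > 0))
  100 * abs(target - plan_energy) / target
}

#' Macronutrient accuracy
#'
#' Per nutrient: 100 when the intake lies inside the recommended gram range;
#' outside, accuracy falls linearly with the relative distance to the nearest
#' bound, floored at 0: `100 * max(0, 1 - dist / nearest_bound)`. A value
#' outside a zero bound scores 0. A second, coarser variant — the fraction of
#' values inside the range — is reported alongside by [evaluate_plans()].
#'
#' @param n Numeric vector of intakes (grams), or matrix (rows = days/users).
#' @param min_g,max_g Range bounds, recycled across rows.
#' @param targets Optional tibble from [derive_macro_targets()].
#' @return Accuracy in \[0, 100\], same shape as `n`.
#' @export
macro_accuracy <- function(n, min_g = NULL, max_g = NULL, targets = NULL) {
  if (!is.null(targets)) {
    min_g <- targets$min_g
    max_g <- targets$max_g
  }
  n_mat <- if (is.matrix(n)) n else matrix(n, nrow = 1)
  lo <- matrix(min_g, nrow(n_mat), ncol(n_mat), byrow = !is.matrix(min_g))
  hi <- matrix(max_g, nrow(n_mat), ncol(n_mat), byrow = !is.matrix(max_g))
  below <- n_mat < lo
  above <- n_mat > hi
  dist <- ifelse(below, lo - n_mat, ifelse(above, n_mat - hi, 0))
  bound <- ifelse(below, lo, hi)
  acc <- ifelse(dist == 0, 100,
                ifelse(bound <= 0, 0, 100 * pmax(0, 1 - dist / bound)))
  if (is.matrix(n)) acc else unname(drop(acc))
}

#' Weekly meal variability
#'
#' On the 1-7 scale: plan-level variability counts distinct daily plans in the
#' week (1 = one plan repeated, 7 = every day unique); per-slot variability
#' counts distinct meals in that slot across the 7 days.
#'
#' @param week A `weekly_plan` from [generate_weekly()].
#' @return List with `plan_level` (scalar) and `per_slot` (named length-6
#'   vector).
#' @export
weekly_variability <- function(week) {
  stopifnot(inherits(week, "weekly_plan"), length(week$days) == 7)
  ids <- t(vapply(week$days, function(p) p$meal_ids, integer(6)))
  plan_level <- nrow(unique(ids))
  per_slot <- apply(ids, 2, function(col) length(unique(col)))
  list(plan_level = plan_level,
       per_slot = setNames(per_slot, meal_slots()))
}

#' Export latent means for a set of profiles
#'
#' Writes the posterior mean of each profile (no sampling noise) together
#' with its group label, for downstream 2-D embedding (e.g. t-SNE) and
#' cluster diagnostics.
#'
#' @param profiles Profile tibble.
#' @param checkpoint Model checkpoint.
#' @return Tibble with `user_id`, `group` and `mu_1..mu_d` columns.
#' @export
export_latent <- function(profiles, checkpoint) {
  x <- encode_profiles(profiles, checkpoint$bounds)
  eps <- matrix(0, nrow(x), checkpoint$config$latent_dim)
  latent <- vae_encode(checkpoint$params, x, eps)
  mu <- latent$mu
  colnames(mu) <- paste0("mu_", seq_len(ncol(mu)))
  dplyr::bind_cols(tibble::tibble(user_id = profiles$user_id,
                                  group = profiles$group),
                   tibble::as_tibble(mu))
}

#' Cluster separation of groups in the latent space
#'
#' Mean silhouette width of the group labels on the latent means (Euclidean
#' distance). Compare against [latent_silhouette()] on permuted labels to
#' judge whether grouping structure is real.
#'
#' @param latent_tbl Output of [export_latent()].
#' @param permute Permute the labels (fixed by `seed`) to obtain a null
#'   baseline.
#' @param seed Seed for the permutation.
#' @return Mean silhouette width (in \[-1, 1\]).
#' @export
latent_silhouette <- function(latent_tbl, permute = FALSE, seed = 1) {
  mu <- as.matrix(latent_tbl[grep("^mu_", names(latent_tbl))])
  labels <- latent_tbl$group
  if (permute) {
    set.seed(seed)
    labels <- sample(labels)
  }
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(mu))
  mean(sil[, "sil_width"])
}

#' Evaluate weekly plans against profile targets
#'
#' Per user and overall: mean/sd percent caloric difference across the 7 days,
#' per-nutrient macronutrient accuracy (both the graded bounded-distance
#' definition of [macro_accuracy()] and the in-range-fraction variant), and
#' the two variability scores.
#'
#' @param weeks List of `weekly_plan` objects.
#' @param guidelines Guideline policy for macro targets.
#' @return List with `per_user` tibble and `summary` (named list of overall
#'   means/sds).
#' @export
evaluate_plans <- function(weeks, guidelines = default_guidelines()) {
  rows <- lapply(weeks, function(wk) {
    prof <- wk$profile
    tg <- derive_macro_targets(prof$target_ei, prof$group, guidelines)
    cal <- vapply(wk$days, function(p) p$ei_adjusted, numeric(1))
    cd <- caloric_difference(cal, prof$target_ei)
    nut <- t(vapply(wk$days, function(p) p$nutrients_adjusted, numeric(4)))
    acc <- macro_accuracy(nut, tg$min_g, tg$max_g)
    in_range <- 100 * colMeans(sweep(nut, 2, tg$min_g, ">=") &
                                 sweep(nut, 2, tg$max_g, "<="))
    vb <- weekly_variability(wk)
    tibble::tibble(
      user_id = prof$user_id, group = prof$group,
      caloric_diff_mean = mean(cd), caloric_diff_sd = sd(cd),
      acc_protein = mean(acc[, 1]), acc_carbohydrate = mean(acc[, 2]),
      acc_fat = mean(acc[, 3]), acc_sfa = mean(acc[, 4]),
      acc_average = mean(acc),
      in_range_protein = in_range[1], in_range_carbohydrate = in_range[2],
      in_range_fat = in_range[3], in_range_sfa = in_range[4],
      variability_plan = vb$plan_level,
      variability_slot_mean = mean(vb$per_slot)
    )
  })
  per_user <- dplyr::bind_rows(rows)
  summary <- list(
    caloric_diff_mean = mean(per_user$caloric_diff_mean),
    caloric_diff_sd = stats::sd(
      unlist(lapply(weeks, function(wk) {
        caloric_difference(vapply(wk$days, function(p) p$ei_adjusted, numeric(1)),
                           wk$profile$target_ei)
      }))),
    macro_accuracy_average = mean(per_user$acc_average),
    variability_plan_mean = mean(per_user$variability_plan),
    variability_slot_mean = mean(per_user$variability_slot_mean)
  )
  list(per_user = per_user, summary = summary)
}
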
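#' Default guideline policy
#'
#' Loads the bundled YAML of percent-of-energy macronutrient ranges (protein
#' 10-20 %E, carbohydrate 45-60 %E, fat 20-35 %E, SFA 0-10 %E), Atwater
#' conversion factors and per-group overrides (stricter SFA cap for CVD,
#' narrower carbohydrate range for T2D). Pass a different YAML path to audit or
#' replace the policy.
#'
#' @param path YAML file; defaults to the bundled policy.
#' @return A list with elements `energy_rule`, `atwater`,
#'   `macro_ranges_pct_energy`, `group_overrides`.
#' @export
default_guidelines <- function(path = system.file("extdata", "guidelines.yaml",
                                                  package = "dietvae")) {
  g <- yaml::read_yaml(path)
  need <- c("atwater", "macro_ranges_pct_energy")
  if (!all(need %in% names(g))) {
    rlang::abort("guideline config must contain 'atwater' and 'macro_ranges_pct_energy'",
                 class = "dietvae_config_error")
  }
  for (nm in names(g$macro_ranges_pct_energy)) {
    r <- g$macro_ranges_pct_energy[[nm]]
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0) {
      rlang::abort(sprintf("malformed guideline range for '%s'", nm),
                   class = "dietvae_config_error")
    }
  }
  g
}

#' Nutrients targeted by the guideline losses
#' @return `c("protein", "carbohydrate", "fat", "sfa")`.
#' @export
macro_nutrients <- function() c("protein", "carbohydrate", "fat", "sfa")

#' Daily gram ranges for the four macronutrients
#'
#' Converts the configured percent-of-energy ranges into gram/day ranges for a
#' given target energy intake using Atwater factors (4 kcal/g protein and
#' carbohydrate, 9 kcal/g fat and SFA), applying any group-specific override.
#' The mapping is linear in `target_ei`.
#'
#' @param target_ei Target energy intake, kcal/day (scalar).
#' @param group Population group label (for overrides); `NULL` for defaults.
#' @param guidelines A guideline policy from [default_guidelines()].
#' @return A tibble with columns `nutrient`, `min_g`, `max_g` (4 rows, in
#'   [macro_nutrients()] order).
#' @examples
#' derive_macro_targets(2000)
#' @export
derive_macro_targets <- function(target_ei, group = NULL,
                                 guidelines = default_guidelines()) {
  stopifnot(length(target_ei) == 1, target_ei >= 0)
  ranges <- guidelines$macro_ranges_pct_energy
  if (!is.null(group) && group %in% names(guidelines$group_overrides %||% list())) {
    ranges <- modifyList(ranges, guidelines$group_overrides[[group]])
  }
  nutr <- macro_nutrients()
  if (!all(nutr %in% names(ranges))) {
    rlang::abort("guideline ranges must cover protein, carbohydrate, fat, sfa",
                 class = "dietvae_config_error")
  }
  kcal_per_g <- unname(unlist(guidelines$atwater[nutr]))
  lo <- vapply(nutr, function(n) ranges[[n]][1], numeric(1), USE.NAMES = FALSE)
  hi <- vapply(nutr, function(n) ranges[[n]][2], numeric(1), USE.NAMES = FALSE)
  tibble::tibble(
    nutrient = nutr,
    min_g = lo / 100 * target_ei / kcal_per_g,
    max_g = hi / 100 * target_ei / kcal_per_g
  )
}

#' Default normalization bounds
#'
#' Fixed population min/max used to scale continuous profile fields to
#' \[0, 1\] before encoding.
#'
#' @param path YAML file; defaults to the bundled bounds.
#' @return Named list of `c(min, max)` pairs.
#' @export
default_bounds <- function(path = system.file("extdata", "normalization.yaml",
                                              package = "dietvae")) {
  yaml::read_yaml(path)
}

# Field order of the encoder input vector.
profile_fields <- function() {
  c("weight", "height", "bmr", "age", "bmi", "target_ei", "pal",
    "has_cvd", "has_t2d", "has_iron_def")
}

#' Encode profiles as the network input matrix
#'
#' Min-max normalizes the seven continuous fields (weight, height, BMR, age,
#' BMI, target energy intake, PAL) by the fixed population bounds, clips to
#' \[0, 1\], and appends the three 0/1 disease flags, giving one length-10 row
#' per profile in a fixed field order.
#'
#' @param profiles Profile tibble.
#' @param bounds Normalization bounds from [default_bounds()].
#' @return Numeric matrix `n x 10` with rownames `user_id`.
#' @export
encode_profiles <- function(profiles, bounds = default_bounds()) {
  validate_profiles(profiles)
  fields <- profile_fields()
  cont <- fields[1:7]
  missing <- setdiff(cont, names(bounds))
  if (length(missing) > 0) {
    rlang::abort(paste0("normalization bounds missing: ", paste(missing, collapse = ", ")),
                 class = "dietvae_config_error")
  }
  x <- matrix(0, nrow(profiles), length(fields),
              dimnames = list(profiles$user_id, fields))
  for (f in cont) {
    b <- bounds[[f]]
    x[, f] <- pmin(1, pmax(0, (profiles[[f]] - b[1]) / (b[2] - b[1])))
  }
  x[, "has_cvd"] <- as.numeric(profiles$has_cvd)
  x[, "has_t2d"] <- as.numeric(profiles$has_t2d)
  x[, "has_iron_def"] <- as.numeric(profiles$has_iron_def)
  x
}
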
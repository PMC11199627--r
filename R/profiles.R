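#' Body mass index
#'
#' @param weight Body weight in kg (vectorized).
#' @param height Height in metres (vectorized).
#' @return BMI in kg/m^2. Displays conventionally round to 2 decimals.
#' @examples
#' compute_bmi(68, 1.73)
#' @export
compute_bmi <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) {
    rlang::abort("weight and height must be positive", class = "dietvae_domain_error")
  }
  weight / height^2
}

#' Energy-adjustment rule for the target energy intake
#'
#' The factorial estimate of daily energy expenditure (BMR x PAL) is shifted by
#' a fixed amount `d_adjust` for users outside the normal BMI band, so that
#' underweight users gain and overweight/obese users lose weight.
#'
#' @param d_adjust Adjustment in kcal/day (default 500, the value used for all
#'   reported experiments).
#' @param bmi_low,bmi_high BMI thresholds (default 18.5 and 25 kg/m^2). The
#'   low branch applies at `bmi <= bmi_low`, the high branch at
#'   `bmi >= bmi_high`.
#' @return An object of class `energy_rule`.
#' @export
energy_rule <- function(d_adjust = 500, bmi_low = 18.5, bmi_high = 25) {
  stopifnot(d_adjust >= 0, bmi_low < bmi_high)
  structure(list(d_adjust = d_adjust, bmi_low = bmi_low, bmi_high = bmi_high),
            class = "energy_rule")
}

#' Target daily energy intake
#'
#' `EI = BMR*PAL + D` if `BMI <= 18.5`; `BMR*PAL` if `18.5 < BMI < 25`;
#' `BMR*PAL - D` if `BMI >= 25`.
#'
#' @param bmr Basal metabolic rate, kcal/day (vectorized).
#' @param pal Physical activity level multiplier (vectorized).
#' @param bmi Body mass index, kg/m^2 (vectorized).
#' @param rule An [energy_rule()].
#' @return Target energy intake, kcal/day.
#' @examples
#' compute_energy_target(1596.83, 1.195, 22.72)
#' @export
compute_energy_target <- function(bmr, pal, bmi, rule = energy_rule()) {
  stopifnot(inherits(rule, "energy_rule"))
  base <- bmr * pal
  ifelse(bmi <= rule$bmi_low, base + rule$d_adjust,
         ifelse(bmi >= rule$bmi_high, base - rule$d_adjust, base))
}

#' Mifflin-St Jeor basal metabolic rate
#'
#' @param weight kg; @param height m; @param age years
#' @param sex "male" or "female" (vectorized).
#' @return BMR in kcal/day.
#' @export
mifflin_st_jeor <- function(weight, height, age, sex) {
  10 * weight + 6.25 * (height * 100) - 5 * age + ifelse(sex == "male", 5, -161)
}

#' The ten population groups
#'
#' @return Character vector of the ten user-group labels, in the canonical
#'   order used throughout (healthy groups first, then excess weight, then
#'   medical conditions).
#' @export
user_groups <- function() {
  c("Healthy adults", "Healthy adolescents", "Healthy older adults",
    "Athletes", "Adults who are overweight", "Adults who are obese",
    "Adults with CVD", "Adults with T2D", "Adults with iron deficiency",
    "Adults with low fruit & veg")
}

group_flags <- function(group) {
  list(has_cvd = group == "Adults with CVD",
       has_t2d = group == "Adults with T2D",
       has_iron_def = group == "Adults with iron deficiency")
}

#' Validate a profile table
#'
#' Checks the structural invariants of a cohort tibble: positive
#' anthropometrics, `pal >= 1`, cached BMI consistent with weight/height
#' (within 0.005), positive energy target, and disease flags consistent with
#' the group label.
#'
#' @param profiles A tibble as produced by [simulate_profiles()] or
#'   [read_profiles_csv()].
#' @return The validated tibble, invisibly. Errors describe the first
#'   violating row.
#' @export
validate_profiles <- function(profiles) {
  req <- c("user_id", "weight", "height", "age", "sex", "bmr", "pal", "bmi",
           "group", "has_cvd", "has_t2d", "has_iron_def", "target_ei")
  missing <- setdiff(req, names(profiles))
  if (length(missing) > 0) {
    rlang::abort(paste0("profiles missing columns: ", paste(missing, collapse = ", ")),
                 class = "dietvae_validation_error")
  }
  fail <- function(cond, what) {
    if (any(cond)) {
      rlang::abort(sprintf("profile row %d: %s", which(cond)[1], what),
                   class = "dietvae_validation_error")
    }
  }
  fail(profiles$weight <= 0, "weight must be positive")
  fail(profiles$height <= 0, "height must be positive")
  fail(profiles$pal < 1.0, "pal must be >= 1.0")
  fail(abs(profiles$bmi - compute_bmi(profiles$weight, profiles$height)) > 0.005,
       "cached BMI inconsistent with weight/height")
  fail(profiles$target_ei <= 0, "target_ei must be positive")
  fail(profiles$group == "Adults with CVD" & !profiles$has_cvd,
       "CVD group requires has_cvd")
  fail(profiles$group == "Adults with T2D" & !profiles$has_t2d,
       "T2D group requires has_t2d")
  fail(profiles$group == "Adults with iron deficiency" & !profiles$has_iron_def,
       "iron-deficiency group requires has_iron_def")
  invisible(profiles)
}

#' Read a profile CSV
#'
#' Reads the 11-column cohort schema (User ID, Weight, Height, PAL, BMI, BMR,
#' Age, Iron Deficiency, T2D, Heart disease, Subgroup). BMI is recomputed from
#' weight/height (the file's 2-decimal BMI column is kept as `bmi_reported`)
#' and the target energy intake is derived via [compute_energy_target()]. The
#' schema does not carry sex; the column is left `NA` unless present.
#'
#' @param path CSV path.
#' @param rule [energy_rule()] used to derive `target_ei`.
#' @return A validated profile tibble.
#' @export
read_profiles_csv <- function(path, rule = energy_rule()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, name_repair = "minimal")
  names(raw) <- tolower(trimws(names(raw)))
  need <- c("user id", "weight", "height", "pal", "bmi", "bmr", "age",
            "iron deficiency", "t2d", "heart disease", "subgroup")
  if (!all(need %in% names(raw))) {
    rlang::abort(paste0("profile CSV missing columns: ",
                        paste(setdiff(need, names(raw)), collapse = ", ")),
                 class = "dietvae_format_error")
  }
  yes <- function(x) tolower(trimws(as.character(x))) %in% c("yes", "true", "1")
  out <- tibble::tibble(
    user_id = as.character(raw[["user id"]]),
    weight = as.numeric(raw$weight),
    height = as.numeric(raw$height),
    age = as.numeric(raw$age),
    sex = if ("sex" %in% names(raw)) tolower(raw$sex) else NA_character_,
    bmr = as.numeric(raw$bmr),
    pal = as.numeric(raw$pal),
    bmi = compute_bmi(as.numeric(raw$weight), as.numeric(raw$height)),
    bmi_reported = as.numeric(raw$bmi),
    group = as.character(raw$subgroup),
    has_cvd = yes(raw[["heart disease"]]),
    has_t2d = yes(raw$t2d),
    has_iron_def = yes(raw[["iron deficiency"]])
  )
  out$target_ei <- compute_energy_target(out$bmr, out$pal, out$bmi, rule)
  validate_profiles(out)
  out
}

#' Write a profile CSV in the canonical 11-column schema
#'
#' @param profiles Profile tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  out <- tibble::tibble(
    `User ID` = profiles$user_id,
    Weight = profiles$weight,
    Height = profiles$height,
    PAL = profiles$pal,
    BMI = round(profiles$bmi, 2),
    BMR = round(profiles$bmr, 2),
    Age = profiles$age,
    `Iron Deficiency` = ifelse(profiles$has_iron_def, "Yes", "No"),
    T2D = ifelse(profiles$has_t2d, "Yes", "No"),
    `Heart disease` = ifelse(profiles$has_cvd, "Yes", "No"),
    Subgroup = profiles$group
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Bundled demo cohort
#'
#' Twenty user profiles spanning the ten population groups (two per group),
#' with printed BMI/BMR values; handy for examples and for checking BMI
#' arithmetic against an independently tabulated column.
#'
#' @return A validated profile tibble of 20 rows.
#' @export
demo_profiles <- function() {
  read_profiles_csv(system.file("extdata", "demo_profiles.csv", package = "dietvae"))
}
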
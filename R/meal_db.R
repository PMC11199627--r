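# Meal records and the 12-column CSV schema:
#   Meal name, Meal type, Calories, Protein, Carbohydrates, Fat,
#   Saturated Fat, Iron, Vitamin C, Fibre, Number of fruits, Number of vegetables
# Nutrient fields describe the reference portion (base_portion = 1.0); all
# portion scaling downstream is multiplicative.

meal_csv_headers <- function() {
  c("Meal name", "Meal type", "Calories", "Protein", "Carbohydrates", "Fat",
    "Saturated Fat", "Iron", "Vitamin C", "Fibre", "Number of fruits",
    "Number of vegetables")
}

meal_numeric_cols <- function() {
  c("calories", "protein", "carbohydrate", "fat", "sfa", "iron", "vitamin_c",
    "fibre", "n_fruits", "n_vegetables")
}

# Map tolerant lowercase header -> internal name
meal_header_map <- function() {
  c("meal name" = "name", "meal type" = "slot", "calories" = "calories",
    "protein" = "protein", "carbohydrates" = "carbohydrate", "fat" = "fat",
    "saturated fat" = "sfa", "iron" = "iron", "vitamin c" = "vitamin_c",
    "fibre" = "fibre", "number of fruits" = "n_fruits",
    "number of vegetables" = "n_vegetables")
}

#' Construct a meal database
#'
#' Validates meal records (non-negative nutrients, SFA not exceeding total fat,
#' slot one of the six types), assigns dense `meal_id` 1..M, and indexes meals
#' by slot. Every slot must be represented.
#'
#' @param meals A data frame with columns `name`, `slot`, `calories`,
#'   `protein`, `carbohydrate`, `fat`, `sfa`, `iron`, `vitamin_c`, `fibre`,
#'   `n_fruits`, `n_vegetables` (missing micronutrient columns default to 0).
#' @param drop_invalid Drop rows violating invariants with a warning
#'   (default), instead of erroring.
#' @return A `meal_db` object: list with `meals` (tibble incl. `meal_id`),
#'   `slot_index` (named list of meal_id vectors), `n_meals`.
#' @export
meal_db <- function(meals, drop_invalid = TRUE) {
  meals <- tibble::as_tibble(meals)
  for (col in meal_numeric_cols()) {
    if (!col %in% names(meals)) meals[[col]] <- 0
    meals[[col]] <- suppressWarnings(as.numeric(meals[[col]]))
  }
  meals$slot <- tolower(trimws(as.character(meals$slot)))
  bad <- !meals$slot %in% meal_slots() |
    !stats::complete.cases(meals[meal_numeric_cols()]) |
    rowSums(as.matrix(meals[meal_numeric_cols()]) < 0) > 0 |
    meals$sfa > meals$fat
  if (any(bad)) {
    msg <- sprintf("dropping %d invalid meal row(s): %s", sum(bad),
                   paste(which(bad), collapse = ", "))
    if (!drop_invalid) rlang::abort(msg, class = "dietvae_validation_error")
    rlang::warn(msg)
    meals <- meals[!bad, , drop = FALSE]
  }
  if (nrow(meals) == 0) {
    rlang::abort("meal database is empty after validation",
                 class = "dietvae_validation_error")
  }
  meals <- meals[order(match(meals$slot, meal_slots())), , drop = FALSE]
  meals$meal_id <- seq_len(nrow(meals))
  if (!"base_portion" %in% names(meals)) meals$base_portion <- 1.0
  missing_slots <- setdiff(meal_slots(), unique(meals$slot))
  if (length(missing_slots) > 0) {
    rlang::abort(paste0("no meals for slot(s): ", paste(missing_slots, collapse = ", ")),
                 class = "dietvae_validation_error")
  }
  slot_index <- lapply(setNames(meal_slots(), meal_slots()),
                       function(s) meals$meal_id[meals$slot == s])
  structure(list(meals = meals, slot_index = slot_index, n_meals = nrow(meals)),
            class = "meal_db")
}

#' @export
print.meal_db <- function(x, ...) {
  counts <- vapply(x$slot_index, length, integer(1))
  cat("<meal_db> ", x$n_meals, " meals (",
      paste(sprintf("%s: %d", names(counts), counts), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Read a meal CSV
#'
#' Header matching is case-insensitive and whitespace-tolerant. Rows violating
#' the record invariants (negative nutrients, SFA > fat, unknown slot) are
#' rejected with a line-numbered warning.
#'
#' @param path CSV path.
#' @return A [meal_db()].
#' @export
read_meal_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "dietvae_format_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, name_repair = "minimal",
                         progress = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  map <- meal_header_map()
  missing <- setdiff(names(map), names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("meal CSV missing header(s): ", paste(missing, collapse = ", ")),
                 class = "dietvae_format_error")
  }
  meals <- setNames(raw[names(map)], unname(map))
  for (extra in c("equivalent_of", "cuisine")) {
    if (extra %in% names(raw)) meals[[extra]] <- raw[[extra]]
  }
  meal_db(meals)
}

#' Write a meal database as CSV
#'
#' Emits the canonical 12-column schema; `equivalent_of`/`cuisine` columns are
#' appended when present (expanded databases).
#'
#' @param db A [meal_db()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meal_csv <- function(db, path) {
  stopifnot(inherits(db, "meal_db"))
  meal_rows_to_csv(db$meals, path)
}

# Row-level writer shared with partial outputs (e.g. parsed equivalents that
# do not cover every slot and so cannot form a full database).
meal_rows_to_csv <- function(m, path) {
  out <- tibble::tibble(
    `Meal name` = m$name, `Meal type` = m$slot, Calories = m$calories,
    Protein = m$protein, Carbohydrates = m$carbohydrate, Fat = m$fat,
    `Saturated Fat` = m$sfa, Iron = m$iron, `Vitamin C` = m$vitamin_c,
    Fibre = m$fibre, `Number of fruits` = m$n_fruits,
    `Number of vegetables` = m$n_vegetables
  )
  for (extra in c("equivalent_of", "cuisine")) {
    if (extra %in% names(m)) out[[extra]] <- m[[extra]]
  }
  readr::write_csv(out, path)
  invisible(path)
}

# Matrix of per-meal energy/macros used by planner and evaluation.
meal_nutrient_matrix <- function(db) {
  m <- as.matrix(db$meals[, c("calories", macro_nutrients())])
  rownames(m) <- db$meals$meal_id
  m
}

# Fingerprint of the vocabulary for checkpoint compatibility checks.
vocab_hash <- function(db) {
  rlang::hash(list(db$meals$name, db$meals$slot, db$n_meals))
}
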
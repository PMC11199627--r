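# Equivalent-meal database expansion. The LLM sits behind a provider
# interface: the package builds the prompts and parses CSV responses, and
# ships only an offline mock provider; live API calls are out of scope.

#' Build the two-stage equivalent-meal prompt
#'
#' Stage one sets the role: the model is presented as "FoodAI", a system
#' proficient at recommending meals and knowledgeable about world cuisines,
#' and is asked to acknowledge with "FoodAI is ready". Stage two is the
#' per-meal query embedding the meal's nutrition facts and demanding CSV
#' output with the exact 12 headers.
#'
#' @param meal One row of `meal_db()$meals` (or any list with `name`, `slot`
#'   and the nutrient fields).
#' @param cuisines Non-empty character vector of cuisines to draw from.
#' @param n_equivalents Number of equivalent meals to request per cuisine.
#' @return List with elements `role_prompt` and `meal_prompt` (character).
#' @export
build_equivalence_prompt <- function(meal, cuisines, n_equivalents = 1) {
  if (length(cuisines) == 0) {
    rlang::abort("at least one cuisine is required", class = "dietvae_argument_error")
  }
  role_prompt <- paste(
    "You are FoodAI, an AI system proficient at recommending meals and",
    "knowledgeable about many world cuisines. Your task is to propose",
    "equivalent meals from specified cuisines that match a reference meal's",
    "ingredients, nutrition facts and calories. Reply exactly with",
    "\"FoodAI is ready\" to acknowledge.")
  facts <- sprintf(
    "%s: %.2f", c("Calories", "Protein", "Carbohydrates", "Fat",
                  "Saturated Fat", "Iron", "Vitamin C", "Fibre"),
    c(meal$calories, meal$protein, meal$carbohydrate, meal$fat, meal$sfa,
      meal$iron, meal$vitamin_c, meal$fibre))
  meal_prompt <- paste0(
    "Reference meal (", meal$slot, "): ", meal$name, ". Nutrition facts: ",
    paste(facts, collapse = ", "),
    ", Number of fruits: ", meal$n_fruits,
    ", Number of vegetables: ", meal$n_vegetables, ". ",
    "Propose ", n_equivalents, " equivalent meal(s) from each of these cuisines: ",
    paste(cuisines, collapse = ", "),
    ", with similar ingredients, nutrition facts and calories. ",
    "Answer only with CSV using exactly these headers: ",
    paste(meal_csv_headers(), collapse = ", "), ".")
  list(role_prompt = role_prompt, meal_prompt = meal_prompt)
}

#' Parse an equivalent-meal CSV response
#'
#' Tolerant parser for LLM responses purporting to be CSV: strips code fences
#' and prose lines before the header, locates the header row, and drops rows
#' with non-numeric nutrient values (with a warning). The slot of every parsed
#' meal is coerced to `expected_slot`, since equivalents substitute for the
#' queried meal.
#'
#' @param response_text Character scalar (possibly multi-line) or vector of lines.
#' @param expected_slot Slot of the queried meal.
#' @return Tibble of valid meal rows (possibly empty, with a warning).
#' @export
parse_equivalents <- function(response_text, expected_slot) {
  stopifnot(expected_slot %in% meal_slots())
  lines <- unlist(strsplit(paste(response_text, collapse = "\n"), "\n"))
  lines <- lines[!grepl("^\\s*```", lines)]
  header_re <- "^\\s*\"?meal name\"?\\s*,"
  hdr <- grep(header_re, tolower(lines))
  if (length(hdr) == 0) {
    rlang::warn("no CSV header found in response; returning 0 meals")
    return(tibble::tibble())
  }
  block <- lines[hdr[1]:length(lines)]
  block <- block[nzchar(trimws(block))]
  raw <- tryCatch(
    readr::read_csv(I(paste(block, collapse = "\n")), show_col_types = FALSE,
                    name_repair = "minimal", progress = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0) {
    rlang::warn("response CSV had no parseable rows")
    return(tibble::tibble())
  }
  names(raw) <- tolower(trimws(names(raw)))
  map <- meal_header_map()
  keep <- intersect(names(map), names(raw))
  if (!"meal name" %in% keep) {
    rlang::warn("response CSV lacks a 'Meal name' column")
    return(tibble::tibble())
  }
  meals <- setNames(raw[keep], unname(map[keep]))
  for (col in meal_numeric_cols()) {
    if (!col %in% names(meals)) meals[[col]] <- 0
    meals[[col]] <- suppressWarnings(as.numeric(meals[[col]]))
  }
  meals$slot <- expected_slot
  bad <- !stats::complete.cases(meals[meal_numeric_cols()]) |
    rowSums(as.matrix(meals[meal_numeric_cols()]) < 0) > 0 |
    meals$sfa > meals$fat
  if (any(bad)) {
    rlang::warn(sprintf("dropping %d invalid equivalent row(s)", sum(bad)))
    meals <- meals[!bad, , drop = FALSE]
  }
  if ("cuisine" %in% names(raw)) meals$cuisine <- raw$cuisine[!bad]
  tibble::as_tibble(meals)
}

#' Offline mock of the equivalent-meal provider
#'
#' Stands in for the LLM so the expansion pipeline is testable without
#' network: returns a renamed copy of the meal whose calories and nutrients
#' are the originals plus Gaussian noise of configurable per-field standard
#' deviation, truncated at zero (and SFA clipped to fat).
#'
#' @param meal One meal row (list-like with the nutrient fields).
#' @param jitter Named numeric vector of per-field standard deviations; fields
#'   among `calories`, `protein`, `carbohydrate`, `fat`, `sfa` (missing fields
#'   get 0). Default approximates observed LLM equivalence spread (protein
#'   ~6.7 g, carbohydrates ~12.6 g, fat ~5.2 g, SFA ~2.7 g, calories ~25 kcal).
#' @param cuisine Label recorded on the generated meal.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A one-row tibble in meal-record form with `equivalent_of` and
#'   `cuisine` set.
#' @export
mock_equivalents <- function(meal,
                             jitter = c(calories = 25, protein = 6.7,
                                        carbohydrate = 12.64, fat = 5.19,
                                        sfa = 2.74),
                             cuisine = "International", seed = 1) {
  stopifnot(all(jitter >= 0))
  fields <- c("calories", "protein", "carbohydrate", "fat", "sfa")
  jit <- setNames(rep(0, length(fields)), fields)
  jit[names(jitter)[names(jitter) %in% fields]] <-
    jitter[names(jitter) %in% fields]
  out <- tibble::tibble(
    name = paste0(cuisine, " equivalent of ", meal$name),
    slot = meal$slot,
    calories = meal$calories, protein = meal$protein,
    carbohydrate = meal$carbohydrate, fat = meal$fat, sfa = meal$sfa,
    iron = meal$iron, vitamin_c = meal$vitamin_c, fibre = meal$fibre,
    n_fruits = meal$n_fruits, n_vegetables = meal$n_vegetables,
    equivalent_of = meal$meal_id %||% NA_integer_,
    cuisine = cuisine
  )
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  for (f in fields) {
    out[[f]] <- max(0, out[[f]] + rnorm(1, 0, jit[f]))
  }
  out$sfa <- min(out$sfa, out$fat)
  out
}

#' Expand a meal database with mock equivalents
#'
#' Applies [mock_equivalents()] to every meal, producing one equivalent per
#' meal per cuisine with per-meal derived seeds.
#'
#' @param db A [meal_db()].
#' @inheritParams mock_equivalents
#' @param cuisines Character vector of cuisines.
#' @return A [meal_db()] of the equivalents (with `equivalent_of` mapping back
#'   to the original `meal_id`).
#' @export
mock_expand_db <- function(db, cuisines = "International",
                           jitter = c(calories = 25, protein = 6.7,
                                      carbohydrate = 12.64, fat = 5.19,
                                      sfa = 2.74),
                           seed = 1) {
  rows <- list()
  for (cu in cuisines) {
    for (i in seq_len(db$n_meals)) {
      rows[[length(rows) + 1]] <- mock_equivalents(
        db$meals[i, ], jitter = jitter, cuisine = cu,
        seed = derive_seed(seed, paste0(cu, "/", i)))
    }
  }
  meal_db(dplyr::bind_rows(rows))
}

#' Nutrient differences between an expanded database and the originals
#'
#' For each nutrient and for calories, the mean and standard deviation of
#' (equivalent - original) across matched meal pairs. Matching is by the
#' `equivalent_of` back-reference of the expanded database (falling back to
#' `meal_id` when absent).
#'
#' @param original,equivalent [meal_db()] objects.
#' @return Tibble with columns `field`, `mean_diff`, `sd_diff`, `n_pairs`.
#' @export
equivalence_report <- function(original, equivalent) {
  stopifnot(inherits(original, "meal_db"), inherits(equivalent, "meal_db"))
  eq <- equivalent$meals
  ref_id <- if ("equivalent_of" %in% names(eq)) eq$equivalent_of else eq$meal_id
  idx <- match(ref_id, original$meals$meal_id)
  ok <- !is.na(idx)
  if (!any(ok)) {
    rlang::abort("no matched meal pairs between databases",
                 class = "dietvae_empty_report_error")
  }
  fields <- c("calories", macro_nutrients())
  diffs <- as.matrix(eq[ok, fields]) - as.matrix(original$meals[idx[ok], fields])
  tibble::tibble(
    field = fields,
    mean_diff = unname(colMeans(diffs)),
    sd_diff = unname(apply(diffs, 2, function(v) if (length(v) > 1) sd(v) else 0)),
    n_pairs = sum(ok)
  )
}
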
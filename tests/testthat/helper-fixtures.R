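# Fixtures are built in code: no data files needed.

# A deterministic small database: `per_slot` meals per slot with spread-out
# calories so energy-based selection is meaningful.
tiny_db <- function(per_slot = 3) {
  rows <- lapply(seq_along(meal_slots()), function(si) {
    s <- meal_slots()[si]
    k <- seq_len(per_slot)
    tibble::tibble(
      name = paste(s, k), slot = s,
      calories = 100 + 40 * si + 60 * (k - 1),
      protein = 5 + 2 * si + k, carbohydrate = 20 + 3 * si + 2 * k,
      fat = 4 + si + k, sfa = 1 + 0.3 * k,
      iron = 1, vitamin_c = 5, fibre = 2, n_fruits = 0, n_vegetables = 1
    )
  })
  meal_db(dplyr::bind_rows(rows))
}

# One meal per slot with the given calories (planted-solution scenarios).
one_per_slot_db <- function(kcals = c(400, 150, 550, 200, 600, 180)) {
  meal_db(tibble::tibble(
    name = paste("only", meal_slots()), slot = meal_slots(),
    calories = kcals, protein = 20, carbohydrate = 50, fat = 10, sfa = 3,
    iron = 1, vitamin_c = 5, fibre = 2, n_fruits = 0, n_vegetables = 1
  ))
}

toy_profile <- function(user_id = "T01", weight = 68, height = 1.73, age = 41,
                        pal = 1.195, group = "Healthy adults") {
  bmi <- compute_bmi(weight, height)
  bmr <- mifflin_st_jeor(weight, height, age, "male")
  tibble::tibble(
    user_id = user_id, weight = weight, height = height, age = age,
    sex = "male", bmr = bmr, pal = pal, bmi = bmi, group = group,
    has_cvd = group == "Adults with CVD", has_t2d = group == "Adults with T2D",
    has_iron_def = group == "Adults with iron deficiency",
    target_ei = compute_energy_target(bmr, pal, bmi)
  )
}

small_config <- function(db, latent_dim = 16, hidden = 24) {
  model_config(vocab_size = db$n_meals, encoder_hidden = 24,
               latent_dim = latent_dim, decoder_layers = 2,
               decoder_hidden = hidden)
}

# Untrained checkpoint usable by the planner.
quick_checkpoint <- function(db, seed = 1, ...) {
  cfg <- small_config(db, ...)
  list(params = init_params(cfg, seed = seed), config = cfg,
       bounds = default_bounds(), vocab_hash = dietvae:::vocab_hash(db),
       n_meals = db$n_meals)
}
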
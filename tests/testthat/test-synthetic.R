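test_that("cohort apportionment reproduces the reference group counts exactly", {
  profs <- simulate_profiles(cohort_spec(n_users = 3000, seed = 1))
  counts <- table(factor(profs$group, levels = user_groups()))
  expect_equal(unname(c(counts)), c(85, 158, 131, 103, 92, 635, 706, 766, 231, 93))
  expect_equal(nrow(profs), 3000)
})

test_that("simulated profiles respect group constraints and internal consistency", {
  profs <- simulate_profiles(cohort_spec(n_users = 600, seed = 2))
  expect_true(all(abs(profs$bmi - profs$weight / profs$height^2) < 0.005))
  expect_true(all(profs$weight >= 46 & profs$weight <= 180))
  expect_true(all(profs$height >= 1.60 & profs$height <= 2.0))
  byg <- split(profs, profs$group)
  expect_true(all(byg[["Adults who are obese"]]$bmi >= 30))
  ow <- byg[["Adults who are overweight"]]$bmi
  expect_true(all(ow >= 25 & ow < 30))
  expect_true(all(byg[["Healthy adolescents"]]$age >= 15 &
                    byg[["Healthy adolescents"]]$age <= 19))
  expect_true(all(byg[["Healthy older adults"]]$age >= 65))
  expect_true(all(byg[["Athletes"]]$pal >= 1.7))
  expect_true(all(byg[["Adults with CVD"]]$has_cvd))
  # sexes equally split within each group (within rounding)
  for (g in names(byg)) {
    expect_lte(abs(sum(byg[[g]]$sex == "male") - nrow(byg[[g]]) / 2), 0.5)
  }
})

test_that("profile generation is a pure function of the spec seed", {
  a <- simulate_profiles(cohort_spec(n_users = 40, seed = 9))
  b <- simulate_profiles(cohort_spec(n_users = 40, seed = 9))
  expect_identical(a, b)
  path_a <- withr::local_tempfile(fileext = ".csv")
  path_b <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(a, path_a); write_profiles_csv(b, path_b)
  expect_identical(readLines(path_a), readLines(path_b))
  c_ <- simulate_profiles(cohort_spec(n_users = 40, seed = 10))
  expect_false(identical(a$weight, c_$weight))
})

test_that("simulated meal marginals match the configured slot statistics", {
  db <- simulate_meal_db(meal_dist_spec(seed = 1))
  stats <- dietvae:::default_meal_stats()
  expect_equal(db$n_meals, sum(stats$n_meals)) # 1349
  counts <- vapply(db$slot_index, length, integer(1))
  expect_equal(unname(counts[stats$slot]), as.integer(stats$n_meals))
  for (i in seq_len(6)) {
    sl <- db$meals[db$meals$slot == stats$slot[i], ]
    sem <- stats$cal_s[i] / sqrt(stats$n_meals[i])
    expect_lt(abs(mean(sl$calories) - stats$cal_m[i]), 3 * sem)
  }
  # nothing negative anywhere
  expect_true(all(as.matrix(db$meals[dietvae:::meal_numeric_cols()]) >= 0))
  expect_true(all(db$meals$sfa <= db$meals$fat))
})

test_that("zero-spread specs make identical meals and draws stay non-negative", {
  stats <- dietvae:::default_meal_stats()
  stats[grep("_s$", names(stats))] <- 0
  db <- simulate_meal_db(meal_dist_spec(stats = stats, seed = 3), n_per_slot = 5)
  br <- db$meals[db$meals$slot == "breakfast", ]
  expect_true(all(br$calories == br$calories[1]))
  expect_true(all(br$protein == br$protein[1]))
  # large-n truncation check on the highest-variance slot
  many <- dietvae:::rtrunc_norm(1e5, 169.16, 136.85)
  expect_true(all(many >= 0))
})

test_that("truth plans hit the energy target and find planted solutions", {
  profs <- simulate_profiles(cohort_spec(n_users = 12, seed = 4))
  db <- simulate_meal_db(meal_dist_spec(seed = 5), n_per_slot = 15)
  plans <- assemble_truth_plans(profs, db, days_per_user = 3, seed = 6)
  expect_equal(nrow(plans), 36)
  expect_true(all(plans$rel_err[plans$accepted] <= 0.10))
  expect_gt(mean(plans$accepted), 0.9)
  # planted solution: a one-meal-per-slot db summing exactly to the target
  prof <- toy_profile()
  share <- prof$target_ei * c(0.2, 0.1, 0.25, 0.1, 0.25, 0.1)
  planted <- one_per_slot_db(kcals = share)
  found <- assemble_truth_plans(prof, planted, days_per_user = 1, seed = 7)
  expect_identical(unlist(found[1, paste0("m", 1:6)], use.names = FALSE), 1:6)
  expect_equal(found$rel_err, 0)
  # reproducible under the seed
  again <- assemble_truth_plans(profs, db, days_per_user = 3, seed = 6)
  expect_identical(plans, again)
})
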
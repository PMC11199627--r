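test_that("compute_bmi matches hand values and rejects bad input", {
  expect_equal(round(compute_bmi(68, 1.73), 2), 22.72)
  expect_equal(compute_bmi(100, 2.0), 25)
  expect_equal(round(compute_bmi(130, 1.64), 2), 48.33)
  expect_error(compute_bmi(0, 1.7), class = "dietvae_domain_error")
  expect_error(compute_bmi(70, -1), class = "dietvae_domain_error")
})

test_that("energy target follows the three BMI branches", {
  # middle branch: plain BMR x PAL
  expect_equal(compute_energy_target(1596.83, 1.195, 22.72), 1908.21, tolerance = 1e-5)
  # high branch: minus D
  expect_equal(compute_energy_target(1980.25, 1.195, 48.33), 1866.40, tolerance = 1e-5)
  # boundary cases use <= 18.5 and >= 25
  expect_equal(compute_energy_target(1000, 1.5, 18.5), 1500 + 500)
  expect_equal(compute_energy_target(1000, 1.5, 25), 1500 - 500)
})

test_that("energy target is a step function with jumps of exactly D", {
  rule <- energy_rule(d_adjust = 500)
  bmi <- seq(15, 40, by = 0.01)
  ei <- compute_energy_target(2000, 1.2, bmi, rule)
  base <- 2000 * 1.2
  in_low <- bmi <= 18.5; in_mid <- bmi > 18.5 & bmi < 25; in_high <- bmi >= 25
  # mutually exclusive and exhaustive
  expect_true(all(in_low + in_mid + in_high == 1))
  expect_true(all(ei[in_low] == base + 500))
  expect_true(all(ei[in_mid] == base))
  expect_true(all(ei[in_high] == base - 500))
})

test_that("macro targets convert %E ranges through Atwater factors", {
  tg <- derive_macro_targets(2000)
  carb <- tg[tg$nutrient == "carbohydrate", ]
  expect_equal(c(carb$min_g, carb$max_g), c(225, 300))
  sfa <- tg[tg$nutrient == "sfa", ]
  expect_equal(sfa$max_g, 0.10 * 2000 / 9, tolerance = 1e-12)
  expect_equal(sfa$min_g, 0)
  # homogeneous of degree 1 in EI; zero EI collapses all ranges
  tg2 <- derive_macro_targets(4000)
  expect_equal(tg2$min_g, 2 * tg$min_g)
  expect_equal(tg2$max_g, 2 * tg$max_g)
  tg0 <- derive_macro_targets(0)
  expect_true(all(tg0$min_g == 0 & tg0$max_g == 0))
})

test_that("group overrides tighten ranges", {
  tg_cvd <- derive_macro_targets(2000, group = "Adults with CVD")
  expect_equal(tg_cvd$max_g[tg_cvd$nutrient == "sfa"], 0.07 * 2000 / 9)
  tg_t2d <- derive_macro_targets(2000, group = "Adults with T2D")
  expect_equal(tg_t2d$min_g[tg_t2d$nutrient == "carbohydrate"], 0.40 * 2000 / 4)
})

test_that("profile encoding normalizes to [0,1] in a stable field order", {
  p <- toy_profile()
  bounds <- default_bounds()
  x <- encode_profiles(p, bounds)
  expect_equal(dim(x), c(1, 10))
  expect_true(all(x >= 0 & x <= 1))
  expect_identical(colnames(x), dietvae:::profile_fields())
  # bounds map to exactly 0 and 1
  p_lo <- toy_profile(weight = 46); p_hi <- toy_profile(weight = 180)
  expect_equal(unname(encode_profiles(p_lo, bounds)[1, "weight"]), 0)
  expect_equal(unname(encode_profiles(p_hi, bounds)[1, "weight"]), 1)
  # flags are the trailing 0/1 entries
  p_cvd <- toy_profile(group = "Adults with CVD")
  expect_equal(unname(encode_profiles(p_cvd, bounds)[1, 8:10]), c(1, 0, 0))
  # idempotent: same input, same vector
  expect_identical(encode_profiles(p, bounds), x)
  # missing bound is a config error
  expect_error(encode_profiles(p, bounds[-1]), class = "dietvae_config_error")
})

test_that("profile CSV round-trips through the 11-column schema", {
  profs <- simulate_profiles(cohort_spec(n_users = 25, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(profs, path)
  back <- read_profiles_csv(path)
  expect_equal(nrow(back), 25)
  expect_equal(back$weight, profs$weight)
  expect_equal(back$group, profs$group)
  expect_equal(back$has_cvd, profs$has_cvd)
  # target EI re-derived consistently (BMI is re-computed from weight/height)
  expect_equal(back$target_ei, profs$target_ei, tolerance = 1e-3)
})

test_that("profile validation catches inconsistent rows", {
  p <- toy_profile()
  p$bmi <- p$bmi + 1
  expect_error(validate_profiles(p), class = "dietvae_validation_error")
  p2 <- toy_profile(group = "Adults with CVD")
  p2$has_cvd <- FALSE
  expect_error(validate_profiles(p2), class = "dietvae_validation_error")
  p3 <- toy_profile()
  p3$pal <- 0.9
  expect_error(validate_profiles(p3), class = "dietvae_validation_error")
})
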
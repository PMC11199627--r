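test_that("caloric difference is the absolute percent deviation", {
  expect_equal(caloric_difference(2000, 2000), 0)
  expect_equal(caloric_difference(1600, 2000), 20)
  expect_equal(caloric_difference(2400, 2000), 20) # symmetric
  expect_true(all(caloric_difference(runif(20, 500, 4000), 2000) >= 0))
})

test_that("macro accuracy is 100 on the box and degrades with relative distance", {
  expect_equal(macro_accuracy(75, 50, 100), 100)
  expect_equal(macro_accuracy(50, 50, 100), 100) # bounds inclusive
  expect_equal(macro_accuracy(110, 50, 100), 90)
  expect_equal(macro_accuracy(25, 50, 100), 50)
  # outside a zero bound scores 0
  expect_equal(macro_accuracy(5, 0, 0), 0)
  # continuous and non-increasing away from the box
  v <- seq(100, 300, by = 1)
  acc <- vapply(v, function(x) macro_accuracy(x, 50, 100), numeric(1))
  expect_true(all(diff(acc) <= 0))
  expect_true(all(acc >= 0 & acc <= 100))
  # floored at zero far away
  expect_equal(macro_accuracy(1000, 50, 100), 0)
  # vectorized across the four nutrients
  tg <- derive_macro_targets(2000)
  acc4 <- macro_accuracy(c(80, 260, 50, 15), targets = tg)
  expect_length(acc4, 4)
  expect_equal(acc4[2], 100) # 260 g carbohydrate inside [225, 300]
})

test_that("weekly variability counts distinct plans and distinct slot meals", {
  db <- tiny_db(8)
  ck <- quick_checkpoint(db)
  wk <- generate_weekly(toy_profile(), ck, db, seed = 3, lambda = 0)
  # construct degenerate weeks by editing the days
  wk_same <- wk
  for (d in 2:7) wk_same$days[[d]] <- wk_same$days[[1]]
  v1 <- weekly_variability(wk_same)
  expect_equal(v1$plan_level, 1)
  expect_true(all(v1$per_slot == 1))
  v7 <- weekly_variability(wk)
  expect_equal(v7$plan_level, 7)
  expect_true(all(v7$per_slot == 7))
  # (A,A,B,B,C,C,C) pattern gives 3 distinct daily plans
  wk_abc <- wk
  pat <- c(1, 1, 2, 2, 3, 3, 3)
  for (d in 1:7) wk_abc$days[[d]] <- wk$days[[pat[d]]]
  expect_equal(weekly_variability(wk_abc)$plan_level, 3)
  # permutation invariance over days
  wk_perm <- wk_abc
  ord <- c(4, 1, 7, 3, 6, 2, 5)
  for (d in 1:7) wk_perm$days[[d]] <- wk_abc$days[[ord[d]]]
  expect_equal(weekly_variability(wk_perm)$plan_level, 3)
  expect_equal(weekly_variability(wk_perm)$per_slot,
               weekly_variability(wk_abc)$per_slot)
})

test_that("latent export carries one row per profile with stable means", {
  db <- tiny_db(3)
  ck <- quick_checkpoint(db)
  profs <- simulate_profiles(cohort_spec(n_users = 15, seed = 14))
  lat <- export_latent(profs, ck)
  expect_equal(nrow(lat), 15)
  expect_equal(sum(grepl("^mu_", names(lat))), ck$config$latent_dim)
  # identical profiles map to identical latent means
  two <- dplyr::bind_rows(toy_profile("X1"), toy_profile("X2"))
  lat2 <- export_latent(two, ck)
  expect_equal(unlist(lat2[1, -(1:2)]), unlist(lat2[2, -(1:2)]),
               ignore_attr = TRUE)
})

test_that("plan evaluation summarizes caloric, macro and variability metrics", {
  db <- tiny_db(8)
  ck <- quick_checkpoint(db)
  profs <- simulate_profiles(cohort_spec(n_users = 5, seed = 16))
  weeks <- lapply(seq_len(nrow(profs)), function(i) {
    generate_weekly(profs[i, ], ck, db, seed = i)
  })
  ev <- evaluate_plans(weeks)
  expect_equal(nrow(ev$per_user), 5)
  expect_equal(ev$summary$caloric_diff_mean, 0, tolerance = 1e-9)
  expect_equal(ev$summary$caloric_diff_sd, 0, tolerance = 1e-9)
  expect_true(all(ev$per_user$acc_average >= 0 & ev$per_user$acc_average <= 100))
  expect_true(all(ev$per_user$variability_plan >= 1 &
                    ev$per_user$variability_plan <= 7))
  expect_equal(ev$summary$variability_slot_mean, 7) # hard mask, 8 meals/slot
})
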
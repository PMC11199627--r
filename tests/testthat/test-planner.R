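test_that("daily generation is deterministic, slot-ordered and correctly typed", {
  db <- tiny_db(3)
  ck <- quick_checkpoint(db)
  prof <- toy_profile()
  p1 <- generate_daily(prof, ck, db, seed = 5)
  p2 <- generate_daily(prof, ck, db, seed = 5)
  expect_identical(p1$meal_ids, p2$meal_ids)
  expect_identical(p1$meals$slot, meal_slots())
  slot_of <- db$meals$slot[match(p1$meal_ids, db$meals$meal_id)]
  expect_identical(slot_of, meal_slots())
  # energy bookkeeping from database values
  expect_equal(p1$ei_raw, sum(db$meals$calories[match(p1$meal_ids, db$meals$meal_id)]))
  # mismatched vocabulary is refused
  expect_error(generate_daily(prof, ck, tiny_db(2), seed = 1),
               class = "dietvae_checkpoint_error")
})

test_that("a one-meal-per-slot database forces that plan", {
  db <- one_per_slot_db()
  ck <- quick_checkpoint(db)
  p <- generate_daily(toy_profile(), ck, db, seed = 3)
  expect_identical(p$meal_ids, 1:6)
})

test_that("portion optimizer zeroes the caloric difference exactly", {
  db <- one_per_slot_db(kcals = c(400, 150, 450, 200, 300, 100)) # 1600 kcal
  ck <- quick_checkpoint(db)
  plan <- generate_daily(toy_profile(), ck, db, seed = 1)
  adj <- optimize_portions(plan, 2000)
  expect_equal(adj$diff_frac, 0.25)
  expect_equal(adj$portion_factor, 1.25)
  expect_equal(adj$ei_adjusted, 2000)
  # nutrients scale by the same factor (linearity contract)
  expect_equal(adj$nutrients_adjusted, 1.25 * plan$nutrients_raw)
  # a plan already on target is unchanged
  same <- optimize_portions(plan, plan$ei_raw)
  expect_equal(same$portion_factor, 1)
  expect_equal(same$ei_adjusted, plan$ei_raw)
})

test_that("optimizer exactness holds over a batch of generated plans", {
  db <- tiny_db(4)
  ck <- quick_checkpoint(db)
  profs <- simulate_profiles(cohort_spec(n_users = 30, seed = 8))
  cd <- vapply(seq_len(nrow(profs)), function(i) {
    plan <- generate_daily(profs[i, ], ck, db, seed = i)
    adj <- optimize_portions(plan, profs$target_ei[i])
    abs(adj$ei_adjusted - profs$target_ei[i]) / profs$target_ei[i]
  }, numeric(1))
  expect_lt(max(cd), 1e-9)
})

test_that("degenerate zero-energy plans are refused by the optimizer", {
  db <- one_per_slot_db(kcals = rep(0, 6))
  ck <- quick_checkpoint(db)
  plan <- generate_daily(toy_profile(), ck, db, seed = 1)
  expect_error(optimize_portions(plan, 2000),
               class = "dietvae_degenerate_plan_error")
})

test_that("hard weekly masking forces within-week slot uniqueness", {
  db <- tiny_db(8) # 8 meals per slot > 7 days
  ck <- quick_checkpoint(db)
  wk <- generate_weekly(toy_profile(), ck, db, seed = 2, lambda = 0)
  expect_length(wk$days, 7)
  ids <- t(vapply(wk$days, function(p) p$meal_ids, integer(6)))
  for (t in 1:6) expect_equal(length(unique(ids[, t])), 7)
})

test_that("lambda = 1 disables masking and repeats are allowed", {
  db <- tiny_db(8)
  ck <- quick_checkpoint(db)
  wk <- generate_weekly(toy_profile(), ck, db, seed = 2, lambda = 1,
                        optimize = FALSE)
  ids <- t(vapply(wk$days, function(p) p$meal_ids, integer(6)))
  # unmasked decoding of the same profile is driven only by the latent draw;
  # with an untrained model most days repeat the argmax plan
  expect_lt(mean(apply(ids, 2, function(col) length(unique(col)))), 7)
})

test_that("slot pool exhaustion resets the mask instead of failing", {
  db <- tiny_db(3) # 3 meals per slot < 7 days
  ck <- quick_checkpoint(db)
  wk <- generate_weekly(toy_profile(), ck, db, seed = 4, lambda = 0)
  ids <- t(vapply(wk$days, function(p) p$meal_ids, integer(6)))
  for (t in 1:6) {
    # days 1-3 exhaust the pool without repetition, then the mask resets
    expect_equal(length(unique(ids[1:3, t])), 3)
    expect_equal(length(unique(ids[, t])), 3)
  }
})

test_that("weekly plans are portion-optimized per day and exportable", {
  db <- tiny_db(8)
  ck <- quick_checkpoint(db)
  prof <- toy_profile()
  wk <- generate_weekly(prof, ck, db, seed = 6)
  for (d in 1:7) {
    expect_equal(wk$days[[d]]$ei_adjusted, prof$target_ei, tolerance = 1e-12)
  }
  ex <- weekly_plan_export(wk)
  expect_length(ex$days, 7)
  expect_equal(ex$target_ei, prof$target_ei)
  expect_length(ex$days[[1]]$meals, 6)
})
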
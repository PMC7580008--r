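test_that("generation is deterministic given the seed and honors counts", {
  cfg <- synthetic_config(n_children = 8, n_adults = 30, seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$recalls, b$recalls)

  expect_equal(sum(!a$subjects$is_child), 30)
  expect_equal(sum(a$subjects$is_child), 8)
  days <- dplyr::count(a$recalls, subject_id, day)
  expect_equal(nrow(days), 2 * 38) # every subject has exactly two days
  expect_true(all(days$n >= 3 & days$n <= 8)) # meals always present

  c_ <- generate_cohort(synthetic_config(n_children = 8, n_adults = 30, seed = 124))
  expect_false(identical(a$recalls$energy, c_$recalls$energy))
})

test_that("generated data satisfy every recall-table invariant", {
  coh <- small_cohort(seed = 77, n_children = 20, n_adults = 80)
  expect_silent(validate_recalls(coh$recalls))
  expect_silent(validate_subjects(coh$subjects))
  expect_true(all(coh$recalls$time >= 0 & coh$recalls$time <= 1439))
  expect_true(all(coh$recalls[, c("energy", "fruit", "vegetables", "fiber")] >= 0))
  # main meals present on every day
  meals <- coh$recalls |>
    dplyr::filter(label %in% meal_labels()) |>
    dplyr::count(subject_id, day)
  expect_true(all(meals$n == 3))
})

test_that("with couplings off the energy marginal matches its target", {
  cfg <- synthetic_config(
    n_children = 0, n_adults = 20000, seed = 42,
    lunch_time_trad = 0,
    meal_energy_trad = c(lunch = 0, dinner = 0, after_dinner_snack = 0),
    energy_pct_coupling = 0, fv_gap = 0,
    nonfv_slope_weights = c(fiber = 0, sugar = 0, satfat = 0, sodium = 0),
    age_couplings = c(fv = 0, fiber = 0, sugar = 0, satfat = 0, sodium = 0),
    female_couplings = c(fv = 0, fiber = 0, sugar = 0, satfat = 0, sodium = 0)
  )
  cfg$z_slope <- 0
  coh <- generate_cohort(cfg)
  si <- subject_intake(coh$recalls)
  expect_lt(abs(mean(si$energy) - 2265) / 2265, 0.01)
})

test_that("lunch is the largest meal in expectation under defaults", {
  coh <- generate_cohort(synthetic_config(n_children = 0, n_adults = 10000, seed = 7))
  by_meal <- coh$recalls |>
    dplyr::filter(label %in% meal_labels()) |>
    dplyr::group_by(label) |>
    dplyr::summarise(m = mean(energy), .groups = "drop")
  m <- setNames(by_meal$m, by_meal$label)
  expect_gt(m[["lunch"]], m[["dinner"]])
  expect_gt(m[["lunch"]], m[["breakfast"]])
  # dinner and breakfast comparable (within 15% of each other)
  expect_lt(abs(m[["dinner"]] - m[["breakfast"]]) / m[["breakfast"]], 0.15)
})

test_that("the day-to-day lunch jitter reproduces a ~24-minute mean gap", {
  coh <- generate_cohort(synthetic_config(n_children = 0, n_adults = 4000, seed = 19))
  lc <- lunch_consistency(coh$recalls)
  expect_lt(abs(mean(lc$lunch_day_gap, na.rm = TRUE) - 24), 2)
})

test_that("a stronger fruit+veg coupling widens the early-late gap", {
  gaps <- sapply(c(0, 60, 120), function(g) {
    cfg <- synthetic_config(n_children = 0, n_adults = 4000, seed = 11, fv_gap = g)
    coh <- generate_cohort(cfg)
    si <- subject_intake(coh$recalls)
    early <- si$pct_energy_before_cutoff >= 60
    mean(si$fruit_veg[early]) - mean(si$fruit_veg[!early])
  })
  expect_true(all(diff(gaps) > 0))
})

test_that("adult nutrient marginals are near their configured targets", {
  coh <- generate_cohort(synthetic_config(n_children = 0, n_adults = 20000, seed = 3))
  si <- subject_intake(coh$recalls)
  tg <- nutrient_targets(FALSE)
  expect_lt(abs(mean(si$fruit_veg) - tg$fruit_veg[1]) / tg$fruit_veg[1], 0.05)
  expect_lt(abs(sd(si$fruit_veg) - tg$fruit_veg[2]) / tg$fruit_veg[2], 0.10)
  expect_lt(abs(mean(si$fiber_density) - tg$fiber_density[1]) / tg$fiber_density[1], 0.05)
  expect_lt(abs(mean(si$saturated_fat_pct) - tg$saturated_fat_pct[1]) / tg$saturated_fat_pct[1], 0.05)
  expect_lt(abs(mean(si$sugar_pct) - tg$sugar_pct[1]) / tg$sugar_pct[1], 0.05)
  expect_lt(abs(mean(si$sodium) - tg$sodium[1]) / tg$sodium[1], 0.05)
  expect_lt(abs(mean(si$energy_density) - tg$energy_density[1]) / tg$energy_density[1], 0.05)
})

test_that("adult BMI correlates with age near the configured 0.4", {
  coh <- generate_cohort(synthetic_config(n_children = 0, n_adults = 20000, seed = 29))
  s <- coh$subjects[!is.na(coh$subjects$bmi), ]
  rho <- dq_spearman(s$age, s$bmi)$rho
  expect_lt(abs(rho - 0.4), 0.05)
})

test_that("null couplings recover a null slope and gap", {
  cfg <- synthetic_config(
    n_children = 0, n_adults = 260, seed = 500,
    lunch_time_trad = 0,
    meal_energy_trad = c(lunch = 0, dinner = 0, after_dinner_snack = 0),
    energy_pct_coupling = 0, fv_gap = 0,
    nonfv_slope_weights = c(fiber = 0.25, sugar = 0.25, satfat = 0.25, sodium = 0.25),
    age_couplings = c(fv = 0, fiber = 0, sugar = 0, satfat = 0, sodium = 0),
    female_couplings = c(fv = 0, fiber = 0, sugar = 0, satfat = 0, sodium = 0)
  )
  cfg$z_slope <- 0
  rec <- recovery_report(cfg, n_replicates = 30, include_meal_model = FALSE)
  s <- rec$summary
  slope_row <- s[s$quantity == "z_slope_adjusted", ]
  gap_row <- s[s$quantity == "fv_gap", ]
  expect_lt(abs(slope_row$mean), 3 * slope_row$mc_se)
  expect_lt(abs(gap_row$mean), 3 * gap_row$mc_se)
})
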
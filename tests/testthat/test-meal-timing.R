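test_that("percent of energy before the cutoff follows the pooled definition", {
  # 600 kcal at 9:00 + 400 kcal at 20:00, both days -> 60%
  r <- two_meal_subject()
  expect_equal(pct_energy_before(r)$pct_energy_before_cutoff, 60)

  # strict "before": an occasion starting exactly at the cutoff is late
  at_cutoff <- dplyr::bind_rows(lapply(1:2, function(d) {
    occ_row("S1", d, "lunch", 960, energy = 500)
  }))
  expect_equal(pct_energy_before(at_cutoff)$pct_energy_before_cutoff, 0)

  all_early <- dplyr::bind_rows(lapply(1:2, function(d) {
    occ_row("S1", d, "breakfast", 540, energy = 300)
  }))
  expect_equal(pct_energy_before(all_early)$pct_energy_before_cutoff, 100)
})

test_that("pooled and per-day percent agree on identical days but differ otherwise", {
  r <- two_meal_subject()
  expect_equal(
    pct_energy_before(r, method = "per_day")$pct_energy_before_cutoff, 60
  )
  uneven <- dplyr::bind_rows(
    occ_row("S1", 1, "breakfast", 540, energy = 900),
    occ_row("S1", 1, "dinner", 1200, energy = 100),
    occ_row("S1", 2, "breakfast", 540, energy = 100),
    occ_row("S1", 2, "dinner", 1200, energy = 900)
  )
  expect_equal(pct_energy_before(uneven)$pct_energy_before_cutoff, 50)
  expect_equal(
    pct_energy_before(uneven, method = "per_day")$pct_energy_before_cutoff,
    mean(c(90, 10))
  )
})

test_that("percent before cutoff is monotone in the cutoff and 100 at 24:00", {
  coh <- small_cohort(seed = 13, n_children = 2, n_adults = 20)
  cuts <- seq(300, 1440, by = 60)
  mat <- sapply(cuts, function(ct) {
    pct_energy_before(coh$recalls, cutoff = ct)$pct_energy_before_cutoff
  })
  expect_true(all(diff(t(mat)) >= -1e-12))
  expect_true(all(abs(mat[, length(cuts)] - 100) < 1e-12))
})

test_that("early-eater classification is inclusive at the threshold", {
  expect_true(classify_early_eater(60))
  expect_false(classify_early_eater(59.99))
  expect_true(classify_early_eater(75))
})

test_that("eating after 20:00 uses a strict any-day rule", {
  at_2000 <- dplyr::bind_rows(lapply(1:2, function(d) {
    three_meal_day("S1", d, times = c(540, 915, 1200))
  }))
  expect_false(classify_after_time(at_2000)$eats_after_cutoff)

  one_late <- dplyr::bind_rows(
    three_meal_day("S1", 1),
    three_meal_day("S1", 2),
    occ_row("S1", 2, "after_dinner_snack", 1350, energy = 150)
  )
  expect_true(classify_after_time(one_late)$eats_after_cutoff)

  early_only <- dplyr::bind_rows(lapply(1:2, function(d) {
    dplyr::bind_rows(
      occ_row("S1", d, "breakfast", 540, energy = 400),
      occ_row("S1", d, "lunch", 900, energy = 700)
    )
  }))
  expect_false(classify_after_time(early_only)$eats_after_cutoff)

  # monotone: appending a later occasion never flips true -> false
  flagged <- classify_after_time(one_late)$eats_after_cutoff
  later <- dplyr::bind_rows(
    one_late, occ_row("S1", 1, "after_dinner_snack", 1400, energy = 10)
  )
  expect_true(classify_after_time(later)$eats_after_cutoff >= flagged)
})

test_that("largest meal maximizes energy with earliest-start tie-break", {
  r <- dplyr::bind_rows(
    three_meal_day("S1", 1, kcal = c(400, 800, 300), times = c(540, 900, 1200)),
    three_meal_day("S1", 2, kcal = c(350, 800, 400), times = c(540, 930, 1200))
  )
  lm1 <- largest_meal(r)
  expect_equal(lm1$largest_meal_label, "lunch")
  expect_equal(lm1$largest_meal_time, 915) # mean of 15:00 and 15:30

  # tie 500/500 between breakfast (9:00) and dinner (20:00) -> breakfast
  tie <- three_meal_day("S2", 1, kcal = c(500, 100, 500), times = c(540, 900, 1200))
  tie <- dplyr::bind_rows(tie, three_meal_day("S2", 2, kcal = c(500, 100, 500)))
  expect_equal(largest_meal(tie)$largest_meal_label, "breakfast")

  # winners differ between days: reported time is still the mean
  split <- dplyr::bind_rows(
    three_meal_day("S3", 1, kcal = c(100, 900, 100), times = c(540, 900, 1200)),
    three_meal_day("S3", 2, kcal = c(100, 100, 900), times = c(540, 900, 1230))
  )
  expect_equal(largest_meal(split)$largest_meal_time, (900 + 1230) / 2)

  # the winner dominates every other occasion that day
  coh <- small_cohort(seed = 21, n_children = 2, n_adults = 15)
  win <- largest_meal(coh$recalls) |>
    dplyr::select(subject_id, largest_meal_by_day) |>
    tidyr::unnest(largest_meal_by_day)
  per_day_max <- coh$recalls |>
    dplyr::group_by(subject_id, day) |>
    dplyr::summarise(max_e = max(energy), .groups = "drop")
  joined <- dplyr::left_join(win, per_day_max, by = c("subject_id", "day"))
  expect_equal(joined$energy, joined$max_e)
})

test_that("occasion times average over the days the label occurs", {
  r <- dplyr::bind_rows(
    three_meal_day("S1", 1, times = c(540, 900, 1200)),
    three_meal_day("S1", 2, times = c(540, 930, 1200)),
    occ_row("S1", 1, "morning_snack", 660, energy = 100)
  )
  mt <- mean_occasion_times(r)
  expect_equal(mt$mean_time[mt$label == "lunch"], 915)
  expect_equal(mt$mean_time[mt$label == "morning_snack"], 660)
  expect_equal(mt$days_present[mt$label == "morning_snack"], 1L)
  expect_setequal(
    mt$label, c("breakfast", "lunch", "dinner", "morning_snack")
  )
})

test_that("lunch consistency reports the absolute gap with inclusive 1-h flag", {
  gap <- function(t1, t2) {
    r <- dplyr::bind_rows(
      three_meal_day("S1", 1, times = c(540, t1, 1200)),
      three_meal_day("S1", 2, times = c(540, t2, 1200))
    )
    lunch_consistency(r)
  }
  g <- gap(900, 924)
  expect_equal(g$lunch_day_gap, 24)
  expect_true(g$lunch_within_1h)
  expect_true(gap(780, 840)$lunch_within_1h) # exactly 60 min
  g2 <- gap(720, 990)
  expect_equal(g2$lunch_day_gap, 270)
  expect_false(g2$lunch_within_1h)

  # lunch missing on a day: flagged missing, not an error
  no_lunch <- dplyr::bind_rows(
    three_meal_day("S1", 1),
    occ_row("S1", 2, "breakfast", 540, energy = 300)
  )
  expect_true(is.na(lunch_consistency(no_lunch)$lunch_day_gap))
})

test_that("the timing profile assembles per-subject flags consistently", {
  coh <- small_cohort(seed = 31, n_children = 5, n_adults = 25)
  tp <- timing_profile(coh$recalls)
  expect_equal(nrow(tp), 30)
  expect_true(all(tp$pct_energy_before_cutoff >= 0 & tp$pct_energy_before_cutoff <= 100))
  expect_equal(tp$early_eater, tp$pct_energy_before_cutoff >= 60)
})
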
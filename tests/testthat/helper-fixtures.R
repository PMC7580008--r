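# In-code fixtures: tiny hand-built recall tables used across the tests.

# one eating occasion row with all quantities defaulting to zero
occ_row <- function(subject_id, day, label, time, energy = 0,
                    carbohydrate = 0, protein = 0, fat = 0, saturated_fat = 0,
                    sugar = 0, fiber = 0, sodium = 0, fruit = 0,
                    vegetables = 0, water = 0, food_mass = 0, alcohol = 0) {
  tibble::tibble(
    subject_id = subject_id, day = as.integer(day), label = label,
    time = as.integer(time), energy = energy, carbohydrate = carbohydrate,
    protein = protein, fat = fat, saturated_fat = saturated_fat,
    sugar = sugar, fiber = fiber, sodium = sodium, fruit = fruit,
    vegetables = vegetables, water = water, food_mass = food_mass,
    alcohol = alcohol
  )
}

# a subject with identical simple days: breakfast 600 kcal at 9:00 and
# dinner 400 kcal at 20:00 (60% of energy before 16:00)
two_meal_subject <- function(id = "S1", breakfast_kcal = 600,
                             dinner_kcal = 400, breakfast_time = 540,
                             dinner_time = 1200) {
  dplyr::bind_rows(lapply(1:2, function(d) {
    dplyr::bind_rows(
      occ_row(id, d, "breakfast", breakfast_time, energy = breakfast_kcal),
      occ_row(id, d, "dinner", dinner_time, energy = dinner_kcal)
    )
  }))
}

# three-meal recall day mirroring the child per-meal energy means
three_meal_day <- function(id = "S1", day = 1,
                           kcal = c(560, 665, 520),
                           times = c(540, 915, 1200)) {
  dplyr::bind_rows(
    occ_row(id, day, "breakfast", times[1], energy = kcal[1]),
    occ_row(id, day, "lunch", times[2], energy = kcal[2]),
    occ_row(id, day, "dinner", times[3], energy = kcal[3])
  )
}

# subject-intake row(s) with only the DQS-relevant columns
dqs_intake <- function(fruit_veg, fiber_density, sugar_pct,
                       saturated_fat_pct, sodium,
                       subject_id = paste0("S", seq_along(fruit_veg))) {
  tibble::tibble(
    subject_id = subject_id, fruit_veg = fruit_veg,
    fiber_density = fiber_density, sugar_pct = sugar_pct,
    saturated_fat_pct = saturated_fat_pct, sodium = sodium
  )
}

small_cohort <- function(seed = 42, n_children = 10, n_adults = 60) {
  generate_cohort(
    synthetic_config(n_children = n_children, n_adults = n_adults, seed = seed)
  )
}

# independent step-up BH oracle: try every k from m down to 1
bh_stepup_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  k_star <- 0
  for (k in m:1) {
    if (p[ord][k] <= k * alpha / m) {
      k_star <- k
      break
    }
  }
  sig <- rep(FALSE, m)
  if (k_star > 0) sig[ord[seq_len(k_star)]] <- TRUE
  sig
}
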
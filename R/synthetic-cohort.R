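# Synthetic two-recall survey cohort generator. Emulates the statistical
# structure the analysis assumes: two recall days per subject, up to eight
# labelled eating occasions with realistic clock times, lunch as the largest
# meal, nutrient marginals matching the adult survey means/SDs, and a latent
# "traditionalism" factor that couples an earlier, larger lunch with higher
# fruit/vegetable intake, lower total energy and older age.

#' Occasion-level generator defaults
#'
#' Per-label occurrence probability (per day; main meals always present),
#' subject-level mean start time and between-subject SD (minutes since
#' midnight), day-to-day jitter SD, and mean occasion energy for adults and
#' children (kcal). Lunch jitter of 21 min/day makes the expected absolute
#' between-day lunch gap 2*21/sqrt(pi) ~ 24 min.
#'
#' @return Tibble with one row per occasion label.
#' @export
occasion_defaults <- function() {
  tibble::tibble(
    label = occasion_labels(),
    prob = c(0.40, 1, 0.85, 1, 0.90, 0.30, 1, 0.55),
    time_mean = c(420, 540, 690, 915, 1020, 1110, 1200, 1290),
    time_sd = c(30, 45, 40, 55, 40, 35, 35, 30),
    jitter_sd = c(20, 20, 20, 21, 20, 20, 20, 20),
    energy_adult = c(100, 537, 130, 761, 150, 120, 568, 140),
    energy_child = c(134, 560, 174, 665, 201, 161, 520, 188)
  )
}

#' Nutrient marginal targets
#'
#' Subject-level two-day-average targets (mean, SD) for the generator, for
#' adults and children separately: macronutrient percent of energy, fiber
#' density (g/1000 kcal), fruit and vegetables (g/day), sodium (g/day),
#' water (ml/day) and energy density (kcal/g food).
#'
#' @param child Logical; child targets instead of adult targets.
#' @return Named list of `c(mean, sd)` pairs plus fruit-pattern parameters.
#' @export
nutrient_targets <- function(child = FALSE) {
  if (child) {
    list(
      carbohydrate_pct = c(46, 8), protein_pct = c(15, 4), fat_pct = c(39, 8),
      saturated_fat_pct = c(12, 4), sugar_pct = c(13.6, 6.4),
      fiber_density = c(8.1, 3.4), fruit_veg = c(424, 259),
      sodium = c(3.66, 2.69), water = c(1996, 1327),
      energy_density = c(1.01, 0.34),
      fruit_mean = 169, fruit_zero_p = 0.23
    )
  } else {
    list(
      carbohydrate_pct = c(44, 10), protein_pct = c(16, 4), fat_pct = c(40, 9),
      saturated_fat_pct = c(13, 4), sugar_pct = c(13.2, 7.4),
      fiber_density = c(10.9, 6.4), fruit_veg = c(473, 295),
      sodium = c(3.99, 3.00), water = c(2246, 1333),
      energy_density = c(0.89, 0.32),
      fruit_mean = 184, fruit_zero_p = 0.20
    )
  }
}

#' Synthetic-cohort configuration
#'
#' All generative parameters of [generate_cohort()], with defaults set to
#' the survey conditions the package emulates: 74 children and 260 adults,
#' 54% female, adult age categories in proportions 75/73/73/39, breakfast
#' around 9:00, lunch around 15:15 and dinner around 20:00 with lunch the
#' largest meal (adult per-meal energy means 537/761/568 kcal, child
#' 560/665/520 kcal), nutrient marginals per [nutrient_targets()], and
#' couplings through a latent traditionalism factor that shift lunch
#' earlier, raise fruit/vegetable and fiber intake, and lower total energy
#' for early eaters.
#'
#' The calibration constants (`pct_center`, `pct_sd`, `pct_spread`,
#' `age_gap`, `female_gap`) summarize the distribution of percent of energy
#' before 16:00 that the timing part of the generator realizes; they are
#' frozen from a large calibration run (see [calibrate_config()]) and are
#' what lets the generator size the fruit+vegetable coupling so the
#' early-vs-late gap equals `fv_gap` and the total generative z-score slope
#' on percent-before equals `z_slope`.
#'
#' @param n_children,n_adults Cohort sizes.
#' @param p_female Probability a subject is female.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param adult_age_counts Sampling weights of the four adult age
#'   categories.
#' @param occasions Occasion-level parameters, see [occasion_defaults()].
#' @param occasion_energy_cv Lognormal CV of per-occasion energy.
#' @param subject_scale_cv Lognormal CV of the subject-level appetite scale
#'   multiplying all occasion energies.
#' @param trad_age_loading Loading of standardized age on the latent
#'   traditionalism factor T.
#' @param lunch_time_trad Minutes the subject-mean lunch time shifts per
#'   unit of T (negative = earlier).
#' @param meal_energy_trad Named log-multipliers of occasion energy per unit
#'   of T.
#' @param energy_pct_coupling Change of log daily energy per percentage
#'   point of energy-before-16:00 (negative: early eaters eat less overall).
#' @param z_slope Generative slope of the diet-quality z-score on percent of
#'   energy before 16:00, per percentage point.
#' @param fv_gap Target early-vs-late fruit+vegetable difference, g/day.
#' @param nonfv_slope_weights Relative shares of the z-slope carried by the
#'   fiber, sugar, saturated-fat and sodium components (fruit+vegetables
#'   takes whatever `fv_gap` implies; the rest is split by these weights).
#' @param age_couplings,female_couplings Additive intake shifts per year of
#'   age (centered) and for females (centered), per component.
#' @param pct_center,pct_sd,pct_spread,age_gap,female_gap Calibration
#'   constants, see above.
#' @param component_sds Named vector of calibrated population SDs of the
#'   five scored components (`fv`, `fiber`, `sugar`, `satfat`, `sodium`);
#'   `NULL` falls back to the [nutrient_targets()] SDs.
#' @param coupling_scale_fv,coupling_scale_nonfv Calibrated scale factors
#'   applied to the fruit+vegetable and to the remaining component
#'   couplings; they compensate the attenuation that non-negativity floors
#'   introduce so the realized `fv_gap` and `z_slope` match their targets.
#' @param alcohol Adult alcohol model: probability of any intake and the
#'   mean/sdlog of percent of energy among consumers (children never drink).
#' @param bmi_age_slope,bmi_sd Adult BMI model: `BMI = 25.2 +
#'   slope*(age - mean age) + N(0, sd)`, targeting a Spearman correlation
#'   with age of about 0.4.
#' @param p_measured_anthro Probability height/weight were measured rather
#'   than self-reported.
#' @param p_missing_anthro Probability height/weight are missing.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_children = 74, n_adults = 260, p_female = 0.54, seed = NULL,
    adult_age_counts = c("18-29" = 75, "30-47" = 73, "48-64" = 73, "65-74" = 39),
    occasions = occasion_defaults(),
    occasion_energy_cv = 0.35,
    subject_scale_cv = 0.39,
    trad_age_loading = 0.45,
    lunch_time_trad = -25,
    meal_energy_trad = c(lunch = 0.10, dinner = -0.12, after_dinner_snack = -0.20),
    energy_pct_coupling = -0.00406,
    z_slope = 0.03,
    fv_gap = 96,
    nonfv_slope_weights = c(fiber = 0.0105, sugar = 0.004, satfat = 0.004, sodium = 0.002),
    age_couplings = c(fv = 1.8, fiber = 0.04, sugar = -0.02, satfat = -0.02, sodium = -0.015),
    female_couplings = c(fv = 90, fiber = 1.6, sugar = 0, satfat = -0.9, sodium = -0.66),
    pct_center = 56.66, pct_sd = 15.04, pct_spread = 24.25,
    age_gap = 6.35, female_gap = -0.0018,
    component_sds = c(
      fv = 297.43, fiber = 6.121, sugar = 7.275, satfat = 4.037, sodium = 2.979
    ),
    coupling_scale_fv = 0.998, coupling_scale_nonfv = 1.0266,
    alcohol = list(p_drinker = 0.45, mean_pct = 3.5, sdlog = 0.6),
    bmi_age_slope = 0.1006, bmi_sd = 3.72,
    p_measured_anthro = 0.65, p_missing_anthro = 6 / 334) {
  stopifnot(
    n_adults >= 2 || n_children >= 2,
    p_female >= 0 && p_female <= 1,
    all(occasions$prob >= 0 & occasions$prob <= 1),
    all(occasions$time_sd > 0), all(occasions$jitter_sd > 0),
    occasion_energy_cv > 0, subject_scale_cv > 0,
    abs(trad_age_loading) <= 1
  )
  cfg <- list(
    n_children = n_children, n_adults = n_adults, p_female = p_female,
    seed = seed, adult_age_counts = adult_age_counts, occasions = occasions,
    occasion_energy_cv = occasion_energy_cv,
    subject_scale_cv = subject_scale_cv,
    trad_age_loading = trad_age_loading, lunch_time_trad = lunch_time_trad,
    meal_energy_trad = meal_energy_trad,
    energy_pct_coupling = energy_pct_coupling,
    z_slope = z_slope, fv_gap = fv_gap,
    nonfv_slope_weights = nonfv_slope_weights,
    age_couplings = age_couplings, female_couplings = female_couplings,
    pct_center = pct_center, pct_sd = pct_sd, pct_spread = pct_spread,
    age_gap = age_gap, female_gap = female_gap,
    component_sds = component_sds,
    coupling_scale_fv = coupling_scale_fv,
    coupling_scale_nonfv = coupling_scale_nonfv,
    alcohol = alcohol, bmi_age_slope = bmi_age_slope, bmi_sd = bmi_sd,
    p_measured_anthro = p_measured_anthro,
    p_missing_anthro = p_missing_anthro
  )
  class(cfg) <- "synthetic_config"
  cfg
}

# adult age-category integer ranges implied by the category names
.age_ranges <- function(counts) {
  parts <- strsplit(names(counts), "-", fixed = TRUE)
  lapply(parts, function(p) as.integer(p))
}

# theoretical mean/sd of adult age under category-weighted uniform sampling
.adult_age_moments <- function(counts) {
  rng <- .age_ranges(counts)
  w <- counts / sum(counts)
  m <- vapply(rng, function(r) mean(r), numeric(1))
  v <- vapply(rng, function(r) ((r[2] - r[1] + 1)^2 - 1) / 12, numeric(1))
  mu <- sum(w * m)
  list(mean = mu, sd = sqrt(sum(w * (v + (m - mu)^2))))
}

# lognormal draw with a given mean and sd on the natural scale
.rlnorm_ms <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# component couplings (g or % per percentage point of pct-before) implied by
# the config: fv sized to deliver cfg$fv_gap; the remaining z-slope split
# across the other four components by the configured weights
.component_couplings <- function(cfg) {
  tg <- nutrient_targets(child = FALSE)
  sds <- c(
    fv = tg$fruit_veg[2], fiber = tg$fiber_density[2],
    sugar = tg$sugar_pct[2], satfat = tg$saturated_fat_pct[2],
    sodium = tg$sodium[2]
  )
  # population SDs measured by calibrate_config(), when available, so that
  # the z-slope refers to the SDs the pipeline will actually estimate
  if (!is.null(cfg$component_sds)) {
    sds[names(cfg$component_sds)] <- cfg$component_sds
  }
  b_fv <- (cfg$fv_gap - cfg$age_couplings[["fv"]] * cfg$age_gap -
             cfg$female_couplings[["fv"]] * cfg$female_gap) / cfg$pct_spread
  remaining <- cfg$z_slope - b_fv / sds[["fv"]]
  w_sum <- sum(cfg$nonfv_slope_weights)
  z_slopes <- if (w_sum > 0) {
    remaining * cfg$nonfv_slope_weights / w_sum
  } else {
    setNames(rep(0, 4), names(cfg$nonfv_slope_weights))
  }
  # intake-units slope per %pt; healthy direction: +1 for fv/fiber, -1 others.
  # the calibration scale factors compensate the small attenuation that the
  # non-negativity floors introduce, so the realized gap and slope match the
  # configured targets (see calibrate_config)
  c(
    fv = b_fv * cfg$coupling_scale_fv,
    fiber = z_slopes[["fiber"]] * sds[["fiber"]] * cfg$coupling_scale_nonfv,
    sugar = -z_slopes[["sugar"]] * sds[["sugar"]] * cfg$coupling_scale_nonfv,
    satfat = -z_slopes[["satfat"]] * sds[["satfat"]] * cfg$coupling_scale_nonfv,
    sodium = -z_slopes[["sodium"]] * sds[["sodium"]] * cfg$coupling_scale_nonfv
  )
}

# residual noise SD that keeps a component's total SD at its target given
# the variance explained by the couplings
.noise_sd <- function(target_sd, b_pct, pct_var, b_age, age_var, b_fem, fem_var) {
  expl <- b_pct^2 * pct_var + b_age^2 * age_var + b_fem^2 * fem_var
  sqrt(pmax(target_sd^2 - expl, (0.3 * target_sd)^2))
}

#' Generate a synthetic survey cohort
#'
#' Draws demographics, two recall days of timed eating occasions, and
#' per-occasion nutrient content according to a [synthetic_config()].
#' Deterministic given `config$seed`. All generated data satisfy the recall
#' table invariants (validated before returning).
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_cohort` with elements `subjects` (one
#'   row per subject, including the latent traditionalism draw
#'   `latent_trad`), `recalls` (one row per subject, day and occasion) and
#'   `config`.
#' @export
#' @examples
#' coh <- generate_cohort(synthetic_config(n_children = 5, n_adults = 20, seed = 1))
#' dplyr::count(coh$recalls, subject_id, day)
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(config$seed)
  }

  n_c <- config$n_children
  n_a <- config$n_adults
  n <- n_c + n_a

  ## --- demographics ------------------------------------------------------
  is_child <- c(rep(TRUE, n_c), rep(FALSE, n_a))
  subject_id <- sprintf("S%04d", seq_len(n))
  age <- numeric(n)
  if (n_c > 0) age[is_child] <- sample(10:17, n_c, replace = TRUE)
  rng <- .age_ranges(config$adult_age_counts)
  if (n_a > 0) {
    cat_idx <- sample(
      seq_along(rng), n_a, replace = TRUE,
      prob = config$adult_age_counts / sum(config$adult_age_counts)
    )
    age[!is_child] <- vapply(
      cat_idx, function(i) sample(rng[[i]][1]:rng[[i]][2], 1), numeric(1)
    )
  }
  gender <- ifelse(runif(n) < config$p_female, "female", "male")
  mom <- .adult_age_moments(config$adult_age_counts)
  z_age <- ifelse(is_child, 0, (age - mom$mean) / mom$sd)
  lam <- config$trad_age_loading
  latent_trad <- ifelse(
    is_child, 0, lam * z_age + sqrt(1 - lam^2) * rnorm(n)
  )

  ## --- occasions: presence, times, base energies -------------------------
  occ <- config$occasions
  grid <- tidyr::expand_grid(
    idx = seq_len(n), day = 1:2, occ_row = seq_len(nrow(occ))
  )
  grid$label <- occ$label[grid$occ_row]
  grid$present <- runif(nrow(grid)) < occ$prob[grid$occ_row]
  grid <- grid[grid$present, ]

  # subject-level mean times (shared across days), drawn per subject x label
  subj_time <- tidyr::expand_grid(idx = seq_len(n), occ_row = seq_len(nrow(occ)))
  subj_time$mean_time <- occ$time_mean[subj_time$occ_row] +
    occ$time_sd[subj_time$occ_row] * rnorm(nrow(subj_time)) +
    ifelse(
      occ$label[subj_time$occ_row] == "lunch",
      config$lunch_time_trad * latent_trad[subj_time$idx], 0
    )
  grid <- dplyr::left_join(grid, subj_time, by = c("idx", "occ_row"))
  grid$time <- round(grid$mean_time + occ$jitter_sd[grid$occ_row] * rnorm(nrow(grid)))
  grid$time <- pmin(pmax(grid$time, 0), 1439)

  mean_e <- ifelse(
    is_child[grid$idx], occ$energy_child[grid$occ_row],
    occ$energy_adult[grid$occ_row]
  )
  trad_mult <- rep(0, nrow(grid))
  for (lab in names(config$meal_energy_trad)) {
    sel <- grid$label == lab & !is_child[grid$idx]
    trad_mult[sel] <- config$meal_energy_trad[[lab]] * latent_trad[grid$idx[sel]]
  }
  cv <- config$occasion_energy_cv
  sdlog_o <- sqrt(log(1 + cv^2))
  grid$base_energy <- mean_e * exp(trad_mult) *
    rlnorm(nrow(grid), meanlog = -sdlog_o^2 / 2, sdlog = sdlog_o)

  ## --- percent of energy before 16:00 (scale-invariant) ------------------
  pooled <- grid |>
    dplyr::group_by(.data$idx) |>
    dplyr::summarise(
      pct = 100 * sum(.data$base_energy[.data$time < 960]) / sum(.data$base_energy),
      .groups = "drop"
    )
  pct <- pooled$pct[match(seq_len(n), pooled$idx)]

  ## --- subject appetite scale and final energies -------------------------
  pct_c <- ifelse(is_child, 0, pct - config$pct_center)
  sdlog_s <- sqrt(log(1 + config$subject_scale_cv^2))
  # lognormal appetite with mean 1, times the pct-before coupling
  scale <- exp(
    config$energy_pct_coupling * pct_c +
      rnorm(n, mean = -sdlog_s^2 / 2, sd = sdlog_s)
  )
  grid$energy <- grid$base_energy * scale[grid$idx]
  two_day_energy <- tapply(grid$energy, grid$idx, sum)[as.character(seq_len(n))]
  daily_energy <- as.numeric(two_day_energy) / 2

  ## --- subject-level nutrient profile ------------------------------------
  age_c <- ifelse(is_child, 0, age - mom$mean)
  fem_c <- ifelse(is_child, 0, (gender == "female") - config$p_female)
  bcomp <- .component_couplings(config)
  pct_var <- config$pct_sd^2
  age_var <- mom$sd^2
  fem_var <- config$p_female * (1 - config$p_female)

  draw_component <- function(key, column, lognormal = FALSE, floor_at = 0) {
    tg_a <- nutrient_targets(FALSE)[[column]]
    tg_k <- nutrient_targets(TRUE)[[column]]
    m <- ifelse(is_child, tg_k[1], tg_a[1])
    s_noise_a <- .noise_sd(
      tg_a[2], bcomp[[key]], pct_var,
      config$age_couplings[[key]], age_var,
      config$female_couplings[[key]], fem_var
    )
    s_noise <- ifelse(is_child, tg_k[2], s_noise_a)
    shift <- ifelse(
      is_child, 0,
      bcomp[[key]] * pct_c + config$age_couplings[[key]] * age_c +
        config$female_couplings[[key]] * fem_c
    )
    noise <- if (lognormal) {
      .rlnorm_ms(n, m, s_noise) - m
    } else {
      rnorm(n, 0, s_noise)
    }
    pmax(m + shift + noise, floor_at)
  }

  fruit_veg <- draw_component("fv", "fruit_veg", lognormal = TRUE, floor_at = 15)
  fiber_density <- draw_component("fiber", "fiber_density", floor_at = 0.5)
  sodium <- draw_component("sodium", "sodium", lognormal = TRUE, floor_at = 0.2)

  # macronutrient percents: raw normals plus alcohol, normalized to sum 100
  tg_pick <- function(column, i) {
    ta <- nutrient_targets(FALSE)[[column]]; tk <- nutrient_targets(TRUE)[[column]]
    ifelse(is_child, tk[i], ta[i])
  }
  carb_raw <- pmax(rnorm(n, tg_pick("carbohydrate_pct", 1), tg_pick("carbohydrate_pct", 2)), 10)
  prot_raw <- pmax(rnorm(n, tg_pick("protein_pct", 1), tg_pick("protein_pct", 2)), 5)
  fat_raw <- pmax(rnorm(n, tg_pick("fat_pct", 1), tg_pick("fat_pct", 2)), 10)
  alc_raw <- ifelse(
    !is_child & runif(n) < config$alcohol$p_drinker,
    rlnorm(
      n, log(config$alcohol$mean_pct) - config$alcohol$sdlog^2 / 2,
      config$alcohol$sdlog
    ),
    0
  )
  tot <- carb_raw + prot_raw + fat_raw + alc_raw
  carb_pct <- 100 * carb_raw / tot
  prot_pct <- 100 * prot_raw / tot
  fat_pct <- 100 * fat_raw / tot
  alc_pct <- 100 * alc_raw / tot

  # saturated fat and sugar as coupled sub-shares of fat and carbohydrate
  sub_share <- function(key, column, parent_pct, parent_mean) {
    tg_a <- nutrient_targets(FALSE)[[column]]
    tg_k <- nutrient_targets(TRUE)[[column]]
    m <- ifelse(is_child, tg_k[1], tg_a[1])
    # part of the target SD already produced by parent variation
    base_var_a <- (tg_a[1] / parent_mean)^2 *
      (if (sum(!is_child) > 1) var(parent_pct[!is_child]) else 0)
    eps_a <- .noise_sd(
      sqrt(pmax(tg_a[2]^2 - base_var_a, (0.3 * tg_a[2])^2)),
      bcomp[[key]], pct_var,
      config$age_couplings[[key]], age_var,
      config$female_couplings[[key]], fem_var
    )
    base_var_k <- (tg_k[1] / parent_mean)^2 *
      ifelse(sum(is_child) > 1, var(parent_pct[is_child]), 0)
    eps_k <- sqrt(pmax(tg_k[2]^2 - base_var_k, (0.3 * tg_k[2])^2))
    eps <- ifelse(is_child, eps_k, eps_a)
    shift <- ifelse(
      is_child, 0,
      bcomp[[key]] * pct_c + config$age_couplings[[key]] * age_c +
        config$female_couplings[[key]] * fem_c
    )
    lp <- pmax(m + shift + rnorm(n, 0, eps), 0.5)
    pmin(parent_pct * lp / parent_mean, 0.95 * parent_pct)
  }
  satfat_pct <- sub_share("satfat", "saturated_fat_pct", fat_pct, mean(fat_pct))
  sugar_pct <- sub_share("sugar", "sugar_pct", carb_pct, mean(carb_pct))

  # fruit/vegetable split with a zero-fruit point mass
  fz <- ifelse(is_child, nutrient_targets(TRUE)$fruit_zero_p,
               nutrient_targets(FALSE)$fruit_zero_p)
  fm <- ifelse(is_child, nutrient_targets(TRUE)$fruit_mean,
               nutrient_targets(FALSE)$fruit_mean)
  fv_m <- tg_pick("fruit_veg", 1)
  share_mean <- pmin(fm / ((1 - fz) * fv_m), 0.9)
  conc <- 5
  fruit_share <- ifelse(
    runif(n) < fz, 0,
    rbeta(n, share_mean * conc, (1 - share_mean) * conc)
  )
  fruit <- fruit_veg * fruit_share
  vegetables <- fruit_veg - fruit

  water <- .rlnorm_ms(n, tg_pick("water", 1), tg_pick("water", 2))
  energy_density <- pmax(
    .rlnorm_ms(n, tg_pick("energy_density", 1), tg_pick("energy_density", 2)),
    0.2
  )
  food_mass <- daily_energy / energy_density

  # grams/day from percent of energy via Atwater factors
  fac <- atwater_factors()
  carb_g <- carb_pct * daily_energy / (100 * fac[["carbohydrate"]])
  prot_g <- prot_pct * daily_energy / (100 * fac[["protein"]])
  fat_g <- fat_pct * daily_energy / (100 * fac[["fat"]])
  satfat_g <- satfat_pct * daily_energy / (100 * fac[["fat"]])
  sugar_g <- sugar_pct * daily_energy / (100 * fac[["carbohydrate"]])
  alc_g <- alc_pct * daily_energy / (100 * fac[["alcohol"]])
  fiber_g <- fiber_density * daily_energy / 1000

  ## --- allocate daily amounts to occasions, proportional to energy -------
  w <- grid$energy / as.numeric(two_day_energy[grid$idx])
  alloc <- function(daily) 2 * daily[grid$idx] * w
  recalls <- tibble::tibble(
    subject_id = subject_id[grid$idx],
    day = as.integer(grid$day),
    label = grid$label,
    time = as.integer(grid$time),
    energy = grid$energy,
    carbohydrate = alloc(carb_g),
    protein = alloc(prot_g),
    fat = alloc(fat_g),
    saturated_fat = alloc(satfat_g),
    sugar = alloc(sugar_g),
    fiber = alloc(fiber_g),
    sodium = alloc(sodium),
    fruit = alloc(fruit),
    vegetables = alloc(vegetables),
    water = alloc(water),
    food_mass = alloc(food_mass),
    alcohol = alloc(alc_g)
  )
  recalls <- validate_recalls(recalls)

  ## --- anthropometry and remaining demographics --------------------------
  bmi <- ifelse(
    is_child,
    16 + 0.45 * (age - 10) + rnorm(n, 0, 2.2),
    25.2 + config$bmi_age_slope * (age - mom$mean) + rnorm(n, 0, config$bmi_sd)
  )
  bmi <- pmax(bmi, 13)
  height <- ifelse(
    is_child, 130 + 6 * (age - 10) + rnorm(n, 0, 7),
    ifelse(gender == "female", rnorm(n, 166, 7), rnorm(n, 179, 7))
  )
  weight <- bmi * (height / 100)^2
  miss <- runif(n) < config$p_missing_anthro
  height[miss] <- NA_real_
  weight[miss] <- NA_real_
  bmi_out <- ifelse(miss, NA_real_, bmi)
  bmi_measured <- !miss & runif(n) < config$p_measured_anthro

  smoker_p <- ifelse(is_child, 0.06, ifelse(age >= 65, 0.19, 0.35))
  smoker <- runif(n) < smoker_p
  smoker[runif(n) < 14 / 334] <- NA
  employed_p <- ifelse(
    is_child, 0,
    ifelse(age < 30, 0.51, ifelse(age < 48, 0.87, ifelse(age < 65, 0.69, 0.08)))
  )
  employed_outside_home <- runif(n) < employed_p

  subjects <- tibble::tibble(
    subject_id = subject_id, age = age, is_child = is_child, gender = gender,
    age_category = assign_age_category(age),
    weight = weight, height = height, bmi = bmi_out,
    bmi_measured = bmi_measured, smoker = smoker,
    employed_outside_home = employed_outside_home,
    latent_trad = latent_trad
  )
  validate_subjects(subjects)

  structure(
    list(subjects = subjects, recalls = recalls, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(
    "Synthetic survey cohort:", sum(x$subjects$is_child), "children,",
    sum(!x$subjects$is_child), "adults,", nrow(x$recalls),
    "eating occasions over 2 recall days\n"
  )
  invisible(x)
}

#' Recalibrate the timing constants of a configuration
#'
#' Generates a large adult-only cohort under `config`, measures the realized
#' distribution of percent of energy before 16:00 (mean, SD, early-vs-late
#' spread) and the early-vs-late age and female-share gaps, and returns the
#' configuration with the calibration constants replaced by the measured
#' values. Run this after changing timing or energy parameters; the shipped
#' defaults were produced by this function at `n = 200000`.
#'
#' @param config A [synthetic_config()].
#' @param n Number of adults to simulate.
#' @param seed Seed for the calibration run.
#' @param iterations Fixed-point iterations (the couplings depend on the
#'   constants being calibrated).
#' @return The updated `synthetic_config`.
#' @export
calibrate_config <- function(config = synthetic_config(), n = 50000, seed = 1,
                             iterations = 2) {
  for (it in seq_len(iterations)) {
    big <- config
    big$n_children <- 0
    big$n_adults <- n
    big$seed <- seed
    coh <- generate_cohort(big)
    si <- subject_intake(coh$recalls, coh$subjects)
    p <- si$pct_energy_before_cutoff
    early <- p >= 60
    config$pct_center <- mean(p)
    config$pct_sd <- sd(p)
    config$pct_spread <- mean(p[early]) - mean(p[!early])
    config$age_gap <- mean(si$age[early]) - mean(si$age[!early])
    config$female_gap <- mean(si$gender[early] == "female") -
      mean(si$gender[!early] == "female")
    config$component_sds <- c(
      fv = sd(si$fruit_veg), fiber = sd(si$fiber_density),
      sugar = sd(si$sugar_pct), satfat = sd(si$saturated_fat_pct),
      sodium = sd(si$sodium)
    )

    # fixed-point correction of the coupling scales: the non-negativity
    # floors slightly attenuate the realized early-late fruit+veg gap and
    # the realized z-slope relative to their linear design values
    z <- dqs_zscore(si)
    z$female <- z$gender == "female"
    gap_hat <- mean(si$fruit_veg[early]) - mean(si$fruit_veg[!early])
    fit_fv <- dq_ols(z, z_fv ~ pct_energy_before_cutoff + age + female)
    s_fv <- fit_fv$estimate[fit_fv$term == "pct_energy_before_cutoff"]
    z$z_rest <- z$z_total - z$z_fv
    fit_rest <- dq_ols(z, z_rest ~ pct_energy_before_cutoff + age + female)
    s_rest <- fit_rest$estimate[fit_rest$term == "pct_energy_before_cutoff"]
    if (config$fv_gap != 0 && gap_hat > 0) {
      ratio_fv <- config$fv_gap / gap_hat
      config$coupling_scale_fv <- config$coupling_scale_fv * ratio_fv
      if (s_rest != 0) {
        config$coupling_scale_nonfv <- config$coupling_scale_nonfv *
          (config$z_slope - s_fv * ratio_fv) / s_rest
      }
    }
  }
  config
}

#' Parameter-recovery report for the synthetic generator
#'
#' Runs the full pipeline (intake summary, timing, diet-quality z-score,
#' adjusted regression, mixed model of meal energy) on `n_replicates`
#' independently generated cohorts and summarizes how well the generating
#' parameters are recovered: the age/gender-adjusted OLS slope of the
#' diet-quality z-score on percent of energy before 16:00 against the
#' generative `z_slope`, the early-vs-late fruit+vegetable gap against
#' `fv_gap`, and the lunch marginal mean against the configured lunch
#' energy.
#'
#' @param config A [synthetic_config()]; replicate r uses seed
#'   `config$seed + r`.
#' @param n_replicates Number of replicates (>= 1).
#' @param include_meal_model Fit the per-replicate mixed model (slower).
#' @return List of class `recovery_report`: `$replicates` (per-replicate
#'   estimates) and `$summary` (per-quantity mean, Monte-Carlo SE of the
#'   mean, generating value, bias).
#' @export
recovery_report <- function(config = synthetic_config(seed = 1),
                            n_replicates = 20,
                            include_meal_model = TRUE) {
  stopifnot(n_replicates >= 1)
  base_seed <- if (is.null(config$seed)) 0 else config$seed
  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- base_seed + r
    coh <- generate_cohort(cfg)
    est <- pipeline_estimates(coh, include_meal_model = include_meal_model)
    est$replicate <- r
    est
  })
  lunch_target <- config$occasions$energy_adult[config$occasions$label == "lunch"]
  summ <- tibble::tibble(
    quantity = c("z_slope_adjusted", "fv_gap", "lunch_marginal_mean"),
    generating = c(config$z_slope, config$fv_gap, lunch_target),
    mean = c(
      mean(reps$z_slope), mean(reps$fv_gap),
      if (include_meal_model) mean(reps$lunch_mean) else NA_real_
    ),
    mc_se = c(
      sd(reps$z_slope) / sqrt(n_replicates),
      sd(reps$fv_gap) / sqrt(n_replicates),
      if (include_meal_model) sd(reps$lunch_mean) / sqrt(n_replicates) else NA_real_
    )
  )
  summ$bias <- summ$mean - summ$generating
  out <- list(replicates = reps, summary = summ)
  class(out) <- "recovery_report"
  out
}

#' @export
tidy.recovery_report <- function(x, ...) x$summary

#' Key pipeline estimates for one cohort
#'
#' Convenience used by [recovery_report()] and the acceptance script: runs
#' intake summarization, timing, diet-quality z-scoring and the adjusted
#' regression on the adults of one cohort.
#'
#' @param cohort A `synthetic_cohort` (or list with `subjects`, `recalls`).
#' @param include_meal_model Also fit the per-meal mixed model.
#' @return One-row tibble: `z_slope` (age/gender-adjusted), `fv_gap`
#'   (early minus late mean fruit+vegetables, g/day), and when requested the
#'   three meal marginal means.
#' @export
pipeline_estimates <- function(cohort, include_meal_model = TRUE) {
  si <- subject_intake(cohort$recalls, cohort$subjects)
  adults <- dplyr::filter(si, !.data$is_child)
  z <- dqs_zscore(adults)
  z$female <- z$gender == "female"
  fit <- dq_ols(z, z_total ~ pct_energy_before_cutoff + age + female)
  slope <- fit$estimate[fit$term == "pct_energy_before_cutoff"]
  early <- classify_early_eater(adults$pct_energy_before_cutoff)
  fv_gap <- mean(adults$fruit_veg[early]) - mean(adults$fruit_veg[!early])
  out <- tibble::tibble(z_slope = slope, fv_gap = fv_gap)
  if (include_meal_model) {
    long <- meal_energy_long(cohort$recalls, cohort$subjects, adults_only = TRUE)
    mm <- meal_energy_model(long)
    for (m in mm$means$meal) {
      out[[paste0(m, "_mean")]] <- mm$means$estimate[mm$means$meal == m]
    }
  }
  out
}
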
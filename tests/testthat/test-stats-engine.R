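test_that("two-sample t-test matches the Welch formulas", {
  same <- dq_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  sep <- dq_t_test(c(1, 2, 3), c(11, 12, 13))
  expect_lt(sep$p_value, 0.01)

  # hand evaluation of the Welch statistic and Welch-Satterthwaite df
  a <- c(2.1, 2.4, 2.2, 2.5)
  b <- c(2.0, 2.3, 2.1)
  got <- dq_t_test(a, b)
  se2a <- var(a) / 4
  se2b <- var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df_hand <- (se2a + se2b)^2 / (se2a^2 / 3 + se2b^2 / 2)
  expect_equal(got$statistic, t_hand)
  expect_equal(got$df, df_hand)
  expect_equal(got$p_value, 2 * pt(-abs(t_hand), df_hand))

  expect_error(dq_t_test(1, c(1, 2)), "at least two")
})

test_that("Pearson chi-square matches hand computation", {
  prop <- matrix(c(10, 20, 30, 60), 2)
  res <- dq_chi_square(prop)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  diag2 <- matrix(c(10, 0, 0, 10), 2)
  res2 <- dq_chi_square(diag2)
  expect_equal(res2$statistic, 20)
  expect_equal(res2$df, 1)

  expect_equal(dq_chi_square(matrix(c(5, 6, 7, 8, 9, 10), 2))$df, 2)
  expect_error(dq_chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "marginal")
})

test_that("Benjamini-Hochberg reproduces the step-up procedure", {
  one <- benjamini_hochberg(0.04, alpha = 0.05)
  expect_true(one$significant)

  all1 <- benjamini_hochberg(rep(1, 5))
  expect_false(any(all1$significant))
  expect_equal(all1$p_adjusted, rep(1, 5))

  # results come back in input order and adjusted >= raw
  p <- c(0.03, 0.001, 0.2, 0.04)
  res <- benjamini_hochberg(p)
  expect_equal(res$p_value, p)
  expect_true(all(res$p_adjusted >= res$p_value))

  expect_error(benjamini_hochberg(numeric(0)), "empty")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH flags agree with brute-force step-up on random vectors", {
  set.seed(101)
  for (i in 1:200) {
    m <- sample(1:6, 1)
    p <- round(runif(m), 3)
    res <- benjamini_hochberg(p, alpha = 0.05)
    expect_identical(res$significant, bh_stepup_oracle(p, 0.05))
  }
  # adjusted p-values are monotone in the raw ranking
  p <- runif(20)
  res <- benjamini_hochberg(p)
  ord <- order(p)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-15))
})

test_that("Spearman correlation handles ranks, ties and degenerate input", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(dq_spearman(x, x)$rho, 1)
  expect_equal(dq_spearman(x, -x)$rho, -1)

  # hand rank computation for {(1,2),(2,1),(3,4),(4,3)}
  res <- dq_spearman(1:4, c(2, 1, 4, 3))
  expect_equal(res$rho, 0.6)
  tt <- 0.6 * sqrt(2 / (1 - 0.36))
  expect_equal(res$p_value, 2 * pt(-abs(tt), 2))

  # tied values use average ranks
  res_tie <- dq_spearman(c(1, 2, 2, 3), c(1, 2, 3, 4))
  expect_equal(res_tie$rho, cor(rank(c(1, 2, 2, 3)), rank(c(1, 2, 3, 4))))

  expect_error(dq_spearman(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(dq_spearman(1:2, 2:1), "three")
})

test_that("one-way ANOVA with Tukey matches its closed-form special cases", {
  g <- rep(c("a", "b", "c"), each = 3)
  v <- rep(c(1, 2, 3), times = 3)
  res <- anova_tukey(v, g)
  expect_equal(res$anova$statistic, 0)
  expect_equal(res$anova$p_value, 1)
  expect_true(all(res$tukey$p_adjusted == 1))

  # two-group ANOVA is the pooled t-test: F = t^2
  set.seed(5)
  x <- rnorm(12)
  grp <- rep(c("a", "b"), each = 6)
  res2 <- anova_tukey(x, grp)
  tt <- dq_t_test(x[grp == "a"], x[grp == "b"], variant = "pooled")
  expect_equal(res2$anova$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(res2$anova$p_value, tt$p_value, tolerance = 1e-10)

  expect_error(anova_tukey(c(-1, 1, 2, 3), rep(c("a", "b"), 2), log_transform = TRUE), "positive")

  # equal means, unequal spread: no pair significant (fixed seed)
  set.seed(77)
  vals <- c(rnorm(20, 0, 1), rnorm(20, 0, 3), rnorm(20, 0, 0.5))
  gg <- rep(c("a", "b", "c"), each = 20)
  res3 <- anova_tukey(vals, gg)
  expect_true(all(res3$tukey$p_adjusted > 0.05))
})

test_that("OLS matches the normal equations and flags collinearity", {
  d <- tibble::tibble(x = c(0, 10, 20, 40), y = 0.03 * c(0, 10, 20, 40))
  fit <- suppressWarnings(dq_ols(d, y ~ x)) # exact fit warns by design
  expect_equal(fit$estimate[fit$term == "x"], 0.03)
  expect_equal(fit$std_error[fit$term == "x"], 0, tolerance = 1e-12)

  # 4-point example solved by hand via the normal equations
  d2 <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2.1, 2.9, 4.2, 4.8))
  X <- cbind(1, d2$x)
  beta_hand <- solve(t(X) %*% X, t(X) %*% d2$y)
  fit2 <- dq_ols(d2, y ~ x)
  expect_equal(fit2$estimate, as.numeric(beta_hand))
  resid <- d2$y - X %*% beta_hand
  s2 <- sum(resid^2) / 2
  se_hand <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(fit2$std_error, se_hand)

  d3 <- tibble::tibble(x = 1:5, x2 = 2 * (1:5), y = rnorm(5))
  expect_error(dq_ols(d3, y ~ x + x2), "x2")
})

test_that("the random-intercept meal model recovers balanced-case closed forms", {
  # balanced complete data: marginal means equal per-meal sample means
  set.seed(9)
  n <- 40
  subj <- rep(sprintf("S%02d", 1:n), each = 3)
  meal <- rep(c("breakfast", "lunch", "dinner"), n)
  u <- rep(rnorm(n, 0, 150), each = 3)
  kcal <- c(540, 760, 570)[match(meal, c("breakfast", "lunch", "dinner"))] +
    u + rnorm(3 * n, 0, 120)
  mm <- meal_energy_model(tibble::tibble(subject_id = subj, meal = meal, kcal = kcal))
  sample_means <- tapply(kcal, meal, mean)
  expect_equal(
    mm$means$estimate[match(names(sample_means), mm$means$meal)],
    as.numeric(sample_means),
    tolerance = 1e-8
  )

  # two-meal balanced data: the contrast reproduces the paired t-test
  kcal_bl <- kcal[meal != "dinner"]
  two <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:n), each = 2),
    meal = rep(c("breakfast", "lunch"), n),
    kcal = kcal_bl
  )
  mm2 <- meal_energy_model(two)
  d <- two$kcal[two$meal == "lunch"] - two$kcal[two$meal == "breakfast"]
  tt <- t.test(d)
  ctr <- mm2$contrasts
  expect_equal(ctr$estimate, mean(d), tolerance = 1e-6)
  expect_equal(ctr$std_error, sd(d) / sqrt(n), tolerance = 1e-6)
  # Wald z vs t: same statistic, p-values agree up to the df convention
  expect_equal(abs(ctr$statistic), abs(tt$statistic[[1]]), tolerance = 1e-6)
  expect_equal(ctr$p_value, tt$p.value, tolerance = 0.02)

  expect_error(
    meal_energy_model(tibble::tibble(
      subject_id = "S1", meal = factor("lunch", levels = c("lunch", "dinner")),
      kcal = 500
    )),
    "dinner|two subjects"
  )
})

test_that("variance components are recovered and vanish when absent", {
  set.seed(15)
  n <- 500
  subj <- rep(sprintf("S%03d", 1:n), each = 3)
  meal <- rep(c("breakfast", "lunch", "dinner"), n)
  u <- rep(rnorm(n, 0, 100), each = 3)
  kcal <- 600 + u + rnorm(3 * n, 0, 150)
  mm <- meal_energy_model(tibble::tibble(subject_id = subj, meal = meal, kcal = kcal))
  expect_lt(abs(mm$varcomp$between_subject - 100^2) / 100^2, 0.15)
  expect_lt(abs(mm$varcomp$residual - 150^2) / 150^2, 0.15)

  # independent errors: between-subject component collapses to ~0 and the
  # marginal means match the per-meal group means
  kcal0 <- 600 + rnorm(3 * n, 0, 150)
  mm0 <- meal_energy_model(tibble::tibble(subject_id = subj, meal = meal, kcal = kcal0))
  expect_lt(mm0$varcomp$between_subject, 0.05 * mm0$varcomp$residual)
  sample_means <- tapply(kcal0, meal, mean)
  expect_equal(
    mm0$means$estimate[match(names(sample_means), mm0$means$meal)],
    as.numeric(sample_means),
    tolerance = 1e-6
  )
})
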
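# Tidy wrappers for the statistical procedures used by the survey report:
# two-sample t-tests, Pearson chi-square, Benjamini-Hochberg FDR, Spearman
# correlation, one-way ANOVA with Tukey HSD, OLS regression, and a
# random-intercept mixed model for per-meal energy.

#' Two-sample two-sided t-test
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @param variant `"welch"` (default; Welch-Satterthwaite df) or `"pooled"`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, and per-group n,
#'   mean and SD.
#' @export
dq_t_test <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs at least two observations")
  }
  fit <- t.test(x, y, var.equal = (variant == "pooled"))
  tibble::tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    n_x = length(x), mean_x = mean(x), sd_x = sd(x),
    n_y = length(y), mean_y = mean(y), sd_y = sd(y)
  )
}

#' Pearson chi-square test on a contingency table
#'
#' No continuity correction is applied (plain Pearson X^2).
#'
#' @param tab An r x c matrix or table of counts.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
dq_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("contingency table has a zero marginal; expected counts undefined")
  }
  fit <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value
  )
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up procedure: with the p-values sorted ascending, find the largest k
#' with `p_(k) <= k * alpha / m` and flag the k smallest; adjusted p-values
#' are the standard BH values (`min over j >= i of m * p_(j) / j`, capped at
#' 1). Results are returned in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level, default 0.05.
#' @return Tibble of class `bh_fdr`, in input order: `p_value`,
#'   `p_adjusted`, `significant`; attributes `alpha`, `n_significant` and
#'   `largest_significant_p` (the largest raw p that is flagged, `NA` if
#'   none).
#' @export
benjamini_hochberg <- function(p, alpha = 0.05) {
  if (length(p) == 0) abort("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  sig <- adj <= alpha
  out <- tibble::tibble(p_value = p, p_adjusted = adj, significant = sig)
  class(out) <- c("bh_fdr", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "n_significant") <- sum(sig)
  attr(out, "largest_significant_p") <- if (any(sig)) max(p[sig]) else NA_real_
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged); the p-value uses
#' the t approximation, appropriate for tied data.
#'
#' @param x,y Numeric vectors of equal length, n >= 3; incomplete pairs are
#'   dropped.
#' @return One-row tibble: `rho`, `statistic` (t), `df`, `p_value`, `n`.
#' @export
dq_spearman <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Spearman correlation needs at least three complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman correlation undefined for a constant vector")
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    tstat <- sign(rho) * Inf
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(rho = rho, statistic = tstat, df = n - 2, p_value = p, n = n)
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Optionally natural-log transforms the response first (used for kcal/day,
#' which is right-skewed). Tukey honest-significant-difference p-values come
#' from the studentized-range distribution with the Tukey-Kramer
#' unequal-n standard error.
#'
#' @param values Numeric response.
#' @param group Grouping vector (coerced to factor), at least two groups
#'   with n >= 2 each.
#' @param log_transform Natural-log transform the response first; all values
#'   must then be positive.
#' @return List of class `anova_tukey`: `$anova` (one row: `statistic` F,
#'   `df1`, `df2`, `p_value`), `$tukey` (one row per pair: `contrast`,
#'   `estimate`, `conf_low`, `conf_high`, `p_adjusted`), `$groups` (n, mean,
#'   sd per group).
#' @export
anova_tukey <- function(values, group, log_transform = FALSE) {
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]
  group <- droplevels(factor(group[ok]))
  if (nlevels(group) < 2) abort("need at least two groups")
  if (any(table(group) < 2)) abort("each group needs at least two observations")
  if (log_transform) {
    if (any(values <= 0)) {
      abort("log transform requires strictly positive values")
    }
    values <- log(values)
  }
  fit <- aov(values ~ group)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  out <- list(
    anova = tibble::tibble(
      statistic = an[["F value"]][1],
      df1 = an[["Df"]][1], df2 = an[["Df"]][2],
      p_value = an[["Pr(>F)"]][1]
    ),
    tukey = tibble::tibble(
      contrast = rownames(tk),
      estimate = tk[, "diff"], conf_low = tk[, "lwr"],
      conf_high = tk[, "upr"], p_adjusted = tk[, "p adj"]
    ),
    groups = {
      grp_mean <- tapply(values, group, mean)
      grp_sd <- tapply(values, group, sd)
      tibble::tibble(
        group = levels(group),
        n = as.integer(table(group)),
        mean = as.numeric(grp_mean),
        sd = as.numeric(grp_sd)
      )
    }
  )
  class(out) <- "anova_tukey"
  out
}

#' @export
tidy.anova_tukey <- function(x, ...) x$tukey

#' @export
glance.anova_tukey <- function(x, ...) x$anova

#' Ordinary least squares with tidy output
#'
#' Least-squares fit with an intercept; two-sided p-values from the t
#' distribution. Rank deficiency is an error naming the collinear columns.
#'
#' @param data Data frame holding the response and predictors.
#' @param formula Model formula, e.g. `z_total ~ pct_energy_before_cutoff +
#'   age + gender`.
#' @return Tibble of class `dq_ols`: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`; attribute `n`.
#' @export
dq_ols <- function(data, formula) {
  formula <- as.formula(formula)
  mf <- stats::model.frame(formula, data)
  X <- model.matrix(formula, mf)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort(sprintf(
      "design matrix is rank deficient; collinear column(s): %s",
      paste(dropped, collapse = ", ")
    ))
  }
  fit <- lm(formula, data = data)
  cf <- summary(fit)$coefficients
  out <- tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std_error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "t value"]),
    p_value = unname(cf[, "Pr(>|t|)"])
  )
  class(out) <- c("dq_ols", class(out))
  attr(out, "n") <- nrow(mf)
  out
}

#' Random-intercept mixed model for per-meal energy
#'
#' Fits `kcal ~ meal + (1 | subject)` by REML: meal as a categorical
#' covariate and a subject random intercept to account for within-person
#' correlation. Returns per-meal marginal means with standard errors,
#' pairwise Wald-z contrasts, and the two variance components.
#'
#' @param meals Long tibble with columns `subject_id`, `meal` and `kcal`;
#'   every meal level must be observed and at least two subjects present.
#' @return List of class `meal_energy_model`: `$means` (`meal`, `estimate`,
#'   `std_error`), `$contrasts` (`contrast`, `estimate`, `std_error`,
#'   `statistic`, `p_value`), `$varcomp` (`between_subject`, `residual`),
#'   `$fit` (the underlying `lmerMod`).
#' @export
meal_energy_model <- function(meals) {
  meals <- tibble::as_tibble(meals)
  needed <- c("subject_id", "meal", "kcal")
  if (!all(needed %in% names(meals))) {
    abort("`meals` needs columns subject_id, meal, kcal")
  }
  meals$meal <- factor(meals$meal)
  counts <- table(meals$meal)
  if (any(counts == 0)) {
    abort(sprintf(
      "meal category with no observations: %s",
      paste(names(counts)[counts == 0], collapse = ", ")
    ))
  }
  if (length(unique(meals$subject_id)) < 2) {
    abort("need at least two subjects")
  }
  # cell-means coding: fixed effects are the per-meal marginal means
  fit <- lme4::lmer(
    kcal ~ 0 + meal + (1 | subject_id),
    data = meals,
    REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  lev <- levels(meals$meal)
  means <- tibble::tibble(
    meal = lev,
    estimate = unname(beta),
    std_error = sqrt(diag(V))
  )
  pairs <- utils::combn(seq_along(lev), 2)
  contrasts <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    est <- beta[[j]] - beta[[i]]
    se <- sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
    z <- est / se
    tibble::tibble(
      contrast = paste(lev[j], "-", lev[i]),
      estimate = est, std_error = se, statistic = z,
      p_value = 2 * pnorm(-abs(z))
    )
  })
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(
    means = means,
    contrasts = contrasts,
    varcomp = tibble::tibble(
      between_subject = vc$vcov[vc$grp == "subject_id"],
      residual = vc$vcov[vc$grp == "Residual"]
    ),
    fit = fit
  )
  class(out) <- "meal_energy_model"
  out
}

#' @export
tidy.meal_energy_model <- function(x, ...) x$means

#' @export
glance.meal_energy_model <- function(x, ...) {
  tibble::tibble(
    between_subject_var = x$varcomp$between_subject,
    residual_var = x$varcomp$residual,
    n_obs = stats::nobs(x$fit)
  )
}

#' @export
print.meal_energy_model <- function(x, ...) {
  cat("Random-intercept model of per-meal energy (kcal)\n")
  print(x$means)
  cat("variance components: between-subject",
      format(x$varcomp$between_subject, digits = 4),
      ", residual", format(x$varcomp$residual, digits = 4), "\n")
  invisible(x)
}
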
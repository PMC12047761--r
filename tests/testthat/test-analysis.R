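test_that("AIC values match an independent formula evaluation", {
  x <- 1:7
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1, 12.2, 13.8)
  f <- fit_polynomial_aic(x, y, degrees = c(1, 2))
  for (i in 1:2) {
    d <- c(1, 2)[i]
    fit <- lm(y ~ poly(x, d, raw = TRUE))
    rss <- sum((y - fitted(fit))^2)
    expect_equal(f$table$aic[i], 7 * log(rss / 7) + 2 * (d + 2), tolerance = 1e-10)
  }
  # AIC differences agree with the full Gaussian log-likelihood convention
  delta_pkg <- diff(f$table$aic)
  delta_stats <- diff(vapply(c(1, 2), function(d)
    AIC(lm(y ~ poly(x, d, raw = TRUE))), numeric(1)))
  expect_equal(delta_pkg, delta_stats, tolerance = 1e-8)
})

test_that("Akaike weights identify the generating polynomial", {
  set.seed(26)
  x <- -5:5
  y4 <- 0.02 * x^4 - 0.3 * x^2 + 1 + rnorm(11, 0, 0.05)
  f4 <- fit_polynomial_aic(x, y4, degrees = c(2, 4))
  expect_gt(f4$weights["degree4"], 0.999)
  expect_gt(f4$table$leading_coef[f4$table$degree == 4], 0)
  ylin <- 2 + 0.5 * x + rnorm(11, 0, 0.05)
  flin <- fit_polynomial_aic(x, ylin, degrees = c(1, 2))
  expect_lt(flin$weights["degree2"], 0.5)
})

test_that("Akaike weights always sum to one", {
  set.seed(27)
  for (i in 1:20) {
    x <- seq(-3, 3, length.out = sample(8:15, 1))
    y <- rnorm(length(x))
    f <- fit_polynomial_aic(x, y, degrees = c(1, 2, 4))
    expect_equal(sum(f$weights), 1, tolerance = 1e-12)
  }
  expect_error(fit_polynomial_aic(1:4, rnorm(4), degrees = 4), "points")
})

test_that("the one-sample trend t test matches hand calculations", {
  expect_equal(linear_trend_ttest(c(-2, -1, 0, 1, 2))$t, 0)
  r <- linear_trend_ttest(c(1, 2, 3))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(linear_trend_ttest(rnorm(15))$df, 14)
  expect_error(linear_trend_ttest(1), "participants")
})

test_that("the repeated-measures load ANOVA matches a sums-of-squares oracle", {
  tab <- expand.grid(participant = 1:3, load = c(1, 4))
  tab$accuracy <- c(0.9, 0.8, 0.7, 0.85, 0.75, 0.6)
  r <- anova_load(tab)
  # oracle: within-participant decomposition computed from scratch
  y <- matrix(tab$accuracy, nrow = 3)  # participants x loads
  gm <- mean(y)
  ss_load <- 3 * sum((colMeans(y) - gm)^2)
  ss_subj <- 2 * sum((rowMeans(y) - gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_load - ss_subj
  df1 <- 1; df2 <- 2
  expect_equal(r$F, (ss_load / df1) / (ss_err / df2), tolerance = 1e-10)
  expect_equal(r$df1, df1)
  expect_equal(r$df2, df2)
  # four load levels give numerator df 3; identical cells give F = 0
  tab4 <- expand.grid(participant = 1:4, load = c(1, 4, 6, 8))
  tab4$accuracy <- 0.8
  r4 <- anova_load(tab4)
  expect_equal(r4$df1, 3)
  expect_equal(r4$F, 0)
  expect_error(anova_load(tab4[-1, ]), "cells")
})

test_that("speeded bins have the combinatorial occupancy and conserve the grand mean", {
  cfg <- tiny_speeded_config()
  cfg$base_seed <- 60L
  rec <- simulate_speeded_participant(cfg, participant = 1, reps_per_type = 1)
  bins <- bin_speeded(rec)
  expect_equal(bins$n_trials[bins$value_difference == 0], 6)
  expect_equal(bins$n_trials[bins$value_difference == 5], 1)
  expect_equal(sum(bins$n_trials), 36)
  expect_equal(sum(bins$boost * bins$n_trials) / 36, mean(rec$boost))
  # counts symmetric by side balance
  expect_equal(bins$n_trials[bins$value_difference > 0],
               rev(bins$n_trials[bins$value_difference < 0]))
})

test_that("dACC composition follows the task recipe and is additive", {
  tab <- data.frame(participant = 1, bin = 1:3, value = c(1, 2, 3), boost = c(5, 4, 3))
  sp <- compose_dacc_signal(tab, "speeded")
  expect_equal(sp$dacc, tab$value + tab$boost)
  expect_equal(attr(sp, "recipe"), "value + boost")
  wm <- compose_dacc_signal(tab, "wm")
  expect_equal(wm$dacc, tab$boost)
  tab0 <- tab; tab0$value <- 0
  expect_equal(compose_dacc_signal(tab0, "speeded")$dacc, tab$boost)
  tabc <- tab; tabc$value <- tab$value + 0.7
  expect_equal(compose_dacc_signal(tabc, "speeded")$dacc, sp$dacc + 0.7)
  expect_error(compose_dacc_signal(tab, "nope"), "unknown task")
})

test_that("composition recomputed from raw records matches the binned table", {
  cfg <- tiny_speeded_config()
  cfg$base_seed <- 61L
  rec <- simulate_speeded_participant(cfg, participant = 1, reps_per_type = 2)
  bins <- compose_dacc_signal(bin_speeded(rec), "speeded")
  direct <- tapply(rec$value + rec$boost, rec$value_difference, mean)
  expect_equal(as.numeric(direct), bins$dacc[match(names(direct), bins$value_difference)])
})

test_that("foraging bins agree with an independent group-by pass", {
  cfg <- tiny_foraging_config()
  cfg$base_seed <- 62L
  rec <- simulate_foraging_participant(cfg, participant = 1, blocks = 1)
  fv <- bin_foraging(rec, "forage_value", n_bins = 6)
  qs <- unique(quantile(rec$forage_value, probs = seq(0, 1, length.out = 7)))
  rec$bin <- cut(rec$forage_value, qs, include.lowest = TRUE, labels = FALSE)
  oracle <- tapply(rec$boost, rec$bin, mean)
  expect_equal(as.numeric(oracle), fv$boost[match(names(oracle), fv$bin)])
  # constant boost gives a flat profile in both binnings
  rec$boost <- 2
  expect_true(all(bin_foraging(rec, "forage_value")$boost == 2))
  expect_true(all(bin_foraging(rec, "difficulty")$boost == 2))
})
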
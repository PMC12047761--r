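#' Bin speeded-task records by value difference
#'
#' One bin per value-difference level (-5 ... +5): within-participant means of
#' the boost, value and surprise regressors, the trial-type surprise
#' (absolute deviation of the trial's total offered reward from the session
#' mean), accuracy (excluding timeouts and equal-value trials) and reaction
#' time.
#'
#' @param records Speeded trial records.
#' @return A data.frame with one row per (participant, value_difference).
#' @export
bin_speeded <- function(records) {
  records$session_mean_total <- ave(records$total_reward, records$participant)
  records$trial_surprise <- trial_type_surprise(records$total_reward,
                                                records$session_mean_total)
  out <- aggregate(
    cbind(boost, value, surprise, trial_surprise, rt_cycles) ~ participant + value_difference,
    data = records, FUN = mean)
  acc <- aggregate(correct ~ participant + value_difference, data = records,
                   FUN = mean, na.rm = TRUE, na.action = NULL)
  names(acc)[3] <- "accuracy"
  n <- aggregate(cbind(n_trials = trial) ~ participant + value_difference,
                 data = records, FUN = length)
  out <- merge(merge(out, acc), n)
  if (any(!table(out$value_difference) > 0)) stop("empty value-difference bin")
  out[order(out$participant, out$value_difference), ]
}

#' Group-average a per-participant regressor table
#'
#' @param table Per-participant bin table ([bin_speeded()], [bin_wm()],
#'   [bin_foraging()]).
#' @param bin Name of the bin column.
#' @return Column means per bin across participants.
#' @export
group_bins <- function(table, bin) {
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  num <- setdiff(num, c("participant", bin))
  aggregate(table[num], by = table[bin], FUN = mean, na.rm = TRUE)
}

#' Compose the simulated dACC signal
#'
#' Adds a `dacc` column to a binned regressor table. The recipe is
#' task-specific: `value + boost` for the speeded task, `boost` alone for
#' working memory, `boost` for foraging (with the whole-MPFC composite
#' `boost + value` always available as `mpfc`). The recipe used is recorded
#' in the `"recipe"` attribute.
#'
#' @param table A binned regressor table containing `boost` (and `value`).
#' @param task `"speeded"`, `"wm"` or `"foraging"`.
#' @return The table with `dacc` (and `mpfc`) columns.
#' @export
compose_dacc_signal <- function(table, task) {
  recipe <- switch(task,
    speeded = "value + boost",
    wm = "boost",
    foraging = "boost",
    stop("unknown task id: ", task))
  table$dacc <- if (recipe == "boost") table$boost else table$value + table$boost
  if (!is.null(table$value)) table$mpfc <- table$value + table$boost
  attr(table, "recipe") <- recipe
  table
}

#' Polynomial fits compared by AIC and Akaike weights
#'
#' Least-squares polynomial fits of `y` on `x` for each degree, compared with
#' `AIC = n * log(RSS / n) + 2 * k`, where `k` counts the polynomial
#' coefficients plus the noise variance. Akaike weights are
#' `exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`. The small-sample corrected
#' AICc (`+ 2 k (k + 1) / (n - k - 1)`) is available via `aicc`.
#'
#' @param x Bin centers.
#' @param y Signal per bin.
#' @param degrees Polynomial degrees to compare.
#' @param aicc Use the small-sample correction.
#' @return A list with `table` (degree, aic, weight, leading coefficient),
#'   `fits` (the `lm` objects) and `weights`.
#' @export
fit_polynomial_aic <- function(x, y, degrees = c(1, 2, 4), aicc = FALSE) {
  n <- length(x)
  if (n < max(degrees) + 2) stop("need at least max(degrees) + 2 points")
  fits <- lapply(degrees, function(d) lm(y ~ poly(x, d, raw = TRUE)))
  aic <- vapply(seq_along(degrees), function(i) {
    rss <- sum(residuals(fits[[i]])^2)
    k <- degrees[i] + 2  # coefficients (incl. intercept) + noise variance
    a <- n * log(rss / n) + 2 * k
    if (aicc) a <- a + 2 * k * (k + 1) / (n - k - 1)
    a
  }, numeric(1))
  if (any(vapply(fits, function(f) any(is.na(coef(f))), logical(1))))
    stop("rank-deficient polynomial design")
  delta <- aic - min(aic)
  w <- exp(-delta / 2) / sum(exp(-delta / 2))
  lead <- vapply(seq_along(degrees), function(i) unname(rev(coef(fits[[i]]))[1]), numeric(1))
  list(
    table = data.frame(degree = degrees, aic = aic, weight = w,
                       leading_coef = lead),
    fits = setNames(fits, paste0("degree", degrees)),
    weights = setNames(w, paste0("degree", degrees))
  )
}

#' Per-participant linear-trend slopes
#'
#' Regresses a binned signal on the bin variable within each participant and
#' returns one slope per participant.
#'
#' @param table Per-participant bin table.
#' @param signal Column to regress.
#' @param x Bin column (numeric).
#' @return Named numeric vector of slopes.
#' @export
participant_slopes <- function(table, signal, x) {
  vapply(split(table, table$participant), function(d)
    unname(coef(lm(d[[signal]] ~ d[[x]]))[2]), numeric(1))
}

#' One-sample t test on per-participant slopes
#'
#' Tests whether the mean of the per-participant regression slopes differs
#' from zero; `df = participants - 1`.
#'
#' @param slopes One slope per participant.
#' @return A list with `t`, `df`, `p` (two-sided) and `mean_slope`.
#' @export
linear_trend_ttest <- function(slopes) {
  if (length(slopes) < 2) stop("need at least 2 participants")
  tt <- t.test(slopes)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_slope = mean(slopes))
}

#' Repeated-measures ANOVA for the load main effect
#'
#' Standard one-way repeated-measures decomposition
#' (`aov(accuracy ~ load + Error(participant))`): the load effect is tested
#' against the participant-by-load residual, with dfs `(levels - 1,
#' (levels - 1) * (participants - 1))`.
#'
#' @param table Data.frame with `participant`, `load` and a response column.
#' @param response Name of the response column.
#' @return A list with `F`, `df1`, `df2`, `p`.
#' @export
anova_load <- function(table, response = "accuracy") {
  tab <- table(table$participant, table$load)
  if (any(tab != 1)) stop("missing or duplicated (participant, load) cells")
  d <- data.frame(y = table[[response]], load = factor(table$load),
                  participant = factor(table$participant))
  fit <- aov(y ~ load + Error(participant), data = d)
  s <- summary(fit)[["Error: Within"]][[1]]
  f <- s["load", "F value"]; p <- s["load", "Pr(>F)"]
  if (s["load", "Sum Sq"] == 0) { f <- 0; p <- 1 }  # degenerate: no effect at all
  list(F = f, df1 = s["load", "Df"], df2 = s["Residuals", "Df"], p = p)
}

#' Bin working-memory records by load
#'
#' @param records WM trial records.
#' @return One row per (participant, load) with mean boost, value, surprise
#'   and accuracy.
#' @export
bin_wm <- function(records) {
  out <- aggregate(cbind(boost, value, surprise, accuracy = correct) ~ participant + load,
                   data = records, FUN = mean)
  out[order(out$participant, out$load), ]
}

#' Bin foraging records by foraging value or choice difficulty
#'
#' Quantile bins (computed over all trials, so bins are shared across
#' participants) of the chosen variable; per (participant, bin) means of
#' boost, value and the whole-MPFC composite. Choice difficulty is the
#' negative absolute difference between the engage and forage values: maximal
#' when the two options are closest in value.
#'
#' @param records Foraging trial records.
#' @param by `"forage_value"` or `"difficulty"`.
#' @param n_bins Number of quantile bins (at least 6).
#' @return One row per (participant, bin) with the bin center `x`.
#' @export
bin_foraging <- function(records, by = c("forage_value", "difficulty"), n_bins = 12L) {
  by <- match.arg(by)
  x <- records[[by]]
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
  if (length(unique(bins)) < 6) stop("fewer than 6 occupied bins")
  records$bin <- bins
  out <- aggregate(cbind(boost, value, x = records[[by]]) ~ participant + bin,
                   data = records, FUN = mean)
  out$mpfc <- out$boost + out$value
  out[order(out$participant, out$bin), ]
}
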
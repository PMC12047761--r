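#' Simulate a full multi-participant experiment
#'
#' Runs pretraining and the task session for each simulated participant, with
#' participant `p` seeded at `base_seed + p`, and binds the trial-record
#' streams.
#'
#' @param task `"speeded"`, `"wm"` or `"foraging"`.
#' @param config Full [rml_config()]; defaults for the task when `NULL`.
#' @param n_participants Overrides the config participant count.
#' @param reps Scale knob: reps per trial type (speeded), per load (wm) or
#'   blocks (foraging); `NULL` keeps the config value.
#' @param base_seed Base RNG seed (overrides `config$base_seed`).
#' @return A data.frame of trial records across participants.
#' @export
simulate_experiment <- function(task = c("speeded", "wm", "foraging"),
                                config = NULL, n_participants = NULL,
                                reps = NULL, base_seed = NULL) {
  task <- match.arg(task)
  if (is.null(config)) config <- rml_config(task)
  validate_config(config)
  if (!is.null(base_seed)) config$base_seed <- as.integer(base_seed)
  np <- if (is.null(n_participants)) config$task$n_participants else n_participants
  sim_one <- switch(task,
    speeded = function(p) simulate_speeded_participant(config, p, reps_per_type = reps),
    wm = function(p) simulate_wm_participant(config, p, reps_per_load = reps),
    foraging = function(p) simulate_foraging_participant(config, p, blocks = reps))
  do.call(rbind, lapply(seq_len(np), sim_one))
}

#' Analyse an experiment's trial records
#'
#' Computes the task's headline statistics from a trial-record stream:
#'
#' * speeded: value-difference bins, quartic-vs-quadratic AIC comparison of
#'   the composed dACC signal (`value + boost`), quadratic-coefficient signs
#'   of the value and boost components, and the trial-type surprise profile;
#' * wm: per-load bins, one-sample t test on per-participant boost-on-load
#'   slopes, pooled accuracy, repeated-measures load ANOVA on accuracy, and
#'   trend tests for the surprise and value regressors;
#' * foraging: forage-value and difficulty bins, quadratic-vs-linear AIC
#'   comparison of the boost profile (and of the whole-MPFC composite), and
#'   the t test on per-participant difficulty slopes.
#'
#' @param records Output of [simulate_experiment()].
#' @param task Task id.
#' @param aicc Use small-sample corrected AIC.
#' @return A named list of statistics and binned tables.
#' @export
analyze_experiment <- function(records, task = c("speeded", "wm", "foraging"),
                               aicc = FALSE) {
  task <- match.arg(task)
  if (task == "speeded") {
    bins <- compose_dacc_signal(bin_speeded(records), "speeded")
    g <- group_bins(bins, "value_difference")
    x <- g$value_difference
    quartic <- fit_polynomial_aic(x, g$dacc, degrees = c(2, 4), aicc = aicc)
    value_fit <- fit_polynomial_aic(x, g$value, degrees = 2, aicc = aicc)
    boost_fit <- fit_polynomial_aic(x, g$boost, degrees = 2, aicc = aicc)
    q4 <- coef(quartic$fits$degree4)
    list(task = task, bins = bins, group = g,
         quartic_weight = unname(quartic$weights["degree4"]),
         quartic_leading = unname(q4[5]), quartic_quadratic = unname(q4[3]),
         value_quadratic = unname(coef(value_fit$fits$degree2)[3]),
         boost_quadratic = unname(coef(boost_fit$fits$degree2)[3]),
         aic_table = quartic$table)
  } else if (task == "wm") {
    bins <- compose_dacc_signal(bin_wm(records), "wm")
    trend <- function(signal)
      linear_trend_ttest(participant_slopes(bins, signal, "load"))
    list(task = task, bins = bins, group = group_bins(bins, "load"),
         boost_trend = trend("boost"),
         surprise_trend = trend("surprise"),
         value_trend = trend("value"),
         accuracy_pct = 100 * mean(records$correct),
         load_anova = anova_load(bins))
  } else {
    fv <- bin_foraging(records, "forage_value")
    dif <- bin_foraging(records, "difficulty")
    gfv <- group_bins(fv, "bin")
    quad <- fit_polynomial_aic(gfv$x, gfv$boost, degrees = c(1, 2), aicc = aicc)
    quad_mpfc <- fit_polynomial_aic(gfv$x, gfv$mpfc, degrees = c(1, 2), aicc = aicc)
    slope_t <- linear_trend_ttest(participant_slopes(dif, "boost", "x"))
    slope_t_mpfc <- linear_trend_ttest(participant_slopes(dif, "mpfc", "x"))
    list(task = task, forage_bins = fv, difficulty_bins = dif, group = gfv,
         quadratic_weight = unname(quad$weights["degree2"]),
         quadratic_leading = unname(coef(quad$fits$degree2)[3]),
         quadratic_weight_mpfc = unname(quad_mpfc$weights["degree2"]),
         quadratic_leading_mpfc = unname(coef(quad_mpfc$fits$degree2)[3]),
         difficulty_trend = slope_t, difficulty_trend_mpfc = slope_t_mpfc)
  }
}

#' Write / read trial records as CSV
#'
#' Numeric columns are serialised with 17 significant digits, so a
#' write-read round trip reproduces them exactly; list columns are not
#' supported (trial records contain none).
#'
#' @param records Trial-record data.frame.
#' @param path CSV file path.
#' @return `path` invisibly ([write_records()]); the records
#'   ([read_records()]).
#' @export
write_records <- function(records, path) {
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname write_records
#' @param template Optional records data.frame whose column classes are
#'   restored on read.
#' @export
read_records <- function(path, template = NULL) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 warning = function(w) stop("malformed records file: ",
                                            conditionMessage(w)))
  if (!is.null(template))
    for (nm in names(template))
      if (is.logical(template[[nm]])) df[[nm]] <- as.logical(df[[nm]])
  df
}

#' Run a reproducible experiment to disk
#'
#' Executes [simulate_experiment()] participant by participant, writes one
#' trial-record CSV per participant, the binned regressor table, a statistics
#' JSON and a run manifest (resolved config snapshot, seeds, package version
#' and per-file MD5 checksums). Re-running with the same config and base seed
#' reproduces the output tree bit-identically.
#'
#' @param task Task id.
#' @param out_dir Output directory (created if needed).
#' @param config_path Optional YAML/JSON config file.
#' @param n_participants,reps,base_seed Scale and seed overrides.
#' @return The manifest, invisibly.
#' @export
run_experiment <- function(task, out_dir, config_path = NULL,
                           n_participants = NULL, reps = NULL, base_seed = NULL) {
  config <- load_config(config_path, task)
  if (!is.null(base_seed)) config$base_seed <- as.integer(base_seed)
  np <- if (is.null(n_participants)) config$task$n_participants else n_participants
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- simulate_experiment(task, config, n_participants = np, reps = reps)
  files <- character(0)
  for (p in unique(records$participant)) {
    f <- file.path(out_dir, sprintf("%s_participant%03d.csv", task, p))
    write_records(records[records$participant == p, ], f)
    files <- c(files, f)
  }
  stats <- analyze_experiment(records, task)
  tables <- stats[vapply(stats, is.data.frame, logical(1))]
  for (nm in names(tables)) {
    f <- file.path(out_dir, sprintf("%s_%s.csv", task, nm))
    write_records(tables[[nm]], f)
    files <- c(files, f)
  }
  scalar_stats <- stats[vapply(stats, function(x) !is.data.frame(x), logical(1))]
  stats_file <- file.path(out_dir, sprintf("%s_stats.json", task))
  jsonlite::write_json(scalar_stats, stats_file, auto_unbox = TRUE, digits = NA)
  files <- c(files, stats_file)
  manifest <- list(
    task = task, base_seed = config$base_seed, n_participants = np,
    seeds = config$base_seed + seq_len(np),
    package_version = as.character(packageVersion("rmlcontrol")),
    config = unclass(config),
    checksums = as.list(tools::md5sum(files))
  )
  manifest_file <- file.path(out_dir, sprintf("%s_manifest.json", task))
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
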
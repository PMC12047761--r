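#' Default configuration for a simulated experiment
#'
#' Returns the full nested configuration for one of the three tasks. All model
#' parameters are exposed here; [load_config()] merges a user YAML/JSON file
#' over these defaults. Sections:
#'
#' * `agent`: boost grid, selection temperatures, Kalman noise terms, boost
#'   cost rate and the affine-then-clip LC/VTA mappings (dimensionless LC gain
#'   in `[lc_min, lc_max]`, VTA reward scale with 1 = no scaling).
#' * `ddm`: diffusion module (evidence units per cycle); `base_boundary` is
#'   the half-separation at minimum LC, shrunk towards `boundary_floor`
#'   exponentially in LC; `bias0` the baseline start point (0 outside
#'   foraging).
#' * `task`: design constants (reward grid, loads, deadlines, replications).
#' * `wm`: competitive recurrent network (only for `task = "wm"`).
#' * `analysis`: binning and model-comparison settings.
#'
#' @param task One of `"speeded"`, `"wm"`, `"foraging"`.
#' @return A named nested list of class `rml_config`.
#' @export
rml_config <- function(task = c("speeded", "wm", "foraging")) {
  task <- match.arg(task)
  agent <- list(
    boost_levels = seq(0, 6, length.out = 10),
    boost_temperature = 0.06,
    action_temperature = 0.25,
    cost_rate = 0.3,
    obs_noise_boost = 1,
    obs_noise_act = 1,
    process_noise = 0,
    q_init_mean = 7,
    q_init_uncertainty = 25,
    act_init_mean = 4.5,
    act_init_uncertainty = 25,
    lc_intercept = 0, lc_coeff = 1 / 6, lc_min = 0, lc_max = 1,
    vta_intercept = 1, vta_coeff = 0, vta_min = 1, vta_max = 1
  )
  ddm <- list(
    base_boundary = 220,
    boundary_floor = 40,
    boundary_shrink = 2.2,
    noise_sd = 1,
    drift_scale = 0.02,
    bias0 = 0,
    bias_discount = 1.2,
    max_cycles = 14000L
  )
  cfg <- switch(task,
    speeded = list(
      task = list(
        name = "speeded",
        reward_levels = 2:7,
        reps_per_type = 54L,
        n_participants = 200L,
        pretrain_reps = 30L
      ),
      agent = agent,
      ddm = ddm
    ),
    wm = list(
      task = list(
        name = "wm",
        loads = c(1L, 4L, 6L, 8L),
        reps_per_load = 90L,
        n_participants = 15L,
        match_prob = 0.5
      ),
      agent = modifyList(agent, list(
        cost_rate = 0.01,
        boost_temperature = 0.015,
        obs_noise_boost = 0.06,
        obs_noise_act = 0.12,
        q_init_mean = 1,
        q_init_uncertainty = 1,
        act_init_mean = 0.5,
        act_init_uncertainty = 1
      )),
      wm = list(
        n_units = 16L,
        recurrent_weight = 1,
        inhibition_weight = 0.02,
        gain_base = 1.02,
        gain_lc_coeff = 0.3,
        delay_steps = 50L,
        noise_sd = 0.05,
        decision_noise_sd = 0.416,
        criterion = 0.5,
        readout_off_weight = 0,
        encode_value = 1,
        activation_min = 0,
        activation_max = 1
      )
    ),
    foraging = list(
      task = list(
        name = "foraging",
        n_contexts = 16L,
        n_bandits = 8L,
        context_means = seq(4, 7, length.out = 16),
        context_spreads = c(seq(0.5, 3.5, length.out = 8),
                            seq(3.1, 0.5, length.out = 8)),
        arm_margin = 2,
        reward_sd = 0.5,
        forage_cost = 2.5,
        max_forages = 20L,
        blocks = 18L,
        n_participants = 40L,
        pretrain_reps = 25L
      ),
      agent = modifyList(agent, list(
        boost_levels = seq(0, 8, length.out = 10),
        lc_coeff = 1 / 8,
        cost_rate = 0.12,
        obs_noise_boost = 1.5,
        obs_noise_act = 1
      )),
      ddm = modifyList(ddm, list(
        base_boundary = 140,
        boundary_floor = 20,
        boundary_shrink = 1.5,
        drift_scale = 0.06,
        bias0 = 6,
        max_cycles = 2000L
      ))
    )
  )
  cfg$analysis <- list(
    difficulty_breaks = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, Inf),
    foraging_bins = 12L,
    aicc = FALSE
  )
  cfg$base_seed <- 1L
  structure(cfg, class = "rml_config")
}

validate_scalar <- function(x, key, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("config key '%s' must be a finite numeric scalar", key))
  if (positive && x <= 0)
    stop(sprintf("config key '%s' must be strictly positive", key))
  invisible(x)
}

#' Validate a configuration
#'
#' Checks types and ranges of the fields that the simulators rely on.
#' @param config An `rml_config` list.
#' @return The config, invisibly; errors name the offending key.
#' @export
validate_config <- function(config) {
  a <- config$agent
  if (!is.numeric(a$boost_levels) || length(a$boost_levels) < 2L ||
      is.unsorted(a$boost_levels, strictly = TRUE) || any(a$boost_levels < 0))
    stop("config key 'agent$boost_levels' must be a strictly increasing non-negative grid")
  validate_scalar(a$boost_temperature, "agent$boost_temperature", positive = TRUE)
  validate_scalar(a$action_temperature, "agent$action_temperature", positive = TRUE)
  validate_scalar(a$cost_rate, "agent$cost_rate")
  if (a$cost_rate < 0) stop("config key 'agent$cost_rate' must be non-negative")
  for (k in c("obs_noise_boost", "obs_noise_act", "process_noise",
              "q_init_uncertainty", "act_init_uncertainty"))
    if (a[[k]] < 0) stop(sprintf("config key 'agent$%s' must be non-negative", k))
  if (a$lc_min > a$lc_max) stop("config key 'agent$lc_min' must not exceed lc_max")
  if (a$vta_min > a$vta_max) stop("config key 'agent$vta_min' must not exceed vta_max")
  if (!is.null(config$ddm)) {
    d <- config$ddm
    validate_scalar(d$base_boundary, "ddm$base_boundary", positive = TRUE)
    validate_scalar(d$boundary_floor, "ddm$boundary_floor", positive = TRUE)
    validate_scalar(d$noise_sd, "ddm$noise_sd", positive = TRUE)
    if (d$boundary_floor > d$base_boundary)
      stop("config key 'ddm$boundary_floor' must not exceed base_boundary")
    if (d$max_cycles < 1) stop("config key 'ddm$max_cycles' must be at least 1")
    if (abs(d$bias0) >= d$boundary_floor)
      stop("config key 'ddm$bias0' magnitude must be below boundary_floor")
  }
  if (!is.null(config$wm)) {
    w <- config$wm
    if (w$inhibition_weight < 0) stop("config key 'wm$inhibition_weight' must be non-negative")
    if (w$delay_steps < 1) stop("config key 'wm$delay_steps' must be at least 1")
    if (w$activation_min >= w$activation_max)
      stop("config key 'wm$activation_min' must be below activation_max")
  }
  invisible(config)
}

merge_config <- function(defaults, override, path = character()) {
  for (key in names(override)) {
    full <- paste(c(path, key), collapse = "$")
    if (!key %in% names(defaults))
      stop(sprintf("unknown config key '%s'", full))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(override[[key]]))
        stop(sprintf("config key '%s' must be a section", full))
      defaults[[key]] <- merge_config(defaults[[key]], override[[key]], c(path, key))
    } else {
      defaults[[key]] <- override[[key]]
    }
  }
  defaults
}

#' Load and validate a configuration file
#'
#' Reads a YAML (or JSON, which YAML subsumes) file and merges it over the
#' task defaults from [rml_config()]. Unknown keys raise an error naming the
#' key; an empty file yields the full defaults. The resolved configuration is
#' what [run_experiment()] snapshots into the run manifest.
#'
#' @param path Path to a YAML/JSON config file, or `NULL` for pure defaults.
#' @param task Task name; may also be given as `task:` inside the file.
#' @return A validated `rml_config`.
#' @export
load_config <- function(path = NULL, task = NULL) {
  override <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    override <- yaml::read_yaml(path)
    if (is.null(override)) override <- list()
  }
  if (is.null(task)) task <- override$task$name
  if (is.null(task)) stop("task must be given (argument or task$name in the file)")
  cfg <- merge_config(unclass(rml_config(task)), override)
  cfg$task$name <- task
  cfg <- structure(cfg, class = "rml_config")
  validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#' @param config An `rml_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}
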
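#' Create a meta-learning control agent
#'
#' The agent holds two families of Kalman-tracked values, mirroring the two
#' medial-prefrontal modules of the architecture:
#'
#' * an action-value store (`MPFC_act`): one [value_estimate()] per option,
#'   whose difference `delta-v` drives the task module;
#' * a boost-value store (`MPFC_boost`): one estimate per (condition state,
#'   boost level), learned from net value (reward minus boost cost), from
#'   which the control intensity is sampled by softmax.
#'
#' The agent is a mutable environment; all q-table updates happen in place.
#'
#' @param config The `agent` section of an [rml_config()] (or a full config,
#'   from which the section is taken).
#' @return An object of class `rml_agent`.
#' @export
rml_agent <- function(config = rml_config("speeded")) {
  if (inherits(config, "rml_config") || !is.null(config$agent)) config <- config$agent
  ag <- new.env(parent = emptyenv())
  ag$config <- config
  ag$n_levels <- length(config$boost_levels)
  ag$q_mean <- matrix(numeric(0), nrow = 0, ncol = ag$n_levels)
  ag$q_unc <- matrix(numeric(0), nrow = 0, ncol = ag$n_levels)
  ag$act_mean <- numeric(0)
  ag$act_unc <- numeric(0)
  class(ag) <- "rml_agent"
  ag
}

#' @export
print.rml_agent <- function(x, ...) {
  cat(sprintf("<rml_agent> %d boost levels, %d condition states, %d options\n",
              x$n_levels, nrow(x$q_mean), length(x$act_mean)))
  invisible(x)
}

#' Register a condition state for boost learning
#'
#' Boost q-values are initialised at the configured optimistic prior with high
#' uncertainty, which guarantees early exploration of the boost grid.
#'
#' @param agent An [rml_agent()].
#' @param state_id Character label of the condition visible at trial onset.
#' @return The agent, invisibly.
#' @export
register_state <- function(agent, state_id) {
  if (!state_id %in% rownames(agent$q_mean)) {
    cfg <- agent$config
    agent$q_mean <- rbind(agent$q_mean, matrix(cfg$q_init_mean, 1, agent$n_levels,
                                               dimnames = list(state_id, NULL)))
    agent$q_unc <- rbind(agent$q_unc, matrix(cfg$q_init_uncertainty, 1, agent$n_levels,
                                             dimnames = list(state_id, NULL)))
  }
  invisible(agent)
}

#' Register an option for action-value learning
#' @inheritParams register_state
#' @param option_id Character label of the option/stimulus.
#' @return The agent, invisibly.
#' @export
register_option <- function(agent, option_id) {
  new <- setdiff(option_id, names(agent$act_mean))
  if (length(new)) {
    cfg <- agent$config
    agent$act_mean[new] <- cfg$act_init_mean
    agent$act_unc[new] <- cfg$act_init_uncertainty
  }
  invisible(agent)
}

softmax_probs <- function(q, temperature) {
  z <- (q - max(q)) / temperature
  p <- exp(z)
  p / sum(p)
}

#' Sample a boost level for a condition state
#'
#' Softmax over the learned q-value means at the configured boost temperature.
#' Exact ties are resolved by the sampler itself.
#'
#' @inheritParams register_state
#' @return A list with `level` (boost intensity on the configured grid) and
#'   `index` (position in the grid).
#' @export
select_boost <- function(agent, state_id) {
  i <- match(state_id, rownames(agent$q_mean))
  if (is.na(i)) stop("unknown boost state: ", state_id)
  p <- softmax_probs(agent$q_mean[i, ], agent$config$boost_temperature)
  j <- sample.int(agent$n_levels, 1L, prob = p)
  list(level = agent$config$boost_levels[j], index = j)
}

#' Intrinsic cost of a boost level
#'
#' Linear through the origin: `cost = cost_rate * level`. The cost is
#' subtracted from reward before boost q-values are updated, so the learned
#' boost policy maximises net value.
#'
#' @param level Boost intensity (non-negative scalar or vector).
#' @param cost_rate Cost per unit boost (reward units per boost unit).
#' @return Cost in reward units.
#' @export
boost_cost <- function(level, cost_rate) {
  if (any(level < 0)) stop("boost level must be non-negative")
  cost_rate * level
}

#' LC and VTA outputs for a boost level
#'
#' Affine-then-clip maps from the boost intensity: both outputs are
#' deterministic, non-decreasing and bounded by the configured min/max. With
#' the default VTA mapping (`vta = 1` for all levels) outcomes are unscaled
#' and learning reduces to plain Kalman reinforcement learning.
#'
#' @param level Boost intensity; must lie on the configured grid range.
#' @param config The `agent` section of an [rml_config()].
#' @return A list with `lc` and `vta` scalars.
#' @export
compute_neuromodulation <- function(level, config) {
  if (inherits(config, "rml_config") || !is.null(config$agent)) config <- config$agent
  rng <- range(config$boost_levels)
  if (level < rng[1] || level > rng[2])
    stop("boost level outside the configured range")
  if (config$lc_coeff < 0 || config$vta_coeff < 0)
    stop("LC/VTA mappings must be non-decreasing in boost")
  lc <- min(max(config$lc_intercept + config$lc_coeff * level, config$lc_min), config$lc_max)
  vta <- min(max(config$vta_intercept + config$vta_coeff * level, config$vta_min), config$vta_max)
  list(lc = lc, vta = vta)
}

#' Expected-value difference between two options
#'
#' @param agent An [rml_agent()], or `value_left` may be a [value_estimate()].
#' @param left,right Option labels (when `agent` is given).
#' @return Signed scalar `mean_left - mean_right`; the sign encodes the
#'   favoured side.
#' @export
compute_dv <- function(agent, left, right) {
  if (inherits(agent, "value_estimate"))
    return(agent$mean - left$mean)
  i <- match(c(left, right), names(agent$act_mean))
  if (anyNA(i)) stop("unknown option label")
  unname(agent$act_mean[i[1]] - agent$act_mean[i[2]])
}

#' Update a boost q-value with a net outcome
#' @inheritParams register_state
#' @param index Boost level index (from [select_boost()]).
#' @param net_outcome Reward minus boost cost (and any other cost) for the trial.
#' @param vta VTA scaling signal.
#' @return The q mean before the update (the trial-onset value expectation).
#' @export
update_boost_q <- function(agent, state_id, index, net_outcome, vta = 1) {
  i <- match(state_id, rownames(agent$q_mean))
  if (is.na(i)) stop("unknown boost state: ", state_id)
  cfg <- agent$config
  est <- value_estimate(agent$q_mean[i, index], agent$q_unc[i, index], cfg$obs_noise_boost)
  prior <- est$mean
  est <- kalman_update(est, net_outcome, vta = vta, process_noise = cfg$process_noise)
  agent$q_mean[i, index] <- est$mean
  agent$q_unc[i, index] <- est$uncertainty
  prior
}

#' Update an option's action value with an outcome
#' @inheritParams update_boost_q
#' @param option_id Option label.
#' @param outcome Observed reward.
#' @return The action-value mean before the update.
#' @export
update_act_value <- function(agent, option_id, outcome, vta = 1) {
  i <- match(option_id, names(agent$act_mean))
  if (is.na(i)) stop("unknown option label: ", option_id)
  cfg <- agent$config
  est <- value_estimate(agent$act_mean[i], agent$act_unc[i], cfg$obs_noise_act)
  prior <- est$mean
  est <- kalman_update(est, outcome, vta = vta, process_noise = cfg$process_noise)
  agent$act_mean[i] <- est$mean
  agent$act_unc[i] <- est$uncertainty
  prior
}

#' Mean boost q-values for a state
#' @inheritParams register_state
#' @return Named numeric vector over boost levels.
#' @export
boost_q_means <- function(agent, state_id) {
  i <- match(state_id, rownames(agent$q_mean))
  if (is.na(i)) stop("unknown boost state: ", state_id)
  setNames(agent$q_mean[i, ], format(agent$config$boost_levels, trim = TRUE))
}

#' Action-value means
#' @inheritParams register_state
#' @return Named numeric vector over registered options.
#' @export
act_values <- function(agent) agent$act_mean
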
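#' Generate the speeded decision-making trial sequence
#'
#' The design crosses six reward levels (2--7) for the left and right option,
#' giving 36 trial types balanced by side; each type is presented
#' `reps_per_type` times and the sequence is shuffled. Each reward level has
#' two interchangeable fractal stimuli; the one shown is sampled per trial.
#'
#' @param reps_per_type Presentations of each of the 36 types.
#' @param reward_levels Integer reward levels (default 2:7).
#' @return A data.frame with one row per trial: `type_id`, `left_reward`,
#'   `right_reward`, `value_difference` (left minus right), `left_stim`,
#'   `right_stim`.
#' @export
generate_speeded_trials <- function(reps_per_type = 54L, reward_levels = 2:7) {
  stopifnot(reps_per_type >= 1)
  grid <- expand.grid(left_reward = reward_levels, right_reward = reward_levels,
                      KEEP.OUT.ATTRS = FALSE)
  grid$type_id <- seq_len(nrow(grid))
  trials <- grid[rep(seq_len(nrow(grid)), each = reps_per_type), ]
  trials <- trials[sample.int(nrow(trials)), ]
  rownames(trials) <- NULL
  trials$value_difference <- trials$left_reward - trials$right_reward
  # two fractal exemplars per reward level; pick one per side and trial
  pick <- function(level) paste0("s", level, ".", sample(1:2, length(level), replace = TRUE))
  trials$left_stim <- pick(trials$left_reward)
  trials$right_stim <- pick(trials$right_reward)
  trials
}

#' Linear reward devaluation with reaction time
#'
#' The delivered reward decays linearly from its full value at `rt = 0` to 0
#' at the response deadline; no reward is given at or beyond the deadline.
#'
#' @param reward Reward on offer.
#' @param rt_cycles Reaction time in DDM cycles (non-negative).
#' @param deadline Response deadline in cycles.
#' @return Devalued reward (vectorised).
#' @export
reward_devaluation <- function(reward, rt_cycles, deadline) {
  if (any(rt_cycles < 0)) stop("rt_cycles must be non-negative")
  reward * pmax(0, 1 - rt_cycles / deadline)
}

#' Pretrain option values on stationary rewards
#'
#' Before the task the agent learns the value of each stimulus from repeated
#' exposure to its (stationary) reward. Post-training means converge to the
#' true option values at the Kalman sample-average rate.
#'
#' @param agent An [rml_agent()].
#' @param stimuli Named numeric vector: stimulus label -> true reward.
#' @param reps Exposures per stimulus.
#' @param reward_sd Outcome noise around the true reward (0 = deterministic).
#' @return The agent, invisibly.
#' @export
pretrain_values <- function(agent, stimuli, reps = 30L, reward_sd = 0) {
  register_option(agent, names(stimuli))
  order <- sample(rep(names(stimuli), reps))
  for (s in order) {
    r <- stimuli[[s]] + if (reward_sd > 0) rnorm(1, 0, reward_sd) else 0
    update_act_value(agent, s, r)
  }
  invisible(agent)
}

speeded_stimuli <- function(reward_levels = 2:7) {
  setNames(rep(reward_levels, each = 2),
           paste0("s", rep(reward_levels, each = 2), ".", 1:2))
}

#' Run one speeded decision trial
#'
#' Pipeline: select boost for the condition (the difficulty class `|dv|`,
#' visible at cue onset) -> compute LC/VTA -> `dv` from the pretrained option
#' values -> drift and boundary -> diffusion run -> devalued reward for the
#' chosen option (0 on timeout) -> Kalman updates in both value stores.
#'
#' @param agent An [rml_agent()] with pretrained stimulus values.
#' @param trial One row of [generate_speeded_trials()].
#' @param config Full speeded [rml_config()].
#' @return A one-row data.frame trial record.
#' @export
run_speeded_trial <- function(agent, trial, config) {
  acfg <- config$agent; dcfg <- config$ddm
  state <- paste0("d", abs(trial$value_difference))
  register_state(agent, state)
  sel <- select_boost(agent, state)
  nm <- compute_neuromodulation(sel$level, acfg)
  dv <- compute_dv(agent, trial$left_stim, trial$right_stim)
  drift <- drift_from_dv(dv, dcfg)
  boundary <- boundary_from_lc(nm$lc, dcfg, lc_min = acfg$lc_min)
  out <- run_ddm(drift, boundary, 0, dcfg, n = 1L)
  chosen <- if (out$choice == 1L) "left" else if (out$choice == -1L) "right" else "none"
  reward <- if (chosen == "none") 0 else {
    offered <- if (chosen == "left") trial$left_reward else trial$right_reward
    reward_devaluation(offered, out$rt_cycles, config$ddm$max_cycles)
  }
  cost <- boost_cost(sel$level, acfg$cost_rate)
  net <- reward - cost
  value_prior <- update_boost_q(agent, state, sel$index, net, vta = nm$vta)
  if (chosen != "none") {
    stim <- if (chosen == "left") trial$left_stim else trial$right_stim
    update_act_value(agent, stim, reward, vta = nm$vta)
  }
  correct <- if (chosen == "none" || trial$value_difference == 0L) NA else
    (trial$value_difference > 0L) == (chosen == "left")
  data.frame(
    type_id = trial$type_id, left_reward = trial$left_reward,
    right_reward = trial$right_reward, value_difference = trial$value_difference,
    condition = state, boost = sel$level, lc = nm$lc, dv = dv,
    value = value_prior, surprise = abs(net - value_prior),
    total_reward = trial$left_reward + trial$right_reward,
    choice = chosen, rt_cycles = out$rt_cycles, timed_out = out$timed_out,
    correct = correct, reward = reward, net_value = net,
    stringsAsFactors = FALSE
  )
}

#' Simulate one speeded-task participant
#'
#' Seeds the RNG, pretrains the stimulus values, runs the full shuffled
#' session and returns the trial-record stream.
#'
#' @param config Full speeded [rml_config()].
#' @param participant Participant index (1-based); the RNG seed is
#'   `config$base_seed + participant`.
#' @param reps_per_type Overrides `config$task$reps_per_type` when given.
#' @return A data.frame of trial records with `participant` and `seed`
#'   columns.
#' @export
simulate_speeded_participant <- function(config = rml_config("speeded"),
                                         participant = 1L,
                                         reps_per_type = NULL) {
  seed <- config$base_seed + participant
  set.seed(seed)
  reps <- if (is.null(reps_per_type)) config$task$reps_per_type else reps_per_type
  agent <- rml_agent(config)
  pretrain_values(agent, speeded_stimuli(config$task$reward_levels),
                  reps = config$task$pretrain_reps)
  trials <- generate_speeded_trials(reps, config$task$reward_levels)
  records <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i)
    run_speeded_trial(agent, trials[i, ], config)))
  records$trial <- seq_len(nrow(records))
  records$participant <- participant
  records$seed <- seed
  records$task <- "speeded"
  records
}
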
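#' Build the foraging environment
#'
#' Sixteen contexts (reward patches), each holding eight two-armed bandits.
#' The optimal-arm reward of bandit `j` in context `c` is
#' `context_means[c] + context_spreads[c] * u[j]` with `u` an even grid on
#' \[-1, 1\]; the suboptimal arm sits `arm_margin` below the optimal arm.
#' Context means are distinct and span low- to high-value patches; patch
#' richness also widens the spread of bandit qualities, so richer patches mix
#' excellent and mediocre games while poor patches are uniformly meagre.
#'
#' @param config The `task` section of a foraging [rml_config()].
#' @return A list with the optimal-arm value matrix `values`
#'   (contexts x bandits), `arm_margin`, `reward_sd`, `forage_cost`,
#'   `max_forages`.
#' @export
foraging_env <- function(config = rml_config("foraging")$task) {
  nb <- config$n_bandits
  # stratified-uniform bandit placement within each patch's quality range:
  # smooth in expectation across participants, one draw per environment
  u <- t(replicate(config$n_contexts, sort(2 * ((seq_len(nb) - runif(nb)) / nb) - 1)))
  values <- outer(config$context_means, rep(1, nb)) + config$context_spreads * u
  dimnames(values) <- list(paste0("c", seq_len(config$n_contexts)),
                           paste0("b", seq_len(config$n_bandits)))
  list(values = values, n_contexts = config$n_contexts,
       n_bandits = config$n_bandits, arm_margin = config$arm_margin,
       reward_sd = config$reward_sd, forage_cost = config$forage_cost,
       max_forages = config$max_forages)
}

#' Generate a foraging session
#'
#' Each block contains every initial compound cue (context, bandit) exactly
#' twice, shuffled; the default 18 blocks give 4608 initial trials.
#'
#' @param env A [foraging_env()].
#' @param blocks Number of blocks.
#' @return A data.frame with `block`, `context`, `bandit`.
#' @export
generate_foraging_session <- function(env, blocks = 18L) {
  cues <- expand.grid(context = seq_len(env$n_contexts),
                      bandit = seq_len(env$n_bandits), KEEP.OUT.ATTRS = FALSE)
  one_block <- function(b) {
    blk <- cues[rep(seq_len(nrow(cues)), 2L), ]
    blk <- blk[sample.int(nrow(blk)), ]
    blk$block <- b
    blk
  }
  session <- do.call(rbind, lapply(seq_len(blocks), one_block))
  rownames(session) <- NULL
  session[, c("block", "context", "bandit")]
}

#' One foraging state transition
#'
#' "engage" moves to the bandit stage of the cued bandit; "forage" moves
#' through the waiting state (one forage cost) back to the initial state with
#' a different bandit drawn uniformly from the same context. Twenty
#' consecutive forage decisions terminate the trial.
#'
#' @param state List with `context`, `bandit`, `n_forages`.
#' @param action `"engage"` or `"forage"`.
#' @param env A [foraging_env()].
#' @return The next state; `stage` becomes `"bandit"` on engage, stays
#'   `"initial"` on forage, or `"ended"` when the forage limit is reached.
#' @export
foraging_step <- function(state, action, env) {
  if (!action %in% c("engage", "forage")) stop("illegal action: ", action)
  if (identical(state$stage, "bandit")) stop("illegal action in bandit stage")
  if (action == "engage") {
    state$stage <- "bandit"
    return(state)
  }
  state$n_forages <- state$n_forages + 1L
  if (state$n_forages >= env$max_forages) {
    state$stage <- "ended"
    return(state)
  }
  others <- setdiff(seq_len(env$n_bandits), state$bandit)
  state$bandit <- others[sample.int(length(others), 1L)]
  state$stage <- "initial"
  state
}

bandit_label <- function(context, bandit) paste0("c", context, ".b", bandit)
arm_label <- function(context, bandit, arm) paste0(bandit_label(context, bandit), ".a", arm)
forage_label <- function(context) paste0("c", context, ".forage")

#' Pretrain bandit and arm values for the foraging task
#'
#' The agent plays every bandit in every context `reps` times: arm selection
#' by softmax over the learned arm values, noisy reward from the chosen arm,
#' Kalman updates of both the arm value and the bandit-level engage value.
#' Forage-value estimates start at the learned patch mean minus the forage
#' cost (with full initial uncertainty) and are refined during the task from
#' realised foraging returns.
#'
#' @param agent An [rml_agent()].
#' @param env A [foraging_env()].
#' @param reps Plays per bandit.
#' @param config Full foraging [rml_config()].
#' @return The agent, invisibly.
#' @export
pretrain_foraging <- function(agent, env, reps = 25L, config = rml_config("foraging")) {
  acfg <- config$agent
  for (cx in seq_len(env$n_contexts))
    for (bd in seq_len(env$n_bandits))
      register_option(agent, c(bandit_label(cx, bd), arm_label(cx, bd, 1:2)))
  plays <- expand.grid(context = seq_len(env$n_contexts),
                       bandit = seq_len(env$n_bandits), rep = seq_len(reps))
  plays <- plays[sample.int(nrow(plays)), ]
  for (i in seq_len(nrow(plays))) {
    cx <- plays$context[i]; bd <- plays$bandit[i]
    r <- play_bandit(agent, env, cx, bd, acfg)
    update_act_value(agent, bandit_label(cx, bd), r)
  }
  # forage value prior: learned patch mean minus one forage cost
  for (cx in seq_len(env$n_contexts)) {
    fl <- forage_label(cx)
    register_option(agent, fl)
    agent$act_mean[fl] <- mean(agent$act_mean[bandit_label(cx, seq_len(env$n_bandits))]) -
      env$forage_cost
    agent$act_unc[fl] <- acfg$act_init_uncertainty
  }
  invisible(agent)
}

play_bandit <- function(agent, env, context, bandit, acfg) {
  arms <- arm_label(context, bandit, 1:2)
  p <- softmax_probs(agent$act_mean[arms], acfg$action_temperature)
  arm <- sample.int(2L, 1L, prob = p)
  mu <- env$values[context, bandit] - if (arm == 2L) env$arm_margin else 0
  r <- mu + rnorm(1, 0, env$reward_sd)
  update_act_value(agent, arms[arm], r)
  r
}

difficulty_class <- function(absdv, breaks) {
  paste0("dc", findInterval(absdv, breaks, rightmost.closed = FALSE))
}

#' Run one foraging trial
#'
#' The boost condition is the onset difficulty class: the binned absolute
#' difference between the learned engage value of the cued bandit and the
#' learned forage value of the patch. Each engage/forage decision is a
#' diffusion run whose start point is biased towards "engage", with the bias
#' discounted (and the boundary shrunk) by LC. Timeouts abort the trial with
#' no reward; foraging redraws a different bandit from the patch until the
#' consecutive-forage limit.
#'
#' @param agent Pretrained [rml_agent()].
#' @param env A [foraging_env()].
#' @param cue One row of [generate_foraging_session()].
#' @param config Full foraging [rml_config()].
#' @return A one-row data.frame trial record.
#' @export
run_foraging_trial <- function(agent, env, cue, config) {
  acfg <- config$agent; dcfg <- config$ddm
  cx <- cue$context
  fl <- forage_label(cx)
  v_engage0 <- unname(agent$act_mean[bandit_label(cx, cue$bandit)])
  v_forage0 <- unname(agent$act_mean[fl])
  dv0 <- v_engage0 - v_forage0
  state_id <- difficulty_class(abs(dv0), config$analysis$difficulty_breaks)
  register_state(agent, state_id)
  sel <- select_boost(agent, state_id)
  nm <- compute_neuromodulation(sel$level, acfg)
  boundary <- boundary_from_lc(nm$lc, dcfg, lc_min = acfg$lc_min)
  bias <- bias_from_lc(nm$lc, dcfg, boundary = boundary, lc_min = acfg$lc_min)

  st <- list(context = cx, bandit = cue$bandit, n_forages = 0L, stage = "initial")
  rt_total <- 0L; reward <- 0; outcome <- "aborted"; timed_out <- FALSE
  repeat {
    dv <- unname(agent$act_mean[bandit_label(cx, st$bandit)]) - unname(agent$act_mean[fl])
    out <- run_ddm(drift_from_dv(dv, dcfg), boundary, bias, dcfg, n = 1L)
    rt_total <- rt_total + out$rt_cycles
    if (out$timed_out) { timed_out <- TRUE; outcome <- "aborted"; break }
    action <- if (out$choice == 1L) "engage" else "forage"
    st <- foraging_step(st, action, env)
    if (st$stage == "bandit") {
      reward <- play_bandit(agent, env, cx, st$bandit, acfg)
      update_act_value(agent, bandit_label(cx, st$bandit), reward, vta = nm$vta)
      outcome <- "engaged"
      break
    }
    if (st$stage == "ended") { outcome <- "forage_limit"; break }
  }
  forage_spend <- env$forage_cost * st$n_forages
  cost <- boost_cost(sel$level, acfg$cost_rate)
  net <- reward - forage_spend - cost
  value_prior <- update_boost_q(agent, state_id, sel$index, net, vta = nm$vta)
  if (st$n_forages > 0L && outcome == "engaged")
    update_act_value(agent, fl, reward - forage_spend, vta = nm$vta)
  data.frame(
    block = cue$block, context = cx, bandit = cue$bandit,
    condition = state_id, boost = sel$level, lc = nm$lc,
    v_engage = v_engage0, forage_value = v_forage0, dv = dv0,
    difficulty = -abs(dv0), value = (v_engage0 + v_forage0) / 2,
    state_value = value_prior,
    surprise = abs(net - value_prior), choice = outcome,
    n_forages = st$n_forages, rt_cycles = rt_total, timed_out = timed_out,
    reward = reward, net_value = net, stringsAsFactors = FALSE
  )
}

#' Simulate one foraging participant
#'
#' Seeds the RNG, builds the environment, pretrains bandit and arm values and
#' runs the blocked session.
#'
#' @param config Full foraging [rml_config()].
#' @param participant Participant index; seed is `config$base_seed +
#'   participant`.
#' @param blocks Overrides `config$task$blocks` when given.
#' @return A data.frame of trial records.
#' @export
simulate_foraging_participant <- function(config = rml_config("foraging"),
                                          participant = 1L, blocks = NULL) {
  seed <- config$base_seed + participant
  set.seed(seed)
  env <- foraging_env(config$task)
  agent <- rml_agent(config)
  pretrain_foraging(agent, env, reps = config$task$pretrain_reps, config = config)
  session <- generate_foraging_session(env, if (is.null(blocks)) config$task$blocks else blocks)
  records <- vector("list", nrow(session))
  for (i in seq_len(nrow(session)))
    records[[i]] <- run_foraging_trial(agent, env, session[i, ], config)
  records <- do.call(rbind, records)
  records$trial <- seq_len(nrow(records))
  records$participant <- participant
  records$seed <- seed
  records$task <- "foraging"
  records
}
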
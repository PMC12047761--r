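#' Generate working-memory trial specifications
#'
#' Each load level in `loads` appears `reps_per_load` times; the probe matches
#' one of the memorised words in half the trials (stratified within load, so
#' the per-load match fraction is exactly 0.5 for even reps). Word sets are
#' sampled from the lexicon without replacement.
#'
#' @param reps_per_load Trials per load level.
#' @param loads Load levels (words to retain).
#' @param n_units Lexicon size; must allow a non-match probe at every load.
#' @return A data.frame with `load`, `is_match`, `target_id` and a list column
#'   `word_ids`.
#' @export
generate_wm_trials <- function(reps_per_load = 90L, loads = c(1L, 4L, 6L, 8L),
                               n_units = 16L) {
  if (n_units <= max(loads)) stop("lexicon too small for non-match probes")
  one_load <- function(load) {
    n_match <- floor(reps_per_load / 2)
    is_match <- sample(rep(c(TRUE, FALSE), c(n_match, reps_per_load - n_match)))
    if (reps_per_load %% 2 == 1) is_match[reps_per_load] <- runif(1) < 0.5
    words <- replicate(reps_per_load, sample.int(n_units, load), simplify = FALSE)
    target <- mapply(function(w, m) {
      if (m) w[sample.int(length(w), 1L)] else sample(setdiff(seq_len(n_units), w), 1L)
    }, words, is_match)
    data.frame(load = load, is_match = is_match, target_id = target)[
      , c("load", "is_match", "target_id")] -> df
    df$word_ids <- words
    df
  }
  trials <- do.call(rbind, lapply(loads, one_load))
  trials <- trials[sample.int(nrow(trials)), ]
  rownames(trials) <- NULL
  trials
}

#' Encode a word set into the network
#'
#' The input (phonological) layer has one unit per word; presented words are
#' set to the encoding activation and copied into the output (articulatory)
#' layer, all other units stay at baseline.
#'
#' @param word_ids Indices of the presented words (distinct, in range).
#' @param config The `wm` section of an [rml_config()].
#' @return Network state: list with `input` and `output` activation vectors.
#' @export
encode_words <- function(word_ids, config) {
  if (anyDuplicated(word_ids)) stop("duplicate word ids")
  if (any(word_ids < 1L | word_ids > config$n_units)) stop("word id out of range")
  x <- rep(config$activation_min, config$n_units)
  x[word_ids] <- config$encode_value
  list(input = x, output = x)
}

#' Run the retention delay
#'
#' Iterates the competitive dynamics for `delay_steps`: each output unit is
#' driven by its own recurrent trace with gain
#' `gain_base + gain_lc_coeff * lc`, inhibited laterally by the summed
#' activity of the other units, perturbed by Gaussian noise and clipped to the
#' activation bounds. Lateral inhibition makes retention degrade with load
#' unless the LC-driven gain compensates.
#'
#' @param state Network state from [encode_words()].
#' @param lc LC output controlling the gain.
#' @param config The `wm` section of an [rml_config()].
#' @return The end-of-delay network state.
#' @export
run_retention <- function(state, lc, config) {
  g <- config$gain_base + config$gain_lc_coeff * lc
  y <- state$output
  for (t in seq_len(config$delay_steps)) {
    inh <- config$inhibition_weight * (sum(y) - y)
    y <- g * config$recurrent_weight * y - inh +
      rnorm(length(y), 0, config$noise_sd)
    y <- pmin(pmax(y, config$activation_min), config$activation_max)
    if (any(!is.finite(y))) stop("activation overflow in retention dynamics")
  }
  state$output <- y
  state
}

#' Probe decision
#'
#' Evidence is a linear readout of the output layer referenced to the probed
#' unit (`activation of the probe minus readout_off_weight times the mean of
#' the others`) plus decision noise; the response is "match" iff the evidence
#' exceeds the criterion. The decision is invariant under relabeling of the
#' non-probed units.
#'
#' @param state End-of-delay network state.
#' @param target_id Probed word.
#' @param config The `wm` section of an [rml_config()].
#' @return A list with `match` (logical) and `evidence`.
#' @export
probe_decision <- function(state, target_id, config) {
  y <- state$output
  evidence <- y[target_id] - config$readout_off_weight * mean(y[-target_id]) +
    rnorm(1, 0, config$decision_noise_sd)
  list(match = evidence > config$criterion, evidence = evidence)
}

#' Simulate one working-memory participant
#'
#' Per trial: the load cue is the boost condition; the selected boost sets the
#' LC output and hence the network gain during retention; the probe decision
#' is scored against ground truth and correct/incorrect feedback (reward 1/0)
#' trains the boost policy net of the boost cost.
#'
#' @param config Full wm [rml_config()].
#' @param participant Participant index; seed is `config$base_seed +
#'   participant`.
#' @param reps_per_load Overrides the config when given.
#' @return A data.frame of trial records.
#' @export
simulate_wm_participant <- function(config = rml_config("wm"), participant = 1L,
                                    reps_per_load = NULL) {
  seed <- config$base_seed + participant
  set.seed(seed)
  acfg <- config$agent; wcfg <- config$wm
  reps <- if (is.null(reps_per_load)) config$task$reps_per_load else reps_per_load
  agent <- rml_agent(config)
  trials <- generate_wm_trials(reps, config$task$loads, wcfg$n_units)
  records <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    state_id <- paste0("load", tr$load)
    register_state(agent, state_id)
    register_option(agent, state_id)
    sel <- select_boost(agent, state_id)
    nm <- compute_neuromodulation(sel$level, acfg)
    net_state <- encode_words(tr$word_ids[[1]], wcfg)
    net_state <- run_retention(net_state, nm$lc, wcfg)
    dec <- probe_decision(net_state, tr$target_id, wcfg)
    correct <- dec$match == tr$is_match
    reward <- as.numeric(correct)
    cost <- boost_cost(sel$level, acfg$cost_rate)
    net <- reward - cost
    q_prior <- update_boost_q(agent, state_id, sel$index, net, vta = nm$vta)
    act_prior <- update_act_value(agent, state_id, reward, vta = nm$vta)
    records[[i]] <- data.frame(
      load = tr$load, condition = state_id, is_match = tr$is_match,
      boost = sel$level, lc = nm$lc,
      value = (q_prior + act_prior) / 2,
      surprise = abs(reward - act_prior),
      decision = dec$match, evidence = dec$evidence, correct = correct,
      reward = reward, net_value = net, stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, records)
  records$trial <- seq_len(nrow(records))
  records$participant <- participant
  records$seed <- seed
  records$task <- "wm"
  records
}
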
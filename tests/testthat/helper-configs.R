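# small configurations used across tests: fast deadlines, few trials
tiny_speeded_config <- function() {
  cfg <- rml_config("speeded")
  cfg$task$pretrain_reps <- 10L
  cfg
}

tiny_wm_config <- function() {
  rml_config("wm")
}

tiny_foraging_config <- function() {
  cfg <- rml_config("foraging")
  cfg$task$pretrain_reps <- 10L
  cfg
}

# independent scalar Kalman recursion, written directly from the filter
# equations (the oracle for the package's kalman_update)
kalman_oracle <- function(mean0, unc0, obs_noise, outcomes, process_noise = 0) {
  m <- mean0; u <- unc0
  for (y in outcomes) {
    k <- u / (u + obs_noise)
    m <- m + k * (y - m)
    u <- (1 - k) * u + process_noise
  }
  list(mean = m, uncertainty = u)
}
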
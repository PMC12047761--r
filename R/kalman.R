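#' Scalar Kalman value estimate
#'
#' A `value_estimate` tracks the expected net value of a state-action pair as
#' a Gaussian belief: a mean (reward units), an uncertainty (variance of the
#' belief, reward units squared) and an assumed observation noise (variance of
#' single outcomes around the true value). Learning by [kalman_update()] is
#' approximate Bayesian value tracking: the update gain adapts from fast
#' (uncertain belief) to slow (converged belief).
#'
#' @param mean Initial expected value (reward units).
#' @param uncertainty Initial estimation variance; must be non-negative.
#' @param observation_noise Assumed outcome variance; must be non-negative.
#' @return An object of class `value_estimate`.
#' @examples
#' v <- value_estimate(mean = 0, uncertainty = 25, observation_noise = 1)
#' v <- kalman_update(v, outcome = 7)
#' v$mean
#' @export
value_estimate <- function(mean = 0, uncertainty = 1, observation_noise = 1) {
  if (!is.finite(mean) || !is.finite(uncertainty) || !is.finite(observation_noise))
    stop("value_estimate fields must be finite")
  if (uncertainty < 0) stop("uncertainty must be non-negative")
  if (observation_noise < 0) stop("observation_noise must be non-negative")
  structure(list(mean = mean, uncertainty = uncertainty,
                 observation_noise = observation_noise),
            class = "value_estimate")
}

#' @export
print.value_estimate <- function(x, ...) {
  cat(sprintf("<value_estimate> mean = %.4f, uncertainty = %.4f, obs noise = %.4f\n",
              x$mean, x$uncertainty, x$observation_noise))
  invisible(x)
}

#' Kalman update of a value estimate
#'
#' Updates the belief with one observed outcome, optionally scaled by the VTA
#' signal (`vta = 1` leaves outcomes untouched). The gain is
#' `k = uncertainty / (uncertainty + observation_noise)`; the posterior mean is
#' `mean + k * (vta * outcome - mean)` and the posterior uncertainty
#' `(1 - k) * uncertainty + process_noise`. With `process_noise = 0`
#' (stationary default) uncertainty never increases and the estimate converges
#' at the sample-average rate; a positive process noise keeps the filter
#' adaptive for nonstationary outcomes.
#'
#' @param estimate A [value_estimate()].
#' @param outcome Observed outcome (finite scalar, reward units).
#' @param vta VTA reward-scaling signal; 1 means no scaling.
#' @param process_noise Additive drift variance re-injected after the update.
#' @return The updated `value_estimate` (the input is not modified).
#' @export
kalman_update <- function(estimate, outcome, vta = 1, process_noise = 0) {
  if (!inherits(estimate, "value_estimate")) stop("estimate must be a value_estimate")
  if (!is.finite(outcome)) stop("outcome must be finite")
  if (estimate$uncertainty < 0) stop("uncertainty must be non-negative")
  k <- if (estimate$uncertainty == 0 && estimate$observation_noise == 0) 1
       else estimate$uncertainty / (estimate$uncertainty + estimate$observation_noise)
  value_estimate(
    mean = estimate$mean + k * (vta * outcome - estimate$mean),
    uncertainty = (1 - k) * estimate$uncertainty + process_noise,
    observation_noise = estimate$observation_noise
  )
}

#' Surprise: absolute prediction error
#'
#' @param estimate_mean Expected outcome.
#' @param outcome Observed outcome.
#' @return `|outcome - estimate_mean|`.
#' @export
surprise <- function(estimate_mean, outcome) {
  if (!all(is.finite(estimate_mean)) || !all(is.finite(outcome)))
    stop("surprise requires finite inputs")
  abs(outcome - estimate_mean)
}

#' Trial-type surprise
#'
#' Absolute difference between the total reward available in a trial and the
#' long-term (session) mean of that total. Used as an analysis regressor for
#' reward-driven surprise at cue onset.
#'
#' @param trial_total_reward Sum of the rewards on offer in a trial.
#' @param long_term_mean_reward Session mean of `trial_total_reward`.
#' @return Non-negative scalar (vectorised).
#' @export
trial_type_surprise <- function(trial_total_reward, long_term_mean_reward) {
  surprise(long_term_mean_reward, trial_total_reward)
}
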
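#' Drift rate from a value difference
#'
#' The absolute value of `dv` sets the drift magnitude, its sign the drift
#' direction (towards the boundary of the favoured option):
#' `drift = drift_scale * dv`.
#'
#' @param dv Signed expected-value difference (reward units).
#' @param config The `ddm` section of an [rml_config()].
#' @return Signed drift (evidence units per cycle).
#' @export
drift_from_dv <- function(dv, config) {
  if (!all(is.finite(dv))) stop("dv must be finite")
  config$drift_scale * dv
}

#' Decision boundary from the LC signal
#'
#' Higher LC activity tightens the boundaries and speeds the decision. The
#' half-separation decays exponentially from `base_boundary` (at the minimum
#' LC level) towards `boundary_floor`:
#' `a(lc) = floor + (base - floor) * exp(-shrink * (lc - lc_min))`,
#' which is strictly positive, strictly decreasing in LC and bounded below by
#' the floor.
#'
#' @param lc LC output (dimensionless gain).
#' @param config The `ddm` section of an [rml_config()]; `lc_min` is read from
#'   the companion `agent` section when a full config is supplied, else 0.
#' @param lc_min Minimum of the LC range (anchor where the boundary equals
#'   `base_boundary`).
#' @return Boundary half-separation (evidence units).
#' @export
boundary_from_lc <- function(lc, config, lc_min = 0) {
  a <- config$boundary_floor +
    (config$base_boundary - config$boundary_floor) * exp(-config$boundary_shrink * (lc - lc_min))
  if (any(a <= 0)) stop("configuration yields a non-positive boundary")
  a
}

#' Starting-point bias from the LC signal
#'
#' In the foraging task the start point is biased towards the "engage"
#' boundary by `bias0`; LC output discounts the bias monotonically towards 0:
#' `bias(lc) = bias0 * exp(-bias_discount * (lc - lc_min))`. The speeded task
#' uses `bias0 = 0`, so the bias is 0 for all trials. If the composed bias
#' magnitude reaches the boundary it is clipped just inside it, with a
#' warning.
#'
#' @inheritParams boundary_from_lc
#' @param boundary Boundary half-separation the bias must stay inside.
#' @return Starting point (evidence units).
#' @export
bias_from_lc <- function(lc, config, boundary = NULL, lc_min = 0) {
  b <- config$bias0 * exp(-config$bias_discount * (lc - lc_min))
  if (!is.null(boundary) && any(abs(b) >= boundary)) {
    warning("starting-point bias clipped inside the boundary")
    b <- sign(b) * pmin(abs(b), 0.99 * boundary)
  }
  b
}

#' Simulate first-passage outcomes of the diffusion module
#'
#' Discrete-time Euler random walk with unit time step ("DDM cycle"):
#' `x_0 = bias`, `x_{t+1} = x_t + drift + noise_sd * xi_t`, absorbed at
#' `+/- boundary`. Returns the first-passage choice and reaction time, or a
#' timeout at `max_cycles` (choice `0`, i.e. none).
#'
#' @param drift,boundary,bias Scalars or length-`n` vectors (recycled).
#' @param config The `ddm` section of an [rml_config()] (`noise_sd`,
#'   `max_cycles`).
#' @param n Number of independent runs.
#' @return A data.frame with columns `choice` (+1 upper, -1 lower, 0 none),
#'   `rt_cycles` and `timed_out`. The invariant `timed_out <=> choice == 0
#'   <=> rt_cycles == max_cycles` holds row-wise.
#' @export
run_ddm <- function(drift, boundary, bias = 0, config, n = max(length(drift), length(boundary), length(bias))) {
  out <- ddm_kernel(rep_len(as.numeric(drift), n), rep_len(as.numeric(boundary), n),
                    rep_len(as.numeric(bias), n), config$noise_sd,
                    as.integer(config$max_cycles))
  as.data.frame(out)
}
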
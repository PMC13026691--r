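#' Vital-sign channels
#'
#' The five channels modelled by the trajectory pipeline: temperature (degC),
#' heart rate (bpm), respiratory rate (breaths/min), systolic and diastolic
#' blood pressure (mmHg). Blood pressure is split into SBP and DBP so that
#' exactly five polynomial trajectory functions exist per subphenotype.
#'
#' @return Character vector of the five channel codes.
#' @export
vs_channels <- function() c("TEMP", "HR", "RR", "SBP", "DBP")

# Physiologic plausibility bounds per channel; rows outside these are rejected
# at ingest, and synthetic templates must keep their mean inside them on [0,24] h.
.vs_bounds <- list(
  TEMP = c(30, 43),
  HR   = c(20, 220),
  RR   = c(4, 60),
  SBP  = c(40, 260),
  DBP  = c(20, 160)
)

#' Physiologic bounds for a channel
#'
#' @param channel One of [vs_channels()].
#' @return Numeric `c(lower, upper)` in the channel's units.
#' @export
vs_bounds <- function(channel) {
  channel <- match.arg(channel, vs_channels())
  .vs_bounds[[channel]]
}

#' Evaluate a polynomial mean trajectory
#'
#' The group mean at time `t` is `beta0 + beta1 * t` (order 1) or
#' `beta0 + beta1 * t + beta2 * t^2` (order 2), with `t` in hours since
#' emergency-department admission.
#'
#' @param beta Numeric coefficient vector of length 2 or 3
#'   (intercept, slope, optional curvature).
#' @param t Numeric vector of times in hours.
#' @return Numeric vector of trajectory means, same length as `t`.
#' @export
group_mean <- function(beta, t) {
  stopifnot(is.numeric(beta), length(beta) %in% c(2L, 3L))
  out <- beta[1] + beta[2] * t
  if (length(beta) == 3L) out <- out + beta[3] * t^2
  out
}
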
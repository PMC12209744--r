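# Event-driven sample-size machinery for a two-arm log-rank TTCW design:
# Schoenfeld required events, incidence-based per-arm sample size, and
# multiplicative censoring inflation.

#' Required events by the Schoenfeld formula
#'
#' `ceil[(z_{1-alpha/2} + z_power)^2 / (p (1 - p) (ln hr)^2)]` with `p` the
#' allocation fraction. Symmetric in `hr` versus `1/hr`.
#'
#' @param hr hypothesized hazard ratio (not 1).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param allocation fraction allocated to arm 1.
#' @return Integer event count.
#' @examples
#' schoenfeld_events(hr = 2, alpha = 0.05, power = 0.8) # 66
#' @export
schoenfeld_events <- function(hr = 2, alpha = 0.05, power = 0.8,
                              allocation = 0.5) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            allocation > 0, allocation < 1, hr > 0)
  if (hr == 1) {
    stop(errorCondition("hr = 1 requires infinitely many events",
                        class = c("ifnttcw_design_error", "ifnttcw_error")))
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling(z^2 / (allocation * (1 - allocation) * log(hr)^2)))
}

#' Per-arm sample size from required events
#'
#' Total n = events / (p1 * P1 + p2 * P2) with arm event probabilities P1,
#' P2 over follow-up; by default P2 is derived from P1 through the
#' proportional-hazards transform `P2 = 1 - (1 - P1)^hr`. Each arm is
#' rounded up.
#'
#' @param events required event count.
#' @param p1_event cumulative event probability in arm 1 (reference).
#' @param hr hazard ratio used to derive arm 2's probability when
#'   `p2_event` is not given.
#' @param p2_event optional explicit arm-2 event probability.
#' @param allocation fraction in arm 1.
#' @return list: `n_per_arm` (arm1, arm2), `n_total`, `p2_event`.
#' @examples
#' sample_size_from_events(42, p1_event = 0.40, hr = 2) # 41 per arm
#' @export
sample_size_from_events <- function(events, p1_event, hr = 2,
                                    p2_event = NULL, allocation = 0.5) {
  if (is.null(p2_event)) p2_event <- 1 - (1 - p1_event)^hr
  if (p1_event <= 0 || p2_event <= 0) {
    stop(errorCondition("zero event probability makes the design infeasible",
                        class = c("ifnttcw_design_error", "ifnttcw_error")))
  }
  stopifnot(p1_event <= 1, p2_event <= 1)
  n_total <- events / (allocation * p1_event + (1 - allocation) * p2_event)
  n1 <- as.integer(ceiling(allocation * n_total))
  n2 <- as.integer(ceiling((1 - allocation) * n_total))
  list(n_per_arm = c(arm1 = n1, arm2 = n2), n_total = n1 + n2,
       p2_event = p2_event)
}

#' Inflate a sample size for anticipated censoring
#'
#' Multiplicative inflation `ceil(n * (1 + allowance))`; maps 112 patients at
#' a 25% allowance to 140.
#'
#' @param total_n sample size before inflation.
#' @param allowance anticipated censoring fraction in \[0, 1).
#' @return Integer inflated sample size.
#' @export
censoring_inflation <- function(total_n, allowance) {
  stopifnot(allowance >= 0, allowance < 1, total_n > 0)
  # guard the ceiling against floating-point excess (100 * 1.1 > 110)
  as.integer(ceiling(total_n * (1 + allowance) - 1e-9))
}

#' Full event-driven design summary
#'
#' @param hr,alpha,power,allocation as in [schoenfeld_events()].
#' @param control_event_prob cumulative event probability in the reference
#'   arm over follow-up (default 0.40 over 5 years).
#' @param censoring_allowance anticipated censoring fraction (default 0.25).
#' @return list: `events`, `n_per_arm`, `n_total`, `n_inflated`.
#' @export
power_design <- function(hr = 2, alpha = 0.05, power = 0.8,
                         allocation = 0.5, control_event_prob = 0.40,
                         censoring_allowance = 0.25) {
  ev <- schoenfeld_events(hr, alpha, power, allocation)
  ss <- sample_size_from_events(ev, control_event_prob, hr,
                                allocation = allocation)
  list(events = ev, n_per_arm = ss$n_per_arm, n_total = ss$n_total,
       n_inflated = censoring_inflation(ss$n_total, censoring_allowance))
}
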
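# Kaplan-Meier estimation with Greenwood variance, fixed-time survival
# contrasts, restricted mean TTCW comparison, and the log-rank test.
# Product-limit estimation goes through survival::survfit; the RMST point
# estimate and plug-in variance are computed here from the curve.

.surv_object <- function(outcomes) {
  stopifnot(all(c("ttcw_months", "censored") %in% names(outcomes)))
  if (all(outcomes$ttcw_months <= 0)) {
    stop(errorCondition("all follow-up times are <= 0",
                        class = c("ifnttcw_contract_error", "ifnttcw_error")))
  }
  survival::Surv(outcomes$ttcw_months, !outcomes$censored)
}

#' Kaplan-Meier estimate with Greenwood variance
#'
#' Product-limit estimate of event-free survival; censorings tied with an
#' event time are counted as at risk for that event (standard convention).
#' The per-step variance is the Greenwood plug-in
#' `S(t)^2 * sum(d / (n * (n - d)))`.
#'
#' @param outcomes outcome table (`ttcw_months`, `censored`).
#' @return Object of class `km_curve`: data.frame `steps` (time, n_risk,
#'   n_event, n_censor, surv, se, var) over all observed times, plus `n`,
#'   `n_events`, `max_time`.
#' @export
km_estimate <- function(outcomes) {
  s <- .surv_object(outcomes)
  fit <- survival::survfit(s ~ 1, conf.type = "plain")
  sm <- summary(fit, censored = TRUE)
  steps <- data.frame(time = sm$time, n_risk = sm$n.risk,
                      n_event = sm$n.event, n_censor = sm$n.censor,
                      surv = sm$surv, se = sm$std.err)
  steps$var <- steps$se^2
  structure(list(steps = steps, n = nrow(outcomes),
                 n_events = sum(!outcomes$censored),
                 max_time = max(outcomes$ttcw_months)),
            class = "km_curve")
}

#' Survival probability of a KM curve at time t
#'
#' @param curve a `km_curve`.
#' @param t months (vectorized).
#' @return S(t) by right-continuous step lookup; 1 before the first time.
#' @export
km_surv_at <- function(curve, t) {
  vapply(t, function(tt) {
    idx <- which(curve$steps$time <= tt)
    if (length(idx) == 0L) 1 else curve$steps$surv[max(idx)]
  }, numeric(1))
}

#' Greenwood variance of a KM curve at time t
#'
#' @param curve a `km_curve`.
#' @param t months (vectorized).
#' @return Greenwood variance of S(t); 0 before the first event.
#' @export
km_var_at <- function(curve, t) {
  vapply(t, function(tt) {
    idx <- which(curve$steps$time <= tt)
    if (length(idx) == 0L) 0 else curve$steps$var[max(idx)]
  }, numeric(1))
}

#' Fixed-time contrast of two KM curves
#'
#' Compares S_A(t) and S_B(t) with a normal approximation using Greenwood
#' variances, either on the survival scale (default, the difference in KM
#' estimates) or after a complementary log-log transform.
#'
#' @param curve_a,curve_b `km_curve` objects.
#' @param t months; must not exceed either curve's maximum observed time.
#' @param transform `"identity"` or `"cloglog"`.
#' @return list with `surv_a`, `surv_b`, `difference` (A - B), `z`, `p_value`.
#' @export
fixed_time_contrast <- function(curve_a, curve_b, t,
                                transform = c("identity", "cloglog")) {
  transform <- match.arg(transform)
  if (t > min(curve_a$max_time, curve_b$max_time)) {
    stop(errorCondition("t is beyond the support of one of the curves",
                        class = c("ifnttcw_contract_error", "ifnttcw_error")))
  }
  sa <- km_surv_at(curve_a, t); sb <- km_surv_at(curve_b, t)
  va <- km_var_at(curve_a, t); vb <- km_var_at(curve_b, t)
  if (transform == "cloglog") {
    # var(log(-log S)) = var(S) / (S log S)^2 by the delta method
    ga <- log(-log(sa)); gb <- log(-log(sb))
    va <- va / (sa * log(sa))^2
    vb <- vb / (sb * log(sb))^2
    diff <- ga - gb
  } else {
    diff <- sa - sb
  }
  se <- sqrt(va + vb)
  z <- if (se == 0) 0 else diff / se
  p <- if (se == 0 && diff == 0) 1 else 2 * stats::pnorm(-abs(z))
  list(t = t, surv_a = sa, surv_b = sb, difference = sa - sb,
       transform = transform, z = z, p_value = p)
}

#' Restricted mean survival time from a KM curve
#'
#' Area under the survival step function on \[0, tau\], with the plug-in
#' variance `sum(A_i^2 * d_i / (n_i * (n_i - d_i)))` over event times
#' `t_i <= tau`, where `A_i` is the area under the curve from `t_i` to tau.
#'
#' @param curve a `km_curve`.
#' @param tau truncation time, months (must be positive and not beyond the
#'   curve's maximum observed time).
#' @return list with `tau`, `rmst`, `var`, `se`.
#' @export
rmst <- function(curve, tau) {
  if (tau <= 0) {
    stop(errorCondition("tau must be positive",
                        class = c("ifnttcw_contract_error", "ifnttcw_error")))
  }
  ev <- curve$steps[curve$steps$n_event > 0 & curve$steps$time <= tau, ,
                    drop = FALSE]
  knots <- c(0, ev$time, tau)
  sv <- c(1, ev$surv) # S on [knot_i, knot_{i+1})
  area <- sum(sv * diff(knots))
  # area to the right of each event time
  if (nrow(ev) > 0L) {
    tail_area <- rev(cumsum(rev(sv[-1] * diff(knots)[-1])))
    v <- sum(tail_area^2 * ev$n_event /
               (ev$n_risk * (ev$n_risk - ev$n_event)))
  } else {
    v <- 0
  }
  list(tau = tau, rmst = area, var = v, se = sqrt(v))
}

#' Compare restricted mean survival times of two groups
#'
#' tau is the smaller of the two groups' maximum observed times (unless
#' given). Groups are treated as independent; the difference is tested with
#' a normal approximation on the plug-in variances.
#'
#' @param outcomes_a,outcomes_b outcome tables for the two groups.
#' @param tau optional truncation time, months.
#' @return list of class `rmst_result`: `tau`, per-group `rmst`, `se`,
#'   95% CIs, `difference` (A - B) with `ci_95` and `p_value`.
#' @export
rmst_compare <- function(outcomes_a, outcomes_b, tau = NULL) {
  ca <- km_estimate(outcomes_a)
  cb <- km_estimate(outcomes_b)
  if (is.null(tau)) tau <- min(ca$max_time, cb$max_time)
  if (tau <= 0) {
    stop(errorCondition("tau must be positive",
                        class = c("ifnttcw_contract_error", "ifnttcw_error")))
  }
  ra <- rmst(ca, tau); rb <- rmst(cb, tau)
  diff <- ra$rmst - rb$rmst
  se <- sqrt(ra$var + rb$var)
  z <- if (se == 0) 0 else diff / se
  p <- if (se == 0 && diff == 0) 1 else 2 * stats::pnorm(-abs(z))
  zc <- stats::qnorm(0.975)
  structure(list(tau = tau,
                 rmst_a = ra$rmst, se_a = ra$se,
                 ci_a = ra$rmst + c(-1, 1) * zc * ra$se,
                 rmst_b = rb$rmst, se_b = rb$se,
                 ci_b = rb$rmst + c(-1, 1) * zc * rb$se,
                 difference = diff, se = se,
                 ci_95 = diff + c(-1, 1) * zc * se,
                 z = z, p_value = p),
            class = "rmst_result")
}

#' @export
print.rmst_result <- function(x, ...) {
  cat(sprintf("Restricted mean TTCW (tau = %.1f months)\n", x$tau))
  cat(sprintf("  group A: %.1f (95%% CI %.1f-%.1f)\n",
              x$rmst_a, x$ci_a[1], x$ci_a[2]))
  cat(sprintf("  group B: %.1f (95%% CI %.1f-%.1f)\n",
              x$rmst_b, x$ci_b[1], x$ci_b[2]))
  cat(sprintf("  difference %.1f (95%% CI %.1f to %.1f), p = %.3g\n",
              x$difference, x$ci_95[1], x$ci_95[2], x$p_value))
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param outcomes_a,outcomes_b outcome tables.
#' @return list with `chisq`, `df` (1) and `p_value`.
#' @export
log_rank <- function(outcomes_a, outcomes_b) {
  df <- rbind(
    data.frame(time = outcomes_a$ttcw_months,
               status = as.integer(!outcomes_a$censored), group = "A"),
    data.frame(time = outcomes_b$ttcw_months,
               status = as.integer(!outcomes_b$censored), group = "B"))
  if (sum(df$status) == 0L) {
    stop(errorCondition("log-rank statistic undefined with zero events",
                        class = c("ifnttcw_contract_error", "ifnttcw_error")))
  }
  sd <- survival::survdiff(survival::Surv(time, status) ~ group, data = df)
  list(chisq = unname(sd$chisq), df = 1L,
       p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Event probability (cumulative incidence) at time t
#'
#' `1 - S(t)`, the reporting scale used for timepoint comparisons.
#'
#' @param curve a `km_curve`.
#' @param t months (vectorized).
#' @return Numeric in \[0, 1\].
#' @export
event_prob_at <- function(curve, t) 1 - km_surv_at(curve, t)
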
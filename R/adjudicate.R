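# MINIMISE composite "Morbi-mortality" endpoint adjudication: scan each
# subject's longitudinal record for the first qualifying event and emit the
# time to clinical worsening (TTCW) or a censoring time.

#' Adjudication rule constants
#'
#' Thresholds of the composite Morbi-mortality endpoint. ILD progression:
#' absolute FVC%-predicted drop of >= `fvc_abs_drop_major` points within
#' `window_months`, or a drop inside `fvc_abs_drop_minor_range` accompanied
#' by a relative DLco decline of >= `dlco_rel_drop` between the same visits.
#' Skin worsening: mRSS increase of >= `mrss_abs_increase` units and
#' >= `mrss_rel_increase` of baseline. Cardiac: ejection fraction below
#' `ef_threshold`, impairing pericardial effusion, treated arrhythmia, or a
#' cardiac device. GI: enteral nutrition >= `enteral_weeks` weeks, any
#' parenteral feeding, or admission for (pseudo-)obstruction.
#'
#' @param fvc_abs_drop_major percent-predicted points (default 10).
#' @param fvc_abs_drop_minor_range two points, default `c(5, 9)`.
#' @param dlco_rel_drop relative decline, default 0.15.
#' @param window_months rolling window for the FVC rule, default 12.
#' @param mrss_abs_increase units, default 5.
#' @param mrss_rel_increase fraction of baseline, default 0.25.
#' @param ef_threshold percent, default 45 (informational; the visit flag
#'   already encodes the threshold crossing).
#' @param enteral_weeks weeks, default 3 (informational, as above).
#' @param horizon_months administrative horizon, default 120.
#' @return A classed list of rule constants.
#' @export
adjudication_rules <- function(fvc_abs_drop_major = 10,
                               fvc_abs_drop_minor_range = c(5, 9),
                               dlco_rel_drop = 0.15,
                               window_months = 12,
                               mrss_abs_increase = 5,
                               mrss_rel_increase = 0.25,
                               ef_threshold = 45,
                               enteral_weeks = 3,
                               horizon_months = 120) {
  stopifnot(fvc_abs_drop_major > 0, dlco_rel_drop > 0, window_months > 0,
            mrss_abs_increase > 0, mrss_rel_increase > 0,
            length(fvc_abs_drop_minor_range) == 2L,
            fvc_abs_drop_minor_range[2] < fvc_abs_drop_major)
  structure(list(fvc_abs_drop_major = fvc_abs_drop_major,
                 fvc_abs_drop_minor_range = fvc_abs_drop_minor_range,
                 dlco_rel_drop = dlco_rel_drop,
                 window_months = window_months,
                 mrss_abs_increase = mrss_abs_increase,
                 mrss_rel_increase = mrss_rel_increase,
                 ef_threshold = ef_threshold,
                 enteral_weeks = enteral_weeks,
                 horizon_months = horizon_months),
            class = "adjudication_rules")
}

.severity_order <- c("ssc_death", "pah", "ild_progression", "cardiac",
                     "renal_crisis", "gi", "digital_vasculopathy",
                     "skin_worsening")

.check_sorted <- function(visits) {
  if (is.unsorted(visits$t, strictly = FALSE)) {
    stop(errorCondition("visits must be sorted by time",
                        class = c("ifnttcw_contract_error", "ifnttcw_error")))
  }
}

#' Detect ILD progression from FVC/DLco trajectories
#'
#' Scans all ordered visit pairs no more than `window_months` apart with both
#' FVC values present. A pair qualifies if the absolute FVC%-predicted drop
#' is >= 10 points, or lies in \[5, 9\] points with a relative DLco decline
#' of >= 15% between the same visits. Returns the earliest qualifying later
#' visit time.
#'
#' @param visits one subject's time-sorted visit data.frame.
#' @param rules an [adjudication_rules()] object.
#' @return Earliest qualifying time (months) or `NA` if none.
#' @export
detect_ild_progression <- function(visits, rules = adjudication_rules()) {
  .check_sorted(visits)
  idx <- which(!is.na(visits$fvc_pct))
  if (length(idx) < 2L) return(NA_real_)
  best <- NA_real_
  for (a in seq_along(idx)[-length(idx)]) {
    i <- idx[a]
    for (b in seq.int(a + 1L, length(idx))) {
      j <- idx[b]
      dt <- visits$t[j] - visits$t[i]
      if (dt > rules$window_months) break
      drop <- visits$fvc_pct[i] - visits$fvc_pct[j]
      hit <- FALSE
      if (drop >= rules$fvc_abs_drop_major) {
        hit <- TRUE
      } else if (drop >= rules$fvc_abs_drop_minor_range[1] &&
                 drop <= rules$fvc_abs_drop_minor_range[2] &&
                 !is.na(visits$dlco_pct[i]) && !is.na(visits$dlco_pct[j])) {
        rel <- (visits$dlco_pct[i] - visits$dlco_pct[j]) / visits$dlco_pct[i]
        if (rel >= rules$dlco_rel_drop) hit <- TRUE
      }
      if (hit && (is.na(best) || visits$t[j] < best)) best <- visits$t[j]
    }
  }
  best
}

#' Detect qualifying skin worsening from mRSS
#'
#' First visit where mRSS exceeds baseline by >= 5 units *and* >= 25% of the
#' baseline value (both inclusive). A baseline mRSS of 0 with an increase of
#' >= 5 units qualifies (the relative condition is treated as satisfied).
#'
#' @param baseline_mrss baseline mRSS (integer >= 0).
#' @param visits one subject's time-sorted visit data.frame.
#' @param rules an [adjudication_rules()] object.
#' @return Earliest qualifying time (months) or `NA`.
#' @export
detect_skin_worsening <- function(baseline_mrss, visits,
                                  rules = adjudication_rules()) {
  .check_sorted(visits)
  if (is.na(baseline_mrss) || baseline_mrss < 0 ||
      any(visits$mrss < 0, na.rm = TRUE)) {
    .stop_validation("mRSS must be non-negative")
  }
  inc <- visits$mrss - baseline_mrss
  rel_ok <- if (baseline_mrss == 0) {
    rep(TRUE, nrow(visits))
  } else {
    inc / baseline_mrss >= rules$mrss_rel_increase
  }
  hit <- which(!is.na(visits$mrss) & inc >= rules$mrss_abs_increase & rel_ok)
  if (length(hit) == 0L) NA_real_ else visits$t[hit[1L]]
}

#' Map visit flags to component events
#'
#' New right-heart-catheter PAH counts only for subjects without baseline PAH;
#' any cardiac flag maps to a cardiac event; any GI-failure flag to a GI
#' event; `ssc_death` is the SSc-death event; `nonssc_death` is returned as a
#' censoring time, not an event.
#'
#' @param baseline one subject's baseline record (one-row data.frame).
#' @param visits one subject's time-sorted visit data.frame.
#' @return list with `events` (data.frame event/time) and `censor_at`
#'   (non-SSc death time or `NA`).
#' @export
detect_flag_events <- function(baseline, visits) {
  .check_sorted(visits)
  death <- visits$ssc_death | visits$nonssc_death
  if (any(death)) {
    d <- which(death)[1L]
    later <- visits[visits$t > visits$t[d], visit_flag_cols, drop = FALSE]
    if (d < nrow(visits) && any(unlist(later))) {
      stop(errorCondition("event flag after a death flag",
                          class = c("ifnttcw_contract_error", "ifnttcw_error")))
    }
  }
  grab <- function(cols) {
    hit <- rowSums(visits[, cols, drop = FALSE]) > 0
    if (any(hit)) visits$t[which(hit)[1L]] else NA_real_
  }
  events <- data.frame(event = character(0), time = numeric(0),
                       stringsAsFactors = FALSE)
  add <- function(ev, t) {
    if (!is.na(t)) rbind(events, data.frame(event = ev, time = t)) else events
  }
  if (!isTRUE(baseline$pah)) events <- add("pah", grab("new_pah_rhc"))
  events <- add("renal_crisis", grab("renal_crisis"))
  events <- add("cardiac", grab(c("cardiac_ef_lt45",
                                  "pericardial_effusion_impairing",
                                  "arrhythmia_treated", "cardiac_device")))
  events <- add("gi", grab(c("enteral_nutrition_3wk", "parenteral_feeding",
                             "gi_obstruction_admission")))
  events <- add("digital_vasculopathy", grab("digital_vasculopathy_admission"))
  events <- add("ssc_death", grab("ssc_death"))
  list(events = events, censor_at = grab("nonssc_death"))
}

#' Adjudicate one subject's first Morbi-mortality event
#'
#' Runs every detector and returns the earliest event; exact ties in time are
#' broken by a fixed severity order (SSc death > PAH > ILD progression >
#' cardiac > renal crisis > GI > digital vasculopathy > skin worsening).
#' With no event, the subject is censored at the minimum of the last visit
#' time, a non-SSc death time, and the 120-month horizon.
#'
#' @param baseline one-row baseline data.frame.
#' @param visits the subject's visit data.frame (any order; sorted here).
#' @param rules an [adjudication_rules()] object.
#' @return One-row outcome data.frame (`subject_id`, `event`, `ttcw_months`,
#'   `censored`).
#' @export
adjudicate_first_event <- function(baseline, visits,
                                   rules = adjudication_rules()) {
  id <- baseline$subject_id
  if (nrow(visits) == 0L) {
    warning(sprintf("subject %s has no visits; censored at 0", id))
    return(data.frame(subject_id = id, event = "none", ttcw_months = 0,
                      censored = TRUE, stringsAsFactors = FALSE))
  }
  visits <- visits[order(visits$t), , drop = FALSE]
  flags <- detect_flag_events(baseline, visits)
  cand <- flags$events
  t_ild <- detect_ild_progression(visits, rules)
  if (!is.na(t_ild)) {
    cand <- rbind(cand, data.frame(event = "ild_progression", time = t_ild))
  }
  t_skin <- detect_skin_worsening(baseline$mrss, visits, rules)
  if (!is.na(t_skin)) {
    cand <- rbind(cand, data.frame(event = "skin_worsening", time = t_skin))
  }
  censor_at <- min(max(visits$t), flags$censor_at, rules$horizon_months,
                   na.rm = TRUE)
  cand <- cand[cand$time <= censor_at, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(subject_id = id, event = "none",
                      ttcw_months = censor_at, censored = TRUE,
                      stringsAsFactors = FALSE))
  }
  cand$rank <- match(cand$event, .severity_order)
  cand <- cand[order(cand$time, cand$rank), , drop = FALSE]
  data.frame(subject_id = id, event = cand$event[1L],
             ttcw_months = cand$time[1L], censored = FALSE,
             stringsAsFactors = FALSE)
}

#' Adjudicate an entire cohort
#'
#' @param baseline baseline table.
#' @param visits visit table (all subjects).
#' @param rules an [adjudication_rules()] object.
#' @return Validated outcome table, one row per baseline subject.
#' @export
adjudicate_cohort <- function(baseline, visits,
                              rules = adjudication_rules()) {
  visits <- validate_visits(visits, baseline)
  by_subject <- split(visits, visits$subject_id)
  out <- do.call(rbind, lapply(seq_len(nrow(baseline)), function(i) {
    id <- baseline$subject_id[i]
    sub <- by_subject[[id]]
    if (is.null(sub)) sub <- visits[0, , drop = FALSE]
    adjudicate_first_event(baseline[i, , drop = FALSE], sub, rules)
  }))
  rownames(out) <- NULL
  validate_outcomes(out)
  out
}

#' Restrict to subjects with complete five-year information
#'
#' Keeps subjects who developed an event (their follow-up to the event is
#' complete) or who were censored at 60 months or later; drops only subjects
#' censored before 60 months.
#'
#' @param outcomes outcome table.
#' @return The retained subset.
#' @export
filter_complete_5yr <- function(outcomes) {
  keep <- !outcomes$censored | outcomes$ttcw_months >= 60
  outcomes[keep, , drop = FALSE]
}
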
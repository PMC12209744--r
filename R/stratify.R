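# Clinical x serologic risk stratification: acral involvement (mRSS > 4 or
# DU disease), cardiopulmonary involvement (baseline PAH or ILD), their
# crossing with the IFN class into eight strata, upset-style intersection
# counts, and relative risks versus the overall cohort at fixed horizons.

.involvement_levels <- c("none", "acral", "cardiopulmonary", "dual")

#' Assign clinical involvement strata and risk groups
#'
#' Acral involvement: mRSS > 4 (strict) or DU disease. Cardiopulmonary
#' involvement: baseline PAH or ILD. The four involvement classes crossed
#' with the IFN class give eight strata; `high_risk` requires a high IFN
#' score plus at least one clinical involvement.
#'
#' @param baseline baseline table.
#' @param scores score table with `ifn_class` (see [score_panels()]).
#' @return data.frame: subject_id, acral, cardiopulmonary, involvement,
#'   ifn_class, stratum, risk_group.
#' @export
assign_strata <- function(baseline, scores) {
  df <- merge(baseline[, c("subject_id", "mrss", "du_disease", "pah", "ild")],
              scores[, c("subject_id", "ifn_class")], by = "subject_id")
  df$acral <- df$mrss > 4 | df$du_disease
  df$cardiopulmonary <- df$pah | df$ild
  df$involvement <- ifelse(df$acral & df$cardiopulmonary, "dual",
                    ifelse(df$acral, "acral",
                    ifelse(df$cardiopulmonary, "cardiopulmonary", "none")))
  df$stratum <- paste(df$involvement, df$ifn_class, sep = ":")
  df$risk_group <- ifelse(df$ifn_class == "high" & df$involvement != "none",
                          "high_risk", "low_risk")
  df[, c("subject_id", "acral", "cardiopulmonary", "involvement",
         "ifn_class", "stratum", "risk_group")]
}

#' Per-stratum counts and event rates (upset-plot data)
#'
#' All eight involvement-by-IFN strata are reported (empty strata with
#' n = 0), with event counts, event rates and a flag for strata whose event
#' rate exceeds 50%.
#'
#' @param strata output of [assign_strata()].
#' @param outcomes outcome table.
#' @return data.frame: involvement, ifn_class, stratum, n, n_event,
#'   event_rate, exceeds_50pct.
#' @export
upset_counts <- function(strata, outcomes) {
  m <- merge(strata, outcomes[, c("subject_id", "censored")],
             by = "subject_id")
  grid <- expand.grid(involvement = .involvement_levels,
                      ifn_class = c("low", "high"),
                      stringsAsFactors = FALSE)
  grid$stratum <- paste(grid$involvement, grid$ifn_class, sep = ":")
  grid$n <- vapply(grid$stratum, function(s) sum(m$stratum == s), integer(1))
  grid$n_event <- vapply(grid$stratum,
                         function(s) sum(!m$censored[m$stratum == s]),
                         integer(1))
  grid$event_rate <- ifelse(grid$n > 0, grid$n_event / grid$n, NA_real_)
  grid$exceeds_50pct <- !is.na(grid$event_rate) & grid$event_rate > 0.5
  grid
}

.rr_point <- function(outcomes, member, t) {
  inc_all <- event_prob_at(km_estimate(outcomes), t)
  inc_g <- event_prob_at(km_estimate(outcomes[member, , drop = FALSE]), t)
  if (inc_all == 0) {
    stop(errorCondition("overall cumulative incidence is zero at horizon",
                        class = c("ifnttcw_contract_error", "ifnttcw_error")))
  }
  inc_g / inc_all
}

#' Relative risk of a group versus the overall cohort at fixed horizons
#'
#' RR(t) = (1 - S_group(t)) / (1 - S_overall(t)) from KM estimates.
#' Confidence intervals come from a subject-level bootstrap (default; the
#' group shares subjects with the overall cohort, so independence does not
#' hold) or from a delta-method approximation on log RR with Greenwood
#' variances treating group and overall as independent (documented
#' approximation).
#'
#' @param outcomes outcome table.
#' @param groups named list of logical membership vectors aligned with
#'   `outcomes` rows, or a character vector of group labels per row.
#' @param horizons months, default `c(24, 36, 48)`.
#' @param method `"bootstrap"` or `"delta"`.
#' @param n_boot bootstrap iterations.
#' @param seed bootstrap seed.
#' @return data.frame: group, horizon, rr, lo, hi, method.
#' @export
rr_vs_overall <- function(outcomes, groups, horizons = c(24, 36, 48),
                          method = c("bootstrap", "delta"),
                          n_boot = 500, seed = 1L) {
  method <- match.arg(method)
  if (is.character(groups) || is.factor(groups)) {
    labs <- as.character(groups)
    groups <- lapply(stats::setNames(nm = sort(unique(labs))),
                     function(g) labs == g)
  }
  rows <- list()
  for (g in names(groups)) {
    member <- groups[[g]]
    for (t in horizons) {
      rr <- .rr_point(outcomes, member, t)
      if (method == "bootstrap") {
        set.seed(seed)
        reps <- replicate(n_boot, {
          idx <- sample(nrow(outcomes), replace = TRUE)
          tryCatch(.rr_point(outcomes[idx, , drop = FALSE], member[idx], t),
                   error = function(e) NA_real_)
        })
        ci <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE,
                              names = FALSE)
      } else {
        call_g <- km_estimate(outcomes[member, , drop = FALSE])
        call_a <- km_estimate(outcomes)
        ig <- event_prob_at(call_g, t); ia <- event_prob_at(call_a, t)
        vg <- km_var_at(call_g, t); va <- km_var_at(call_a, t)
        # delta method on log RR, groups treated as independent
        vlog <- vg / ig^2 + va / ia^2
        ci <- exp(log(rr) + c(-1, 1) * stats::qnorm(0.975) * sqrt(vlog))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, horizon = t, rr = rr, lo = ci[1], hi = ci[2],
        method = method, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
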
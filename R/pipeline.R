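# End-to-end orchestration: simulate -> score -> adjudicate -> survival ->
# Cox/discrimination -> stratification -> report, plus the baseline
# group-comparison table machinery.

#' Run configuration
#'
#' @param seed master seed; flows into the simulation config and every
#'   bootstrap.
#' @param sim a [sim_config()] (defaults to `sim_config(seed = seed)`).
#' @param rules an [adjudication_rules()] object.
#' @param timepoints fixed-time analysis horizons, months.
#' @param rr_horizons relative-risk horizons, months.
#' @param n_boot bootstrap iterations for discrimination/RR uncertainty.
#' @param spline_df penalized-spline degrees of freedom.
#' @return A classed `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       sim = sim_config(seed = seed),
                       rules = adjudication_rules(),
                       timepoints = c(12, 24, 36, 60, 120),
                       rr_horizons = c(24, 36, 48),
                       n_boot = 1000,
                       spline_df = 4) {
  stopifnot(all(timepoints <= 120), n_boot >= 0)
  structure(list(seed = as.integer(seed), sim = sim, rules = rules,
                 timepoints = timepoints, rr_horizons = rr_horizons,
                 n_boot = n_boot, spline_df = spline_df),
            class = "run_config")
}

#' Read a run configuration from YAML/JSON
#'
#' Scalar fields override [run_config()] defaults; `sim` and `rules`
#' sub-maps override the corresponding constructor defaults.
#'
#' @param path YAML (or JSON, a YAML subset) file.
#' @param seed optional seed overriding the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  seed <- seed %||% raw$seed %||% 1L
  sim <- do.call(sim_config, c(list(seed = seed), raw$sim))
  rules <- do.call(adjudication_rules, raw$rules %||% list())
  args <- raw[intersect(names(raw),
                        c("timepoints", "rr_horizons", "n_boot",
                          "spline_df"))]
  do.call(run_config, c(list(seed = seed, sim = sim, rules = rules), args))
}

# baseline comparison table -----------------------------------------------

.compare_categorical <- function(x, g) {
  tab <- table(x, g)
  if (nrow(tab) < 2L) return(list(test = "none", p = NA_real_,
                                  estimate = NA_real_,
                                  note = "constant; skipped"))
  expected <- suppressWarnings(stats::chisq.test(tab)$expected)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    test <- "fisher"
  } else {
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
    test <- "chisq"
  }
  est <- if (all(dim(tab) == c(2L, 2L))) {
    # sample (cross-product) odds ratio: odds of the second variable level
    # in the first group versus the second group
    (tab[2, 1] * tab[1, 2]) / (tab[1, 1] * tab[2, 2])
  } else NA_real_
  list(test = test, p = p, estimate = est, note = "")
}

.compare_continuous <- function(x, g) {
  lv <- unique(g)
  xa <- x[g == lv[1]]; xb <- x[g == lv[2]]
  if (stats::sd(x) == 0) {
    return(list(test = "none", p = NA_real_, estimate = NA_real_,
                note = "constant; skipped"))
  }
  normal <- function(v) {
    if (length(unique(v)) < 3L || length(v) < 3L || length(v) > 5000L) {
      return(FALSE)
    }
    stats::shapiro.test(v)$p.value >= 0.05
  }
  if (normal(xa) && normal(xb)) {
    var_p <- stats::var.test(xa, xb)$p.value
    p <- stats::t.test(xa, xb, var.equal = var_p >= 0.05)$p.value
    test <- "t"
  } else {
    p <- suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
    test <- "wilcoxon"
  }
  list(test = test, p = p, estimate = mean(xa) - mean(xb), note = "")
}

#' Baseline characteristics comparison table
#'
#' Per-variable two-group comparison with automatic test selection:
#' categorical variables use the Fisher exact test when any expected cell
#' count is below 5 and the Pearson chi-square test otherwise; continuous
#' variables use Student's t-test (pooled or Welch by an F-test of variance
#' homogeneity) when both groups pass a Shapiro-Wilk normality gate at 0.05
#' and the Wilcoxon rank-sum test otherwise. P-values receive
#' Benjamini-Hochberg q-values.
#'
#' @param data data.frame of subjects (e.g. baseline joined with scores).
#' @param group two-level grouping vector aligned with `data` rows.
#' @param vars variables to compare (default: all columns except
#'   `subject_id`).
#' @return data.frame: variable, test, estimate (2x2 cross-product odds
#'   ratio or mean difference), p, q, note.
#' @export
baseline_table <- function(data, group,
                           vars = setdiff(names(data), "subject_id")) {
  group <- as.character(group)
  stopifnot(length(group) == nrow(data), length(unique(group)) == 2L)
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    res <- if (is.numeric(x) && length(unique(x)) > 2L) {
      .compare_continuous(x, group)
    } else {
      .compare_categorical(as.character(x), group)
    }
    data.frame(variable = v, test = res$test, estimate = res$estimate,
               p = res$p, note = res$note, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab[, c("variable", "test", "estimate", "p", "q", "note")]
}

# orchestration ------------------------------------------------------------

.split_outcomes <- function(outcomes, scores) {
  m <- merge(outcomes, scores[, c("subject_id", "ifn_class")],
             by = "subject_id")
  list(high = m[m$ifn_class == "high", , drop = FALSE],
       low = m[m$ifn_class == "low", , drop = FALSE],
       all = m)
}

.cox_fit_json <- function(fit) {
  out <- list(n = fit$n, n_events = fit$n_events,
              diverged = fit$diverged, terms = fit$terms)
  if (!is.null(fit$spline)) out$spline <- fit$spline
  out
}

#' Run the full analysis pipeline
#'
#' Simulates a study (controls + patients), derives the IFN threshold,
#' scores and classifies patients, adjudicates the composite endpoint, and
#' runs the survival, Cox/discrimination, stratification and power analyses.
#' Deterministic given the configuration seed.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, writes scores.csv,
#'   outcomes.csv, survival.json, models.json, strata.json and report.txt.
#' @return A `ttcw_report` list with all stage outputs.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  study <- simulate_study(config$sim)
  threshold <- derive_threshold(compute_ifn_score(study$controls))
  scores <- score_panels(study$panels, threshold)
  outcomes <- adjudicate_cohort(study$baseline, study$visits, config$rules)
  grp <- .split_outcomes(outcomes, scores)

  km_all <- km_estimate(outcomes)
  km_high <- km_estimate(grp$high)
  km_low <- km_estimate(grp$low)
  tp <- config$timepoints[config$timepoints <=
                            min(km_high$max_time, km_low$max_time)]
  contrasts <- lapply(tp, function(t) {
    fixed_time_contrast(km_high, km_low, t)
  })
  surv_block <- list(
    event_prob_overall = stats::setNames(
      as.list(event_prob_at(km_all, tp)), paste0("m", tp)),
    event_prob_high = stats::setNames(
      as.list(event_prob_at(km_high, tp)), paste0("m", tp)),
    event_prob_low = stats::setNames(
      as.list(event_prob_at(km_low, tp)), paste0("m", tp)),
    contrasts = contrasts,
    rmst = rmst_compare(grp$high, grp$low),
    log_rank = log_rank(grp$high, grp$low),
    five_year = {
      f <- filter_complete_5yr(grp$all)
      list(n_retained = nrow(f),
           rmst = rmst_compare(f[f$ifn_class == "high", ],
                               f[f$ifn_class == "low", ]))
    })

  cov <- merge(study$baseline, scores, by = "subject_id")
  cov$ifn_high <- cov$ifn_class == "high"
  screen_terms <- c("age", "disease_duration", "aca", "scl70", "ro52",
                    "mrss", "fvc_pct", "dlco_pct", "upper_gi", "ild",
                    "du_disease", "calcinosis", "pah", "mmf", "era",
                    "ifn_score", "ifn_high")
  screen <- univariable_screen(outcomes, cov, screen_terms,
                               smooth = "ifn_score")
  models <- multivariable_models(outcomes, study$baseline, scores,
                                 spline_df = config$spline_df)

  oc_m <- grp$all # outcomes joined with ifn_class
  covnum <- cov
  for (nm in names(covnum)) {
    if (is.logical(covnum[[nm]])) covnum[[nm]] <- as.numeric(covnum[[nm]])
  }
  lp_fn <- function(fit_terms, smooth) {
    function(oc) {
      f <- suppressWarnings(fit_cox(oc, cov, fit_terms, smooth = smooth,
                                    spline_df = config$spline_df))
      lp <- stats::predict(f$model, newdata = covnum, type = "lp")
      unname(lp[match(oc$subject_id, covnum$subject_id)])
    }
  }
  clinical <- c("ild", "pah", "mrss", "du_disease", "age")
  troc <- list(
    model1 = td_roc(oc_m, times = c(12, 24, 36), n_boot = config$n_boot,
                    seed = config$seed,
                    marker_fn = lp_fn(clinical, "ifn_score")),
    model2 = td_roc(oc_m, times = c(12, 24, 36), n_boot = config$n_boot,
                    seed = config$seed,
                    marker_fn = lp_fn(c("ifn_high", clinical), NULL)),
    ifn_only = td_roc(oc_m, marker = merge(oc_m, scores,
                                           by = "subject_id")$ifn_score,
                      times = c(12, 24, 36), n_boot = 0))

  strata <- assign_strata(study$baseline, scores)
  strata_m <- strata[match(outcomes$subject_id, strata$subject_id), ]
  upset <- upset_counts(strata, outcomes)
  rr <- rbind(
    rr_vs_overall(outcomes, stats::setNames(
      list(strata_m$risk_group == "high_risk",
           strata_m$risk_group == "low_risk"),
      c("high_risk", "low_risk")),
      horizons = config$rr_horizons, n_boot = max(config$n_boot, 100),
      seed = config$seed),
    rr_vs_overall(outcomes, stats::setNames(
      list(strata_m$ifn_class == "high", strata_m$ifn_class == "low"),
      c("ifn_high", "ifn_low")),
      horizons = config$rr_horizons, n_boot = max(config$n_boot, 100),
      seed = config$seed))
  risk_lr <- log_rank(outcomes[strata_m$risk_group == "high_risk", ],
                      outcomes[strata_m$risk_group == "low_risk", ])

  tbl_vars <- c("age", "sex", "disease_duration", "ana", "aca", "scl70",
                "ro52", "mrss", "fvc_pct", "dlco_pct", "upper_gi", "ild",
                "du_disease", "calcinosis", "pah", "ifn_score")
  tables <- list(
    by_event = baseline_table(
      cov, ifelse(outcomes$censored[match(cov$subject_id,
                                          outcomes$subject_id)],
                  "no_event", "event"), tbl_vars),
    by_ifn = baseline_table(cov, cov$ifn_class, tbl_vars))

  report <- structure(list(
    config = config, study = study, threshold = threshold,
    scores = scores, outcomes = outcomes, survival = surv_block,
    screen = screen, models = models, td_roc = troc, strata = strata,
    upset = upset, rr = rr, risk_group_log_rank = risk_lr,
    tables = tables, power = power_design()),
    class = "ttcw_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report bundle to disk
#'
#' @param report a `ttcw_report` from [run_all()].
#' @param out_dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(report$scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  .write_table(report$outcomes, file.path(out_dir, "outcomes.csv"),
               "outcomes")
  wj <- function(x, f) {
    jsonlite::write_json(x, file.path(out_dir, f), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  sv <- report$survival
  wj(list(threshold = unclass(report$threshold),
          event_prob = list(overall = sv$event_prob_overall,
                            ifn_high = sv$event_prob_high,
                            ifn_low = sv$event_prob_low),
          contrasts = sv$contrasts,
          rmst = unclass(sv$rmst), log_rank = sv$log_rank,
          five_year = list(n_retained = sv$five_year$n_retained,
                           rmst = unclass(sv$five_year$rmst))),
     "survival.json")
  wj(list(univariable = report$screen,
          model1 = .cox_fit_json(report$models$model1),
          model2 = .cox_fit_json(report$models$model2),
          discrimination = lapply(report$td_roc, function(x) {
            list(auc_at = x$auc_at, c_index = x$c_index,
                 c_index_se = x$c_index_se, n_boot = x$n_boot)
          })),
     "models.json")
  wj(list(upset = report$upset, rr = report$rr,
          risk_group_log_rank = report$risk_group_log_rank),
     "strata.json")
  writeLines(format_report(report), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Human-readable report lines
#'
#' @param report a `ttcw_report`.
#' @return Character vector of report lines.
#' @export
format_report <- function(report) {
  sv <- report$survival
  n_high <- sum(report$scores$ifn_class == "high")
  n_low <- sum(report$scores$ifn_class == "low")
  ev <- merge(report$outcomes, report$scores, by = "subject_id")
  pct <- function(num, den) 100 * num / den
  m2 <- report$models$model2
  hr_ifn <- m2$terms[m2$terms$term == "ifn_high", ]
  c(sprintf("Cohort: %d patients (%d IFN-high, %d IFN-low); threshold %.3f",
            nrow(report$scores), n_high, n_low,
            report$threshold$threshold),
    sprintf("Events: %d (%.1f%%); IFN-high %.0f%% vs IFN-low %.0f%%",
            sum(!report$outcomes$censored),
            pct(sum(!report$outcomes$censored), nrow(report$outcomes)),
            pct(sum(!ev$censored & ev$ifn_class == "high"), n_high),
            pct(sum(!ev$censored & ev$ifn_class == "low"), n_low)),
    sprintf("Restricted mean TTCW (tau %.0f): high %.1f vs low %.1f months, p = %.3g",
            sv$rmst$tau, sv$rmst$rmst_a, sv$rmst$rmst_b, sv$rmst$p_value),
    sprintf("Log-rank chi-square %.2f, p = %.3g",
            sv$log_rank$chisq, sv$log_rank$p_value),
    sprintf("Model 2 IFN-high HR %.2f (95%% CI %.2f-%.2f)",
            hr_ifn$hr, hr_ifn$lo, hr_ifn$hi),
    sprintf("Model 1 C-index %.3f; Model 2 C-index %.3f",
            report$td_roc$model1$c_index, report$td_roc$model2$c_index),
    sprintf("High-risk stratum RR at 24 months: %.2f",
            report$rr$rr[report$rr$group == "high_risk" &
                           report$rr$horizon == 24]))
}

#' @export
print.ttcw_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}
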
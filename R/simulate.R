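# Synthetic lcSSc cohort generator. Emulates the statistical structure the
# downstream analysis assumes: control/patient IFN score distributions,
# baseline covariate prevalences, a latent proportional-hazards first-event
# process realized as 6-monthly visit trajectories, and administrative
# (staggered-entry) censoring capped at 120 months.

# Per-chemokine mean ln concentrations (pg/mL): offsets below are these means
# centred to zero so the subject's score is preserved exactly.
.patient_ln_means <- c(ccl2 = 6.14, ccl8 = 3.78, ccl19 = 5.82,
                       cxcl9 = 6.93, cxcl10 = 5.99, cxcl11 = 3.89)
.control_ln_means <- c(ccl2 = 6.00, ccl8 = 3.43, ccl19 = 5.20,
                       cxcl9 = 6.11, cxcl10 = 5.43, cxcl11 = 3.40)

.default_prevalence <- c(
  ana = 0.95, aca = 0.67, scl70 = 0.081, ro52 = 0.23, rnapol3 = 0.027,
  u1rnp = 0.054, ild = 0.24, pah = 0.06, du_disease = 0.39,
  calcinosis = 0.36, upper_gi = 0.64, sjogren_overlap = 0.10,
  mmf = 0.087, era = 0.047, pde5i = 0.16, iloprost = 0.17, ccb = 0.63,
  hcq = 0.17, aspirin = 0.20, ace = 0.34)

# Clinical prognostic effects on the latent hazard (log HRs per covariate;
# mrss is per unit), matching the reported univariable associations.
.default_clinical_log_hr <- c(ild = log(2.73), pah = log(4.78),
                              du_disease = log(2.12), mrss = log(1.13))

# First-event mix: PAH 13, SSc death 9, ILD progression 6, cardiac 6,
# skin 5, GI 4, digital vasculopathy 3, renal crisis 1 (of 47).
.default_event_mix <- c(pah = 13, ssc_death = 9, ild_progression = 6,
                        cardiac = 6, skin_worsening = 5, gi = 4,
                        digital_vasculopathy = 3, renal_crisis = 1) / 47

#' Simulation configuration
#'
#' Defaults encode the study conditions of the cohort being emulated: 72
#' healthy controls with IFN score ~ N(4.97, 0.27^2); 149 patients with score
#' ~ N(5.45, 0.46^2) (about 45% above the mean + 2 SD control threshold); an
#' exponential latent first-event process with a group hazard ratio of 6.2
#' for IFN-high versus IFN-low calibrated so ten-year event fractions are
#' about 55% versus 12%; 6-monthly visits; and staggered-entry administrative
#' censoring (median available follow-up about 89 months, capped at 120).
#'
#' @param seed integer seed; all randomness flows from it.
#' @param replicate integer replicate index, added to `seed` so replicate
#'   streams are deterministic.
#' @param n_controls,n_patients cohort sizes.
#' @param control_score_mean,control_score_sd,patient_score_mean,patient_score_sd
#'   IFN score distribution parameters.
#' @param chemokine_noise_sd spread of per-chemokine ln values around
#'   score + loading (centred so the score is preserved exactly).
#' @param prevalence named vector of baseline binary-covariate prevalences.
#' @param female_prob,age_mean,age_sd,duration_meanlog,duration_sdlog,
#'   mrss_mean,mrss_sd,fvc_mean,fvc_sd,dlco_mean,dlco_sd continuous baseline
#'   covariate parameters (mRSS truncated at 0 and rounded to integer).
#' @param effect `"group"` (hazard multiplied by `group_hr` for latent
#'   IFN-high subjects) or `"score"` (log-linear in the score,
#'   `score_log_hr` per score unit around the patient mean).
#' @param group_hr hazard ratio for latent IFN-high versus IFN-low; used
#'   directly (no calibration) when `high_event_prob` is `NULL`.
#' @param high_event_prob target marginal ten-year event fraction of the
#'   latent IFN-high stratum (default 0.55). When non-`NULL` (group-effect
#'   mode), the IFN-high hazard multiplier is calibrated against the drawn
#'   covariates to attain it, overriding `group_hr`; with no clinical
#'   effects the calibrated multiplier coincides with the closed form
#'   `log(1 - p_high) / log(1 - p_low)` (about 6.2 at 0.55 vs 0.12).
#' @param score_log_hr log hazard ratio per IFN score unit (effect "score").
#' @param clinical_log_hr named numeric vector of log hazard ratios for
#'   baseline covariates (defaults: ILD 2.73, PAH 4.78, DU disease 2.12,
#'   mRSS 1.13 per unit, on the HR scale); set to `NULL` or zeros for an
#'   IFN-only hazard.
#' @param low_event_prob cumulative event probability over `horizon` months
#'   averaged over the IFN-low stratum (the baseline hazard is calibrated
#'   against the drawn covariates so this marginal fraction is attained).
#' @param event_mix named probabilities of first-event types.
#' @param horizon administrative cap, months.
#' @param visit_interval months between visits.
#' @param entry_stagger_max months of uniform staggered entry; available
#'   follow-up is `horizon - U(0, entry_stagger_max)`.
#' @param fvc_noise_sd,dlco_noise_sd visit-to-visit measurement noise
#'   (percent-predicted points), kept well below the progression thresholds
#'   so only constructed trajectories trigger the rules.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       replicate = 0L,
                       n_controls = 72L,
                       n_patients = 149L,
                       control_score_mean = 4.97,
                       control_score_sd = 0.27,
                       patient_score_mean = 5.45,
                       patient_score_sd = 0.46,
                       chemokine_noise_sd = 0.35,
                       prevalence = .default_prevalence,
                       female_prob = 0.96,
                       age_mean = 60, age_sd = 16,
                       duration_meanlog = log(8), duration_sdlog = 0.9,
                       mrss_mean = 2.09, mrss_sd = 2.63,
                       fvc_mean = 109, fvc_sd = 20,
                       dlco_mean = 67, dlco_sd = 15,
                       effect = c("group", "score"),
                       group_hr = 6.2,
                       high_event_prob = 0.55,
                       score_log_hr = log(2.82),
                       clinical_log_hr = .default_clinical_log_hr,
                       low_event_prob = 0.12,
                       event_mix = .default_event_mix,
                       horizon = 120,
                       visit_interval = 6,
                       entry_stagger_max = 62,
                       fvc_noise_sd = 0.8,
                       dlco_noise_sd = 1.0) {
  effect <- match.arg(effect)
  cfg <- list(seed = as.integer(seed), replicate = as.integer(replicate),
              n_controls = as.integer(n_controls),
              n_patients = as.integer(n_patients),
              control_score_mean = control_score_mean,
              control_score_sd = control_score_sd,
              patient_score_mean = patient_score_mean,
              patient_score_sd = patient_score_sd,
              chemokine_noise_sd = chemokine_noise_sd,
              prevalence = prevalence,
              female_prob = female_prob,
              age_mean = age_mean, age_sd = age_sd,
              duration_meanlog = duration_meanlog,
              duration_sdlog = duration_sdlog,
              mrss_mean = mrss_mean, mrss_sd = mrss_sd,
              fvc_mean = fvc_mean, fvc_sd = fvc_sd,
              dlco_mean = dlco_mean, dlco_sd = dlco_sd,
              effect = effect, group_hr = group_hr,
              high_event_prob = high_event_prob,
              score_log_hr = score_log_hr,
              clinical_log_hr = clinical_log_hr,
              low_event_prob = low_event_prob,
              event_mix = event_mix,
              horizon = horizon, visit_interval = visit_interval,
              entry_stagger_max = entry_stagger_max,
              fvc_noise_sd = fvc_noise_sd, dlco_noise_sd = dlco_noise_sd)
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` list.
#' @return The config, classed, invisibly usable.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  probs <- c(cfg$prevalence, cfg$female_prob, cfg$low_event_prob,
             cfg$high_event_prob, cfg$event_mix)
  if (any(probs < 0 | probs > 1)) {
    .stop_validation("simulation probabilities must lie in [0, 1]")
  }
  sds <- c(cfg$control_score_sd, cfg$patient_score_sd, cfg$mrss_sd,
           cfg$age_sd, cfg$fvc_sd, cfg$dlco_sd)
  if (any(sds <= 0)) .stop_validation("simulation SDs must be > 0")
  if (length(cfg$clinical_log_hr) > 0) {
    known <- c(.organ_cols, "mrss", "age", "du_disease")
    if (is.null(names(cfg$clinical_log_hr)) ||
        !all(names(cfg$clinical_log_hr) %in% known)) {
      .stop_validation("clinical_log_hr must be named by baseline covariates")
    }
  }
  if (abs(sum(cfg$event_mix) - 1) > 1e-8) {
    .stop_validation("event_mix must sum to 1")
  }
  lambda_ref <- -log(1 - cfg$low_event_prob) / cfg$horizon
  lambda_max <- switch(cfg$effect,
    group = lambda_ref * max(1, cfg$group_hr),
    score = lambda_ref * exp(abs(cfg$score_log_hr) * 4 * cfg$patient_score_sd))
  if (lambda_max * cfg$visit_interval > 1) {
    .stop_validation(
      "configuration implies per-visit event probability above 1")
  }
  structure(cfg, class = "sim_config")
}

.effective_seed <- function(cfg, offset = 0L) {
  (cfg$seed + cfg$replicate + offset) %% .Machine$integer.max
}

.make_panels <- function(ids, scores, ln_means, noise_sd,
                         sample_months = 0) {
  loadings <- ln_means - mean(ln_means)
  n <- length(ids)
  eps <- matrix(stats::rnorm(n * 6, sd = noise_sd), nrow = n)
  eps <- eps - rowMeans(eps)
  ln <- outer(scores, rep(1, 6)) + outer(rep(1, n), loadings) + eps
  conc <- exp(ln)
  colnames(conc) <- names(loadings)
  df <- data.frame(subject_id = ids, conc,
                   sample_months_from_baseline = sample_months,
                   stringsAsFactors = FALSE)
  df[, .panel_cols]
}

#' Generate healthy-control chemokine panels
#'
#' Each control's IFN score is drawn from the configured normal distribution;
#' per-chemokine ln concentrations are score + fixed offsets (centred printed
#' control means) + mean-zero noise constrained so the panel's score equals
#' the drawn score exactly.
#'
#' @param cfg a [sim_config()].
#' @return A panel data.frame of `n_controls` rows.
#' @export
generate_controls <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set.seed(.effective_seed(cfg))
  ids <- sprintf("HC%03d", seq_len(cfg$n_controls))
  scores <- stats::rnorm(cfg$n_controls, cfg$control_score_mean,
                         cfg$control_score_sd)
  validate_panels(.make_panels(ids, scores, .control_ln_means,
                               cfg$chemokine_noise_sd))
}

.draw_baseline <- function(cfg, ids) {
  n <- length(ids)
  base <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  base$age <- round(pmin(95, pmax(18, stats::rnorm(n, cfg$age_mean, cfg$age_sd))))
  base$sex <- ifelse(stats::runif(n) < cfg$female_prob, "female", "male")
  base$disease_duration <- round(stats::rlnorm(n, cfg$duration_meanlog,
                                               cfg$duration_sdlog), 1)
  for (col in names(cfg$prevalence)) {
    base[[col]] <- stats::runif(n) < cfg$prevalence[[col]]
  }
  base$mrss <- pmax(0L, as.integer(round(stats::rnorm(n, cfg$mrss_mean,
                                                      cfg$mrss_sd))))
  base$fvc_pct <- pmin(199, pmax(30, stats::rnorm(n, cfg$fvc_mean, cfg$fvc_sd)))
  base$dlco_pct <- pmin(199, pmax(15, stats::rnorm(n, cfg$dlco_mean,
                                                   cfg$dlco_sd)))
  base[, .baseline_cols]
}

.empty_visits <- function(id, times) {
  k <- length(times)
  vis <- data.frame(subject_id = rep(id, k), t = times,
                    fvc_pct = NA_real_, dlco_pct = NA_real_,
                    mrss = NA_integer_, stringsAsFactors = FALSE)
  for (fl in visit_flag_cols) vis[[fl]] <- rep(FALSE, k)
  vis
}

# Realize one subject's visit stream. Non-event visits carry small-noise FVC
# and DLco and a constant mRSS; the event visit (if any) carries the
# trajectory or flag that triggers exactly the intended adjudication rule.
.realize_visits <- function(cfg, id, base_row, event_type, event_visit,
                            last_visit) {
  end <- if (is.na(event_visit)) last_visit else event_visit
  times <- seq(0, end, by = cfg$visit_interval)
  k <- length(times)
  fvc <- base_row$fvc_pct + stats::rnorm(k, sd = cfg$fvc_noise_sd)
  dlco <- base_row$dlco_pct + stats::rnorm(k, sd = cfg$dlco_noise_sd)
  mrss <- rep(base_row$mrss, k)
  vis <- .empty_visits(id, times)
  if (!is.na(event_visit)) {
    i <- k # event terminates the stream at its visit
    if (event_type == "ild_progression") {
      fvc[i] <- fvc[i - 1] - 11
    } else if (event_type == "skin_worsening") {
      b <- base_row$mrss
      mrss[i] <- b + max(5L, as.integer(ceiling(0.25 * b)))
    } else {
      flag <- switch(event_type,
        pah = "new_pah_rhc",
        ssc_death = "ssc_death",
        renal_crisis = "renal_crisis",
        cardiac = sample(c("cardiac_ef_lt45", "pericardial_effusion_impairing",
                           "arrhythmia_treated", "cardiac_device"), 1L),
        gi = sample(c("enteral_nutrition_3wk", "parenteral_feeding",
                      "gi_obstruction_admission"), 1L),
        digital_vasculopathy = "digital_vasculopathy_admission")
      vis[[flag]][i] <- TRUE
    }
  }
  vis$fvc_pct <- round(fvc, 1)
  vis$dlco_pct <- round(dlco, 1)
  vis$mrss <- as.integer(mrss)
  vis
}

#' Generate a synthetic patient cohort
#'
#' Draws IFN scores from the patient distribution, a latent first-event time
#' from an exponential hazard with the configured IFN effect, an event type
#' from the configured mix (excluding "new PAH" for subjects with baseline
#' PAH), and a staggered-entry administrative censoring time. Visit streams
#' every `visit_interval` months realize the latent event: an ILD-progression
#' truth produces an FVC drop crossing the rule, a skin-worsening truth an
#' mRSS rise of >= 5 units and >= 25%, and flag-type truths set the
#' corresponding visit flag at the event visit.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_cohort` with `baseline`, `panels`, `visits`
#'   and `truth` (latent event type/time, censoring time, and whether the
#'   event falls inside the observation window).
#' @export
generate_cohort <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set.seed(.effective_seed(cfg, offset = 1L))
  n <- cfg$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  scores <- stats::rnorm(n, cfg$patient_score_mean, cfg$patient_score_sd)
  latent_threshold <- cfg$control_score_mean + 2 * cfg$control_score_sd
  latent_high <- scores > latent_threshold

  baseline <- .draw_baseline(cfg, ids)
  panels <- .make_panels(ids, scores, .patient_ln_means,
                         cfg$chemokine_noise_sd)

  clin_mult <- rep(1, n)
  for (nm in names(cfg$clinical_log_hr)) {
    clin_mult <- clin_mult *
      exp(cfg$clinical_log_hr[[nm]] * as.numeric(baseline[[nm]]))
  }
  # calibrate the baseline hazard so the IFN-low stratum's marginal
  # horizon-month event fraction matches low_event_prob given the drawn
  # covariate mix (reduces to the closed form when all multipliers are 1)
  score_mult <- exp(cfg$score_log_hr * (scores - cfg$patient_score_mean))
  low_idx <- if (any(!latent_high)) which(!latent_high) else seq_len(n)
  m_low <- clin_mult[low_idx] *
    (if (cfg$effect == "score") score_mult[low_idx] else 1)
  lambda0 <- stats::uniroot(function(l0) {
    mean(1 - exp(-l0 * m_low * cfg$horizon)) - cfg$low_event_prob
  }, c(1e-10, 1), tol = 1e-14)$root
  if (cfg$effect == "group") {
    g <- cfg$group_hr
    if (!is.null(cfg$high_event_prob) && any(latent_high)) {
      # calibrate the IFN-high multiplier against the high-stratum target
      m_high <- clin_mult[latent_high]
      g <- stats::uniroot(function(gg) {
        mean(1 - exp(-lambda0 * m_high * gg * cfg$horizon)) -
          cfg$high_event_prob
      }, c(1, 1e4), tol = 1e-12)$root
    }
    ifn_mult <- ifelse(latent_high, g, 1)
  } else {
    ifn_mult <- score_mult
  }
  lambda <- lambda0 * clin_mult * ifn_mult
  latent_time <- stats::rexp(n, lambda)
  admin <- cfg$horizon - stats::runif(n, 0, cfg$entry_stagger_max)
  last_visit <- floor(admin / cfg$visit_interval) * cfg$visit_interval

  types <- character(n)
  for (i in seq_len(n)) {
    mix <- cfg$event_mix
    if (baseline$pah[i] && "pah" %in% names(mix)) {
      mix <- mix[names(mix) != "pah"]
      mix <- mix / sum(mix)
    }
    types[i] <- sample(names(mix), 1L, prob = mix)
  }

  event_visit <- cfg$visit_interval *
    ceiling(latent_time / cfg$visit_interval)
  observed <- event_visit <= last_visit
  event_visit[!observed] <- NA_real_

  visits <- do.call(rbind, lapply(seq_len(n), function(i) {
    .realize_visits(cfg, ids[i], baseline[i, ], types[i],
                    event_visit[i], last_visit[i])
  }))
  rownames(visits) <- NULL

  truth <- data.frame(
    subject_id = ids,
    ifn_score = scores,
    latent_class = ifelse(latent_high, "high", "low"),
    latent_event = types,
    latent_time = latent_time,
    censor_time = last_visit,
    observed = observed,
    event_visit = ifelse(observed, event_visit, NA_real_),
    stringsAsFactors = FALSE)

  structure(list(baseline = validate_baseline(baseline),
                 panels = validate_panels(panels),
                 visits = validate_visits(visits, baseline),
                 truth = truth),
            class = "sim_cohort")
}

#' Generate a full synthetic study (controls + patients)
#'
#' @param cfg a [sim_config()].
#' @return An `ssc_cohort` bundle (controls, baseline, panels, visits) plus a
#'   `truth` element.
#' @export
simulate_study <- function(cfg) {
  controls <- generate_controls(cfg)
  cohort <- generate_cohort(cfg)
  structure(list(controls = controls, baseline = cohort$baseline,
                 panels = cohort$panels, visits = cohort$visits,
                 outcomes = NULL, truth = cohort$truth),
            class = "ssc_cohort")
}

#' Lightweight two-group survival simulator
#'
#' Draws exponential event times with a group hazard ratio and
#' staggered-entry administrative censoring; used for calibration studies
#' (log-rank type-I error, Cox coverage) where visit-level realization is
#' unnecessary. Uses the current RNG state.
#'
#' @param n subjects (split roughly half and half between groups).
#' @param hr hazard ratio group 1 versus group 0.
#' @param p_control_event cumulative event probability over `horizon` in
#'   group 0.
#' @param horizon,entry_stagger_max censoring model as in [sim_config()].
#' @return data.frame with `time`, `status` (1 event), `group` (0/1).
#' @export
simulate_two_group <- function(n, hr, p_control_event = 0.4,
                               horizon = 120, entry_stagger_max = 62) {
  group <- rep(0:1, length.out = n)
  lambda0 <- -log(1 - p_control_event) / horizon
  lambda <- lambda0 * ifelse(group == 1, hr, 1)
  t_event <- stats::rexp(n, lambda)
  t_cens <- horizon - stats::runif(n, 0, entry_stagger_max)
  data.frame(time = pmin(t_event, t_cens),
             status = as.integer(t_event <= t_cens),
             group = group)
}

#' Latent-truth recovery rate of the adjudicator
#'
#' Fraction of subjects whose adjudicated outcome matches the generator's
#' latent truth: for subjects whose latent event falls inside the observation
#' window, the event type must match and the adjudicated time must be within
#' `tolerance` months of the latent time; otherwise the outcome must be
#' censored.
#'
#' @param truth the `truth` table from [generate_cohort()].
#' @param outcomes the adjudicated outcome table.
#' @param tolerance months (default one visit interval, 6).
#' @return Proportion in \[0, 1\].
#' @export
recovery_rate <- function(truth, outcomes, tolerance = 6) {
  m <- merge(truth, outcomes, by = "subject_id")
  ok <- ifelse(m$observed,
               !m$censored & m$event == m$latent_event &
                 abs(m$ttcw_months - m$latent_time) <= tolerance,
               m$censored)
  mean(ok)
}
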
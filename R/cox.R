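# Cox proportional-hazards modelling: univariable screens with FDR
# correction, the two multivariable models (penalized-spline or categorical
# IFN term), and complementary log-log proportional-hazards diagnostics.

.cox_data <- function(outcomes, covariates = NULL) {
  df <- data.frame(subject_id = outcomes$subject_id,
                   time = outcomes$ttcw_months,
                   status = as.integer(!outcomes$censored),
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    df <- merge(df, covariates, by = "subject_id", sort = FALSE)
  }
  df
}

#' Fit a Cox proportional-hazards model
#'
#' Partial-likelihood fit with Efron tie handling (visit-grid data generate
#' ties). An optional covariate enters as a penalized spline (natural-spline
#' basis, fixed degrees of freedom by default) whose summary is split into a
#' linear-component HR/CI/p and a nonlinear-component p. A monotone
#' likelihood (all events in one group preceding the other) is surfaced as a
#' divergence warning with the capped coefficient retained.
#'
#' @param outcomes outcome table.
#' @param covariates data.frame keyed by `subject_id` holding the model
#'   terms.
#' @param terms character vector of linear term names.
#' @param smooth optional name of the covariate modelled as a penalized
#'   spline.
#' @param spline_df degrees of freedom for the spline (0 requests AIC-based
#'   selection as implemented by [survival::pspline()]).
#' @return Object of class `cox_fit`: `terms` table (term, coef, hr, lo, hi,
#'   se, p), `spline` (linear hr/lo/hi/p and nonlinear p, or NULL),
#'   `loglik`, `n`, `n_events`, `diverged`, and the underlying `model`.
#' @export
fit_cox <- function(outcomes, covariates, terms, smooth = NULL,
                    spline_df = 4) {
  df <- .cox_data(outcomes, covariates)
  if (sum(df$status) < 2L) {
    stop(errorCondition("at least 2 events are required",
                        class = c("ifnttcw_contract_error", "ifnttcw_error")))
  }
  for (tm in c(terms, smooth)) {
    v <- df[[tm]]
    if (is.null(v)) .stop_schema(sprintf("covariate %s not found", tm))
    if (is.logical(v)) df[[tm]] <- as.numeric(v)
    if (length(unique(df[[tm]])) == 1L) {
      if (length(c(terms, smooth)) > 1L) {
        stop(errorCondition(
          sprintf("constant covariate: %s", tm),
          class = c("ifnttcw_collinearity_error", "ifnttcw_error")))
      }
      # a single constant covariate carries no information: the partial
      # likelihood is flat, reported as the null coefficient
      return(structure(list(
        terms = data.frame(term = tm, coef = 0, hr = 1, se = NA_real_,
                           lo = NA_real_, hi = NA_real_, p = NA_real_,
                           stringsAsFactors = FALSE),
        spline = NULL, loglik = NULL, n = nrow(df),
        n_events = sum(df$status), diverged = FALSE, model = NULL),
        class = "cox_fit"))
    }
  }
  rhs <- terms
  if (!is.null(smooth)) {
    rhs <- c(rhs, sprintf("survival::pspline(%s, df = %s)", smooth,
                          spline_df))
  }
  if (length(rhs) == 0L) stop("no model terms given")
  form <- stats::as.formula(paste("survival::Surv(time, status) ~",
                                  paste(rhs, collapse = " + ")))
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(form, data = df, ties = "efron", x = TRUE),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # collinearity shows up as NA coefficients
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(errorCondition(
      sprintf("singular design; collinear term(s): %s",
              paste(bad, collapse = ", ")),
      class = c("ifnttcw_collinearity_error", "ifnttcw_error")))
  }
  # pspline stores its component-test helper with a global environment;
  # rebind it to the survival namespace so summary() works unattached
  if (!is.null(fit$printfun)) {
    fit$printfun <- lapply(fit$printfun, function(pf) {
      environment(pf) <- asNamespace("survival")
      pf
    })
  }
  sm <- summary(fit)
  co <- sm$coefficients
  zc <- stats::qnorm(0.975)
  spline <- NULL
  if (!is.null(smooth)) {
    # the smooth enters the formula last, so summary.coxph.penal reports its
    # linear and nonlinear components as the final two rows (rownames are
    # width-truncated and unreliable for matching)
    lin <- nrow(co) - 1L
    nonlin <- nrow(co)
    spline <- list(
      term = smooth,
      hr = exp(co[lin, "coef"]),
      lo = exp(co[lin, "coef"] - zc * co[lin, "se(coef)"]),
      hi = exp(co[lin, "coef"] + zc * co[lin, "se(coef)"]),
      p_linear = co[lin, "p"],
      p_nonlinear = co[nonlin, "p"])
    co <- co[-c(lin, nonlin), , drop = FALSE]
  }
  term_tab <- if (nrow(co) > 0L) {
    data.frame(term = rownames(co), coef = co[, "coef"],
               hr = exp(co[, "coef"]), se = co[, "se(coef)"],
               lo = exp(co[, "coef"] - zc * co[, "se(coef)"]),
               hi = exp(co[, "coef"] + zc * co[, "se(coef)"]),
               p = co[, ncol(co)], row.names = NULL,
               stringsAsFactors = FALSE)
  } else {
    data.frame(term = character(0), coef = numeric(0), hr = numeric(0),
               se = numeric(0), lo = numeric(0), hi = numeric(0),
               p = numeric(0))
  }
  if (diverged) {
    warning(warningCondition(
      "monotone likelihood: coefficient diverges and is reported capped",
      class = "ifnttcw_divergence_warning"))
  }
  structure(list(terms = term_tab, spline = spline,
                 loglik = fit$loglik, n = fit$n, n_events = fit$nevent,
                 diverged = diverged, model = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: %d subjects, %d events%s\n", x$n, x$n_events,
              if (x$diverged) " [diverged]" else ""))
  if (nrow(x$terms) > 0L) {
    print(cbind(x$terms[, c("term", "hr", "lo", "hi", "p")]), digits = 3)
  }
  if (!is.null(x$spline)) {
    cat(sprintf(
      "  %s (penalized spline): linear HR %.2f (%.2f-%.2f), p = %.3g; nonlinear p = %.3g\n",
      x$spline$term, x$spline$hr, x$spline$lo, x$spline$hi,
      x$spline$p_linear, x$spline$p_nonlinear))
  }
  invisible(x)
}

#' Univariable Cox screen with FDR correction
#'
#' One Cox model per covariate; Benjamini-Hochberg q-values over the
#' screen's p-values. A covariate named in `smooth` is modelled as a
#' penalized spline (its linear-component p enters the FDR correction, and
#' the nonlinear-component p is reported alongside). Per-covariate errors
#' are recorded without aborting the screen.
#'
#' @param outcomes outcome table.
#' @param covariates data.frame keyed by `subject_id`.
#' @param terms covariate names to screen.
#' @param smooth optional subset of `terms` to model as penalized splines.
#' @return data.frame: term, hr, lo, hi, p, p_nonlinear, q, note.
#' @export
univariable_screen <- function(outcomes, covariates, terms, smooth = NULL) {
  rows <- lapply(terms, function(tm) {
    res <- tryCatch({
      if (tm %in% smooth) {
        f <- suppressWarnings(fit_cox(outcomes, covariates, character(0),
                                      smooth = tm))
        data.frame(term = tm, hr = f$spline$hr, lo = f$spline$lo,
                   hi = f$spline$hi, p = f$spline$p_linear,
                   p_nonlinear = f$spline$p_nonlinear, note = "",
                   stringsAsFactors = FALSE)
      } else {
        f <- suppressWarnings(fit_cox(outcomes, covariates, tm))
        data.frame(term = tm, hr = f$terms$hr[1], lo = f$terms$lo[1],
                   hi = f$terms$hi[1], p = f$terms$p[1],
                   p_nonlinear = NA_real_,
                   note = if (f$diverged) "diverged" else "",
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      data.frame(term = tm, hr = NA_real_, lo = NA_real_, hi = NA_real_,
                 p = NA_real_, p_nonlinear = NA_real_,
                 note = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab
}

#' The two multivariable TTCW models
#'
#' Model 1: penalized-spline IFN score + ILD + PAH + mRSS + DU disease +
#' age. Model 2: categorical IFN class (high vs low) + the same clinical
#' covariates.
#'
#' @param outcomes outcome table.
#' @param baseline baseline table (supplies ild, pah, mrss, du_disease, age).
#' @param scores score table from [score_panels()] with `ifn_score` and
#'   `ifn_class`.
#' @param spline_df passed to [fit_cox()].
#' @return list with elements `model1` and `model2` (both `cox_fit`).
#' @export
multivariable_models <- function(outcomes, baseline, scores, spline_df = 4) {
  cov <- merge(baseline[, c("subject_id", "ild", "pah", "mrss",
                            "du_disease", "age")],
               scores, by = "subject_id")
  cov$ifn_high <- as.numeric(cov$ifn_class == "high")
  clinical <- c("ild", "pah", "mrss", "du_disease", "age")
  list(
    model1 = fit_cox(outcomes, cov, clinical, smooth = "ifn_score",
                     spline_df = spline_df),
    model2 = fit_cox(outcomes, cov, c("ifn_high", clinical)))
}

#' Complementary log-log proportional-hazards diagnostic
#'
#' Transforms each group's KM curve to `log(-log(S(t)))` (points with S = 0
#' or 1 are dropped). Under proportional hazards the curves are parallel: at
#' any common time the vertical offset is constant. The summary is the
#' maximum deviation of the per-time offsets from their mean, with a flag
#' when it exceeds `flag_threshold`.
#'
#' @param outcomes_a,outcomes_b outcome tables for the two groups.
#' @param flag_threshold offset-deviation threshold for the `non_parallel`
#'   flag (log(-log) scale), default 0.5.
#' @return list with `curves` (data.frame group/time/cloglog), `offsets`,
#'   `max_deviation`, `non_parallel`.
#' @export
ph_cloglog <- function(outcomes_a, outcomes_b, flag_threshold = 0.5) {
  cl <- function(outc, label) {
    st <- km_estimate(outc)$steps
    st <- st[st$n_event > 0 & st$surv > 0 & st$surv < 1, , drop = FALSE]
    if (nrow(st) == 0L) {
      stop(errorCondition("each group needs at least one event",
                          class = c("ifnttcw_contract_error",
                                    "ifnttcw_error")))
    }
    data.frame(group = label, time = st$time, surv = st$surv,
               cloglog = log(-log(st$surv)), stringsAsFactors = FALSE)
  }
  ca <- cl(outcomes_a, "A"); cb <- cl(outcomes_b, "B")
  lookup <- function(tab, t, col) {
    idx <- which(tab$time <= t)
    if (length(idx) == 0L) NA_real_ else tab[[col]][max(idx)]
  }
  # parallelism is judged where both curves are well estimated
  # (S within [0.1, 0.9]); the cloglog transform is unstable in the tails
  times <- sort(unique(c(ca$time, cb$time)))
  times <- times[times >= max(min(ca$time), min(cb$time))]
  stable <- vapply(times, function(t) {
    sa <- lookup(ca, t, "surv"); sb <- lookup(cb, t, "surv")
    !is.na(sa) && !is.na(sb) && min(sa, sb) >= 0.1 && max(sa, sb) <= 0.9
  }, logical(1))
  if (any(stable)) times <- times[stable]
  offs <- vapply(times, function(t) {
    lookup(ca, t, "cloglog") - lookup(cb, t, "cloglog")
  }, numeric(1))
  offs <- offs[is.finite(offs)]
  dev <- if (length(offs) > 0L) max(abs(offs - mean(offs))) else NA_real_
  list(curves = rbind(ca, cb),
       offsets = offs,
       max_deviation = dev,
       non_parallel = isTRUE(dev > flag_threshold))
}
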
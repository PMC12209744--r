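# Shared fixtures and independent brute-force oracles.

# outcome table from parallel time/censoring vectors
toy_outcomes <- function(times, censored, ids = NULL) {
  n <- length(times)
  data.frame(subject_id = ids %||% sprintf("S%03d", seq_len(n)),
             event = ifelse(censored, "none", "pah"),
             ttcw_months = times, censored = censored,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# one-subject visit stream with optional measurements and flags
toy_visits <- function(id, t, fvc = NA_real_, dlco = NA_real_,
                       mrss = NA_integer_, flags = list()) {
  k <- length(t)
  vis <- data.frame(subject_id = rep(id, k), t = t,
                    fvc_pct = rep_len(fvc, k), dlco_pct = rep_len(dlco, k),
                    mrss = rep_len(mrss, k), stringsAsFactors = FALSE)
  for (fl in visit_flag_cols) vis[[fl]] <- rep(FALSE, k)
  for (fl in names(flags)) {
    stopifnot(fl %in% visit_flag_cols)
    vis[[fl]][flags[[fl]]] <- TRUE
  }
  vis
}

toy_baseline_row <- function(id, mrss = 0L, pah = FALSE, ild = FALSE,
                             du = FALSE) {
  df <- data.frame(subject_id = id, age = 60, sex = "female",
                   disease_duration = 8, stringsAsFactors = FALSE)
  for (col in c("ana", "aca", "scl70", "ro52", "rnapol3", "u1rnp",
                "calcinosis", "upper_gi", "sjogren_overlap", "mmf", "era",
                "pde5i", "iloprost", "ccb", "hcq", "aspirin", "ace")) {
    df[[col]] <- FALSE
  }
  df$ild <- ild; df$pah <- pah; df$du_disease <- du
  df$mrss <- mrss; df$fvc_pct <- 100; df$dlco_pct <- 70
  df
}

# --- independent oracles --------------------------------------------------

# product-limit estimate and Greenwood variance by direct recursion
km_oracle <- function(times, status) {
  ut <- sort(unique(times[status == 1]))
  s <- 1
  gsum <- 0
  out <- data.frame(time = ut, surv = NA_real_, var = NA_real_)
  for (i in seq_along(ut)) {
    t <- ut[i]
    n <- sum(times >= t)
    d <- sum(times == t & status == 1)
    s <- s * (1 - d / n)
    gsum <- gsum + d / (n * (n - d))
    out$surv[i] <- s
    out$var[i] <- s^2 * gsum
  }
  out
}

# two-group log-rank statistic by direct O-E / V summation over risk sets
logrank_oracle <- function(times, status, group) {
  ut <- sort(unique(times[status == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ut) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(times == t & status == 1)
    d1 <- sum(times == t & status == 1 & group == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Cox partial log-likelihood (Breslow form; exact for untied data)
cox_loglik_oracle <- function(beta, times, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
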
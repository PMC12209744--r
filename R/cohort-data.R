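#' @keywords internal
#' @import survival
"_PACKAGE"

#' Chemokine analytes in the type I IFN score
#'
#' Column names of the six serum chemokines (pg/mL) entering the IFN score.
#' @export
ifn_chemokines <- c("ccl2", "ccl8", "ccl19", "cxcl9", "cxcl10", "cxcl11")

# column schemas -----------------------------------------------------------

.autoantibody_cols <- c("ana", "aca", "scl70", "ro52", "rnapol3", "u1rnp")
.organ_cols <- c("ild", "pah", "du_disease", "calcinosis", "upper_gi",
                 "sjogren_overlap")
.treatment_cols <- c("mmf", "era", "pde5i", "iloprost", "ccb", "hcq",
                     "aspirin", "ace")

.baseline_cols <- c("subject_id", "age", "sex", "disease_duration",
                    .autoantibody_cols, .organ_cols,
                    "mrss", "fvc_pct", "dlco_pct", .treatment_cols)

#' Visit-level event flags
#'
#' Boolean visit columns that can trigger a flag-type Morbi-mortality event
#' (or, for `nonssc_death`, censoring).
#' @export
visit_flag_cols <- c("new_pah_rhc", "renal_crisis", "cardiac_ef_lt45",
                     "pericardial_effusion_impairing", "arrhythmia_treated",
                     "cardiac_device", "enteral_nutrition_3wk",
                     "parenteral_feeding", "gi_obstruction_admission",
                     "digital_vasculopathy_admission", "ssc_death",
                     "nonssc_death")

.visit_cols <- c("subject_id", "t", "fvc_pct", "dlco_pct", "mrss",
                 visit_flag_cols)

.panel_cols <- c("subject_id", ifn_chemokines, "sample_months_from_baseline")

.outcome_cols <- c("subject_id", "event", "ttcw_months", "censored")

#' Morbi-mortality event types
#'
#' Valid values of the `event` column of an adjudicated outcome table, ordered
#' by the severity convention used to break exact ties in event time.
#' @export
event_types <- c("ssc_death", "pah", "ild_progression", "cardiac",
                 "renal_crisis", "gi", "digital_vasculopathy",
                 "skin_worsening", "none")

.stop_schema <- function(msg) {
  stop(errorCondition(msg, class = c("ifnttcw_schema_error", "ifnttcw_error")))
}
.stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("ifnttcw_validation_error", "ifnttcw_error")))
}

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    .stop_schema(sprintf("%s table is missing column(s): %s",
                         what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# validators ---------------------------------------------------------------

#' Validate a chemokine panel table
#'
#' One row per serum sample: `subject_id`, the six chemokine concentrations in
#' pg/mL (strictly positive), and `sample_months_from_baseline` (0 for the
#' index sample).
#'
#' @param panels data.frame of panels.
#' @return The validated data.frame, invisibly classed.
#' @export
validate_panels <- function(panels) {
  .check_columns(panels, .panel_cols, "panel")
  if (any(!nzchar(as.character(panels$subject_id)))) {
    .stop_validation("panel table contains an empty subject_id")
  }
  for (chem in ifn_chemokines) {
    v <- panels[[chem]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0L) {
      .stop_validation(sprintf(
        "non-positive or missing %s concentration at row %d", chem, bad[1L]))
    }
  }
  invisible(panels)
}

#' Validate a baseline table
#'
#' @param baseline data.frame with one row per subject.
#' @return The validated data.frame, invisibly.
#' @export
validate_baseline <- function(baseline) {
  .check_columns(baseline, .baseline_cols, "baseline")
  if (anyDuplicated(baseline$subject_id)) {
    .stop_validation("duplicate subject_id in baseline table")
  }
  if (!all(baseline$sex %in% c("female", "male"))) {
    .stop_validation("sex must be 'female' or 'male'")
  }
  bad <- which(baseline$mrss < 0 | baseline$mrss > 51)
  if (length(bad) > 0L) {
    .stop_validation(sprintf("mrss outside [0, 51] at row %d", bad[1L]))
  }
  for (col in c("fvc_pct", "dlco_pct")) {
    v <- baseline[[col]]
    bad <- which(!is.finite(v) | v <= 0 | v >= 200)
    if (length(bad) > 0L) {
      .stop_validation(sprintf("%s outside (0, 200) at row %d", col, bad[1L]))
    }
  }
  invisible(baseline)
}

#' Validate a longitudinal visit table
#'
#' Visit times are months since the serum-sample baseline; FVC%, DLco% and
#' mRSS may be missing at any visit. At most one death flag may be set per
#' subject and it must terminate the visit stream.
#'
#' @param visits data.frame of visits.
#' @param baseline optional baseline table for referential checking.
#' @return The validated data.frame sorted by (subject_id, t), invisibly.
#' @export
validate_visits <- function(visits, baseline = NULL) {
  .check_columns(visits, .visit_cols, "visit")
  if (any(visits$t < 0, na.rm = TRUE)) {
    .stop_validation("visit time t must be >= 0")
  }
  if (!is.null(baseline)) {
    unknown <- setdiff(unique(visits$subject_id), baseline$subject_id)
    if (length(unknown) > 0L) {
      .stop_validation(sprintf("visit for unknown subject: %s", unknown[1L]))
    }
  }
  visits <- visits[order(visits$subject_id, visits$t), , drop = FALSE]
  death <- visits$ssc_death | visits$nonssc_death
  for (id in unique(visits$subject_id[death])) {
    sub <- visits[visits$subject_id == id, , drop = FALSE]
    dd <- which(sub$ssc_death | sub$nonssc_death)
    if (sum(sub$ssc_death & sub$nonssc_death) > 0 || length(dd) > 1L) {
      .stop_validation(sprintf("subject %s has more than one death flag", id))
    }
    if (dd < nrow(sub)) {
      .stop_validation(sprintf("subject %s has visits after a death flag", id))
    }
  }
  invisible(visits)
}

#' Validate an adjudicated outcome table
#'
#' @param outcomes data.frame with `subject_id`, `event`, `ttcw_months`,
#'   `censored`.
#' @return The validated data.frame, invisibly.
#' @export
validate_outcomes <- function(outcomes) {
  .check_columns(outcomes, .outcome_cols, "outcome")
  if (!all(outcomes$event %in% event_types)) {
    .stop_validation("unknown event type in outcome table")
  }
  if (!all(outcomes$censored == (outcomes$event == "none"))) {
    .stop_validation("censored must be TRUE exactly when event is 'none'")
  }
  if (any(outcomes$ttcw_months > 120)) {
    .stop_validation("ttcw_months exceeds the 120-month horizon")
  }
  invisible(outcomes)
}

# io -----------------------------------------------------------------------

.bool_cols <- list(
  baseline = c(.autoantibody_cols, .organ_cols, .treatment_cols),
  visits = visit_flag_cols,
  outcomes = "censored"
)

.read_table <- function(path, what) {
  if (!file.exists(path)) {
    .stop_schema(sprintf("%s file not found: %s", what, path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  for (col in .bool_cols[[what]] %||% character(0)) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort bundle from delimited text tables
#'
#' Reads comma-separated tables (header row, `.` decimal, booleans as 0/1)
#' and returns a validated cohort bundle. Visits are sorted by
#' (subject_id, t) and checked referentially against the baseline table.
#'
#' @param dir directory containing the tables, or `NULL` when explicit paths
#'   are given.
#' @param controls,baseline,panels,visits,outcomes file paths overriding the
#'   default `<dir>/<name>.csv`; `panels` and `outcomes` are optional and
#'   silently skipped when the file does not exist.
#' @return An object of class `ssc_cohort`: a list with elements `controls`,
#'   `baseline`, `panels`, `visits`, `outcomes` (the latter two possibly
#'   `NULL`).
#' @export
read_cohort <- function(dir = NULL,
                        controls = file.path(dir, "controls.csv"),
                        baseline = file.path(dir, "baseline.csv"),
                        panels = file.path(dir, "panels.csv"),
                        visits = file.path(dir, "visits.csv"),
                        outcomes = file.path(dir, "outcomes.csv")) {
  ctl <- validate_panels(.read_table(controls, "controls"))
  base <- validate_baseline(.read_table(baseline, "baseline"))
  pan <- if (file.exists(panels)) validate_panels(.read_table(panels, "panels"))
  vis <- validate_visits(.read_table(visits, "visits"), base)
  out <- if (file.exists(outcomes)) {
    validate_outcomes(.read_table(outcomes, "outcomes"))
  }
  structure(list(controls = ctl, baseline = base, panels = pan,
                 visits = vis, outcomes = out),
            class = "ssc_cohort")
}

.write_table <- function(df, path, what) {
  for (col in .bool_cols[[what]] %||% character(0)) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
}

#' Write a cohort bundle to delimited text tables
#'
#' Lossless inverse of [read_cohort()]: stable column order, booleans as 0/1,
#' UTF-8 subject identifiers preserved.
#'
#' @param cohort an `ssc_cohort` bundle.
#' @param dir output directory (created if needed).
#' @return The vector of files written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ssc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  tabs <- list(controls = "controls", baseline = "baseline",
               panels = "panels", visits = "visits", outcomes = "outcomes")
  whats <- c(controls = "controls", baseline = "baseline", panels = "panels",
             visits = "visits", outcomes = "outcomes")
  for (nm in names(tabs)) {
    df <- cohort[[nm]]
    if (is.null(df)) next
    path <- file.path(dir, paste0(nm, ".csv"))
    what <- switch(nm, baseline = "baseline", visits = "visits",
                   outcomes = "outcomes", "panel")
    .write_table(df, path, what)
    written <- c(written, path)
  }
  invisible(written)
}

#' @export
print.ssc_cohort <- function(x, ...) {
  cat("ssc_cohort bundle\n")
  cat(sprintf("  controls: %d panels\n", nrow(x$controls)))
  cat(sprintf("  patients: %d baseline records", nrow(x$baseline)))
  if (!is.null(x$panels)) cat(sprintf(", %d panels", nrow(x$panels)))
  cat("\n")
  cat(sprintf("  visits:   %d rows, %d subjects\n",
              nrow(x$visits), length(unique(x$visits$subject_id))))
  if (!is.null(x$outcomes)) {
    cat(sprintf("  outcomes: %d (%d events)\n",
                nrow(x$outcomes), sum(!x$outcomes$censored)))
  }
  invisible(x)
}
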
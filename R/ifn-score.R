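# Type I IFN score: mean natural-log serum concentration of six
# IFN-inducible chemokines, thresholded at healthy-control mean + 2 SD.

#' Compute the six-chemokine type I IFN score
#'
#' The score is the average of the natural logarithm of the serum
#' concentrations (pg/mL) of CCL2, CCL8, CCL19, CXCL9, CXCL10 and CXCL11.
#' It is invariant to analyte ordering and scale-equivariant:
#' multiplying every concentration by `c` adds `log(c)` to the score.
#'
#' @param panel a named numeric vector containing the six chemokines, or a
#'   data.frame of panels with the chemokine columns (one score per row).
#' @return Numeric score(s), dimensionless (mean ln pg/mL).
#' @examples
#' compute_ifn_score(c(ccl2 = exp(5), ccl8 = exp(5), ccl19 = exp(5),
#'                     cxcl9 = exp(5), cxcl10 = exp(5), cxcl11 = exp(5)))
#' @export
compute_ifn_score <- function(panel) {
  if (is.data.frame(panel)) {
    missing <- setdiff(ifn_chemokines, names(panel))
    if (length(missing) > 0L) {
      .stop_validation(sprintf("panel is missing analyte(s): %s",
                               paste(missing, collapse = ", ")))
    }
    mat <- as.matrix(panel[, ifn_chemokines, drop = FALSE])
  } else {
    missing <- setdiff(ifn_chemokines, names(panel))
    if (length(missing) > 0L) {
      .stop_validation(sprintf("panel is missing analyte(s): %s",
                               paste(missing, collapse = ", ")))
    }
    mat <- matrix(panel[ifn_chemokines], nrow = 1,
                  dimnames = list(NULL, ifn_chemokines))
  }
  for (chem in ifn_chemokines) {
    v <- mat[, chem]
    if (any(!is.finite(v) | v <= 0)) {
      .stop_validation(sprintf(
        "non-positive or missing concentration for analyte %s", chem))
    }
  }
  rowMeans(log(mat))
}

#' Score a table of panels
#'
#' @param panels a validated panel data.frame (see [validate_panels()]).
#' @param model optional [derive_threshold()] model; when supplied, an
#'   `ifn_class` column ("high"/"low") is added.
#' @return data.frame with `subject_id`, `ifn_score` and, with a model,
#'   `ifn_class`.
#' @export
score_panels <- function(panels, model = NULL) {
  res <- data.frame(subject_id = panels$subject_id,
                    ifn_score = compute_ifn_score(panels),
                    stringsAsFactors = FALSE)
  if (!is.null(model)) {
    res$ifn_class <- classify_ifn(res$ifn_score, model)
  }
  res
}

#' Derive the healthy-control IFN threshold
#'
#' Threshold for a "high" IFN score: mean of the healthy-control scores plus
#' two sample standard deviations (n - 1 denominator).
#'
#' @param hc_scores numeric vector of control IFN scores (length >= 2).
#' @return An object of class `threshold_model` with `hc_mean`, `hc_sd`,
#'   `threshold` and `n_controls`.
#' @examples
#' derive_threshold(c(4, 5, 6)) # mean 5, SD 1, threshold 7
#' @export
derive_threshold <- function(hc_scores) {
  hc_scores <- hc_scores[is.finite(hc_scores)]
  if (length(hc_scores) < 2L) {
    stop(errorCondition("at least 2 control scores are required",
                        class = c("ifnttcw_reference_error", "ifnttcw_error")))
  }
  m <- mean(hc_scores)
  s <- stats::sd(hc_scores)
  if (s == 0) {
    warning("control scores have zero variance; threshold equals the mean")
  }
  structure(list(hc_mean = m, hc_sd = s, threshold = m + 2 * s,
                 n_controls = length(hc_scores)),
            class = "threshold_model")
}

#' Classify IFN scores against a threshold model
#'
#' "High" means strictly above the threshold; a score exactly equal to the
#' threshold is "low" (the score is continuous, so ties are measure-zero).
#'
#' @param score numeric score(s).
#' @param model a `threshold_model`.
#' @return Character vector, "high" or "low".
#' @export
classify_ifn <- function(score, model) {
  stopifnot(inherits(model, "threshold_model"), all(is.finite(score)))
  ifelse(score > model$threshold, "high", "low")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(
    "IFN threshold model: mean %.3f + 2 x SD %.3f = %.3f (n = %d controls)\n",
    x$hc_mean, x$hc_sd, x$threshold, x$n_controls))
  invisible(x)
}
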
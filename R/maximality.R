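#' Criteria defining a maximal-effort test
#'
#' A test is accepted as maximal when at least `required_count` of five
#' criteria hold: (1) peak RER at or above `rer_threshold`; (2) a VO2
#' plateau despite increasing workload (externally judged flag);
#' (3) volitional fatigue seen as a cadence fall (externally judged flag);
#' (4) peak heart rate within `hr_tolerance` beats of the age-predicted
#' maximum `hrmax_coef[1] - hrmax_coef[2] * age`; (5) peak RPE at or above
#' `rpe_threshold`.
#'
#' @param rer_threshold minimum peak respiratory exchange ratio.
#' @param hr_tolerance allowed shortfall from predicted HRmax, beats/min.
#' @param hrmax_coef intercept and age slope of the predicted-HRmax formula.
#' @param rpe_threshold minimum peak Borg rating.
#' @param required_count how many of the five criteria must hold (<= 5).
#' @return A list of class `maximality_criteria`.
#' @export
maximality_criteria <- function(rer_threshold = 1.10, hr_tolerance = 10,
                                hrmax_coef = c(207, 0.67),
                                rpe_threshold = 19, required_count = 4) {
  if (required_count > 5) stop("required_count must be <= 5", call. = FALSE)
  structure(list(rer_threshold = rer_threshold, hr_tolerance = hr_tolerance,
                 hrmax_coef = hrmax_coef, rpe_threshold = rpe_threshold,
                 required_count = required_count),
            class = "maximality_criteria")
}

#' Age-predicted maximal heart rate
#'
#' @param age age in years.
#' @param coef intercept and age slope; the default gives `207 - 0.67 * age`.
#' @return Predicted HRmax in beats/min.
#' @examples
#' predicted_hrmax(40)  # 180.2
#' @export
predicted_hrmax <- function(age, coef = c(207, 0.67)) {
  coef[1] - coef[2] * age
}

#' Judge whether a test was maximal
#'
#' Evaluates the five maximal-effort criteria against the series. Criteria
#' whose data are unavailable (no HR channel, no RPE, no age) simply count
#' as not met; missing data never abort the check.
#'
#' @param x a `cpet_series`.
#' @param criteria a [maximality_criteria()].
#' @param plateau was a VO2 plateau observed (externally judged)?
#' @param rpm_fall was a cadence fall of 10 rpm observed?
#' @param age subject age in years; defaults to the series'
#'   `subject_age` attribute.
#' @return A list of class `maximality_verdict` with the per-criterion
#'   logicals, the count met, and the overall verdict.
#' @export
check_maximality <- function(x, criteria = maximality_criteria(),
                             plateau = FALSE, rpm_fall = FALSE, age = NULL) {
  stopifnot(inherits(x, "cpet_series"),
            inherits(criteria, "maximality_criteria"))
  if (is.null(age)) age <- attr(x, "subject_age")
  peak_of <- function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  hrmax <- if (is.null(age)) NA_real_ else predicted_hrmax(age, criteria$hrmax_coef)
  met <- c(
    rer = isTRUE(peak_of(x$rer) >= criteria$rer_threshold),
    plateau = isTRUE(plateau),
    rpm_fall = isTRUE(rpm_fall),
    hr = isTRUE(peak_of(x$hr) >= hrmax - criteria$hr_tolerance),
    rpe = isTRUE(peak_of(x$rpe) >= criteria$rpe_threshold)
  )
  structure(list(criteria_met = met, n_met = sum(met),
                 required = criteria$required_count,
                 maximal = sum(met) >= criteria$required_count,
                 predicted_hrmax = hrmax),
            class = "maximality_verdict")
}

#' @export
print.maximality_verdict <- function(x, ...) {
  cat(sprintf("Maximal effort: %s (%d/5 criteria met, %d required)\n",
              if (x$maximal) "yes" else "no", x$n_met, x$required))
  cat("  ", paste(sprintf("%s=%s", names(x$criteria_met),
                          ifelse(x$criteria_met, "yes", "no")),
                  collapse = " "), "\n")
  if (!is.na(x$predicted_hrmax)) {
    cat(sprintf("  predicted HRmax: %.1f beat/min\n", x$predicted_hrmax))
  }
  invisible(x)
}
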
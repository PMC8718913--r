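# Orchestration: warm-up exclusion -> derived signals -> trimming ->
# changepoint per method -> average the two method times per threshold ->
# read every channel at the combined instant.

.vt_windows <- list(vt1 = c(0.30, 0.80), vt2 = c(0.50, 1.00))

new_vt_estimate <- function(threshold, method, time, index, series_row,
                            body_mass, indeterminate, methods = NULL) {
  vo2_abs <- series_row$vo2
  structure(list(
    threshold = threshold, method = method, time = time, index = index,
    vo2_abs = vo2_abs,
    vo2_rel = if (is.null(body_mass)) NA_real_ else 1000 * vo2_abs / body_mass,
    work = series_row$work, hr = series_row$hr, rer = series_row$rer,
    ve = series_row$ve, indeterminate = indeterminate, methods = methods),
    class = "vt_estimate")
}

#' @export
print.vt_estimate <- function(x, ...) {
  cat(sprintf("%s (%s): t = %g s, VO2 %.2f L/min, %s W, VE %.1f L/min%s\n",
              toupper(x$threshold), x$method, x$time, x$vo2_abs,
              if (is.na(x$work)) "?" else sprintf("%.1f", x$work), x$ve,
              if (x$indeterminate) " [indeterminate]" else ""))
  invisible(x)
}

.detect_threshold <- function(x, protocol, threshold, body_mass = NULL,
                              min_time = 240, min_seg = 3) {
  stopifnot(inherits(x, "cpet_series"), inherits(protocol, "cpet_protocol"))
  post <- exclude_warmup(x, protocol)
  if (nrow(post) < 12) {
    stop("threshold detection needs at least 12 post-warm-up samples, got ",
         nrow(post), call. = FALSE)
  }
  if (all(is.na(post$work))) post$work <- work_rate_at_time(post$time, protocol)
  sigs <- if (threshold == "vt1") {
    list(excess_co2(post), vslope_signal(post, "vt1"))
  } else {
    list(excess_ve(post), vslope_signal(post, "vt2"))
  }
  win <- .vt_windows[[threshold]]
  dt <- if (nrow(post) > 1) post$time[2] - post$time[1] else 10

  sub <- lapply(sigs, function(sig) {
    tr <- trim_signal(sig$values, win[1], win[2], min_seg = min_seg)
    cp <- single_changepoint_std(tr$values, min_seg = min_seg,
                                 offset = tr$window$lo_index - 1L)
    idx <- cp$global_index
    method <- sub("_vt[12]$", "", sig$name)
    if (method %in% c("vslope_vt1", "vslope_vt2")) method <- "vslope"
    est <- new_vt_estimate(threshold, method, post$time[idx], idx,
                           post[idx, ], body_mass,
                           indeterminate = !cp$significant)
    est$changepoint <- cp
    est
  })
  names(sub) <- vapply(sub, `[[`, "", "method")

  mean_time <- mean(vapply(sub, `[[`, 0, "time"))
  # snap to the sample grid, half-way cases rounding up to the later sample
  idx <- as.integer(floor((mean_time - post$time[1]) / dt + 0.5)) + 1L
  idx <- min(max(idx, 1L), nrow(post))
  indet <- any(vapply(sub, `[[`, TRUE, "indeterminate")) ||
    post$time[idx] <= min_time
  new_vt_estimate(threshold, "combined", post$time[idx], idx, post[idx, ],
                  body_mass, indeterminate = indet, methods = sub)
}

#' Detect the first ventilatory threshold
#'
#' Runs the single-changepoint search on the excess-CO2 signal and the
#' V-slope (VCO2) signal, both trimmed to the 30th-80th percentile of the
#' post-warm-up samples, and averages the two method times; all channel
#' values are then read at that one instant (averaging channel values from
#' two different instants would yield a physiologically inconsistent
#' tuple). The estimate is flagged indeterminate when either sub-detection
#' is non-significant or when the combined time falls at or before
#' `min_time` (the quality-control rule that a threshold during or right
#' after the warm-up stage is not credible).
#'
#' @param x a `cpet_series` (full test, warm-up included).
#' @param protocol the [cpet_protocol()] of the test.
#' @param body_mass body mass in kg, for relative VO2 (optional).
#' @param min_time earliest credible threshold time in seconds.
#' @param min_seg minimum changepoint segment length.
#' @return A `vt_estimate` with `method = "combined"` and the per-method
#'   sub-estimates in `$methods`.
#' @examples
#' sim <- simulate_test(sim_params(seed = 1))
#' detect_vt1(sim$series, sim$params$protocol, body_mass = 76.8)
#' @export
detect_vt1 <- function(x, protocol, body_mass = NULL, min_time = 240,
                       min_seg = 3) {
  .detect_threshold(x, protocol, "vt1", body_mass, min_time, min_seg)
}

#' Detect the respiratory compensation point
#'
#' As [detect_vt1()], but on the excess-ventilation and V-slope (VE)
#' signals trimmed to the 50th-100th percentile of the post-warm-up
#' samples.
#'
#' @inheritParams detect_vt1
#' @return A `vt_estimate` with `method = "combined"`.
#' @export
detect_vt2 <- function(x, protocol, body_mass = NULL, min_time = 240,
                       min_seg = 3) {
  .detect_threshold(x, protocol, "vt2", body_mass, min_time, min_seg)
}

#' Peak values of a test
#'
#' Peak VO2 is the maximum `window`-sample rolling mean (30 s by default at
#' 10-s sampling) of the VO2 channel; peak work, HR, VE and RER are the
#' maxima of the same-windowed channels. Channels that are entirely absent
#' yield `NA`.
#'
#' @param x a `cpet_series`.
#' @param body_mass body mass in kg for relative VO2 (optional).
#' @param window rolling-mean length in samples (default 3 = 30 s).
#' @return A list of class `cpet_peaks` with `vo2_abs`, `vo2_rel`, `work`,
#'   `hr`, `rer`, `ve`.
#' @export
peak_values <- function(x, body_mass = NULL, window = 3) {
  stopifnot(inherits(x, "cpet_series"))
  if (nrow(x) < window) {
    stop("need at least ", window, " samples for the peak rolling mean",
         call. = FALSE)
  }
  pk <- function(v) {
    if (all(is.na(v))) return(NA_real_)
    r <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 1))
    max(r, na.rm = TRUE)
  }
  vo2_abs <- pk(x$vo2)
  structure(list(
    vo2_abs = vo2_abs,
    vo2_rel = if (is.null(body_mass)) NA_real_ else 1000 * vo2_abs / body_mass,
    work = pk(x$work), hr = pk(x$hr), rer = pk(x$rer), ve = pk(x$ve),
    window = window), class = "cpet_peaks")
}

#' Threshold intensities relative to peak
#'
#' Expresses the VO2 and work rate at each threshold as a percentage of the
#' peak values, e.g. `100 * vo2(VT1) / peak VO2`.
#'
#' @param report a `vt_report` from [detect_thresholds()] (or any list with
#'   determinate `vt1`, `vt2` and `peaks` entries).
#' @return A named numeric vector: `pct_peak_vo2_at_vt1`,
#'   `pct_peak_vo2_at_vt2`, `pct_peak_w_at_vt1`, `pct_peak_w_at_vt2`.
#' @export
relative_intensity <- function(report) {
  vt1 <- report$vt1
  vt2 <- report$vt2
  pk <- report$peaks
  if (vt1$indeterminate || vt2$indeterminate) {
    stop("relative intensities need determinate thresholds", call. = FALSE)
  }
  if (!isTRUE(pk$vo2_abs > 0)) stop("peak VO2 absent or zero", call. = FALSE)
  out <- c(pct_peak_vo2_at_vt1 = 100 * vt1$vo2_abs / pk$vo2_abs,
           pct_peak_vo2_at_vt2 = 100 * vt2$vo2_abs / pk$vo2_abs,
           pct_peak_w_at_vt1 = NA_real_, pct_peak_w_at_vt2 = NA_real_)
  if (isTRUE(pk$work > 0)) {
    out["pct_peak_w_at_vt1"] <- 100 * vt1$work / pk$work
    out["pct_peak_w_at_vt2"] <- 100 * vt2$work / pk$work
  }
  out
}

#' Full automated threshold report for one test
#'
#' Convenience wrapper running [detect_vt1()], [detect_vt2()] and
#' [peak_values()], computing relative intensities when both thresholds are
#' determinate, and optionally judging maximal effort.
#'
#' @inheritParams detect_vt1
#' @param maximality optional list with entries `plateau` and `rpm_fall`
#'   (externally judged flags); when given, [check_maximality()] is run.
#' @return A list of class `vt_report`: `vt1`, `vt2`, `peaks`,
#'   `relative_intensity`, `ordering_violated`, `maximality`.
#' @examples
#' sim <- simulate_test(sim_params(seed = 1))
#' detect_thresholds(sim$series, sim$params$protocol, body_mass = 76.8)
#' @export
detect_thresholds <- function(x, protocol, body_mass = NULL, min_time = 240,
                              min_seg = 3, maximality = NULL) {
  vt1 <- detect_vt1(x, protocol, body_mass, min_time, min_seg)
  vt2 <- detect_vt2(x, protocol, body_mass, min_time, min_seg)
  peaks <- peak_values(x, body_mass)
  rep <- structure(list(vt1 = vt1, vt2 = vt2, peaks = peaks,
                        relative_intensity = NULL,
                        ordering_violated = FALSE, maximality = NULL),
                   class = "vt_report")
  if (!vt1$indeterminate && !vt2$indeterminate) {
    rep$relative_intensity <- relative_intensity(rep)
    rep$ordering_violated <- vt1$time >= vt2$time
  }
  if (!is.null(maximality)) {
    rep$maximality <- check_maximality(
      x, plateau = isTRUE(maximality$plateau),
      rpm_fall = isTRUE(maximality$rpm_fall))
  }
  rep
}

#' @export
print.vt_report <- function(x, ...) {
  cat("Automated ventilatory threshold report\n")
  print(x$vt1)
  print(x$vt2)
  cat(sprintf("  peak: VO2 %.2f L/min%s, %s W, VE %.1f L/min\n",
              x$peaks$vo2_abs,
              if (is.na(x$peaks$vo2_rel)) ""
              else sprintf(" (%.1f ml/kg/min)", x$peaks$vo2_rel),
              if (is.na(x$peaks$work)) "?" else sprintf("%.1f", x$peaks$work),
              x$peaks$ve))
  if (!is.null(x$relative_intensity)) {
    ri <- x$relative_intensity
    cat(sprintf("  VT1 at %.1f%% peak VO2 / %.1f%% peak W; VT2 at %.1f%% / %.1f%%\n",
                ri["pct_peak_vo2_at_vt1"], ri["pct_peak_w_at_vt1"],
                ri["pct_peak_vo2_at_vt2"], ri["pct_peak_w_at_vt2"]))
  }
  if (x$ordering_violated) cat("  WARNING: VT1 time >= VT2 time\n")
  if (!is.null(x$maximality)) print(x$maximality)
  invisible(x)
}

#' Serialize a threshold report to a JSON-ready list
#'
#' Numbers are rounded for reporting: one decimal for watts, two for
#' L/min quantities. Used by the command-line `detect` subcommand.
#'
#' @param report a `vt_report`.
#' @return A plain nested list mirroring the report.
#' @export
vt_report_list <- function(report) {
  stopifnot(inherits(report, "vt_report"))
  est <- function(e) list(
    threshold = e$threshold, method = e$method, time_s = e$time,
    vo2_abs_l_min = round(e$vo2_abs, 2),
    vo2_rel_ml_kg_min = if (is.na(e$vo2_rel)) NULL else round(e$vo2_rel, 1),
    work_w = if (is.na(e$work)) NULL else round(e$work, 1),
    hr_beat_min = if (is.na(e$hr)) NULL else round(e$hr, 0),
    rer = round(e$rer, 3), ve_l_min = round(e$ve, 1),
    indeterminate = e$indeterminate,
    methods = if (!is.null(e$methods)) lapply(e$methods, est))
  out <- list(vt1 = est(report$vt1), vt2 = est(report$vt2),
              peak = list(vo2_abs_l_min = round(report$peaks$vo2_abs, 2),
                          vo2_rel_ml_kg_min = if (is.na(report$peaks$vo2_rel))
                            NULL else round(report$peaks$vo2_rel, 1),
                          work_w = if (is.na(report$peaks$work)) NULL
                            else round(report$peaks$work, 1),
                          hr_beat_min = if (is.na(report$peaks$hr)) NULL
                            else round(report$peaks$hr, 0),
                          rer = round(report$peaks$rer, 3),
                          ve_l_min = round(report$peaks$ve, 1)),
              ordering_violated = report$ordering_violated)
  if (!is.null(report$relative_intensity)) {
    out$relative_intensity <- as.list(round(report$relative_intensity, 1))
  }
  out
}

#' Diagnostic plot of a detected test
#'
#' Two panels: the VT1 signals (excess CO2 and VCO2) and the VT2 signals
#' (excess VE and VE) against time, with the combined threshold times as
#' vertical lines.
#'
#' @param x a `cpet_series`.
#' @param report a `vt_report` for the same series.
#' @param protocol the test protocol (for warm-up exclusion).
#' @return Invisibly, `report`.
#' @export
plot_vt_detection <- function(x, report, protocol) {
  post <- exclude_warmup(x, protocol)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  panel <- function(sig, raw, raw_lab, vt, main) {
    graphics::plot(sig$time, sig$values, pch = 16, cex = 0.5,
                   xlab = "time (s)", ylab = sig$name, main = main)
    graphics::abline(v = vt$time, lty = 2,
                     col = if (vt$indeterminate) "grey50" else "red")
    graphics::par(new = TRUE)
    graphics::plot(post$time, raw, type = "l", col = "blue",
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = "blue")
    graphics::mtext(raw_lab, side = 4, line = 2, col = "blue", cex = 0.8)
  }
  panel(excess_co2(post), post$vco2, "VCO2 (L/min)", report$vt1, "VT1")
  panel(excess_ve(post), post$ve, "VE (L/min)", report$vt2, "VT2")
  invisible(report)
}
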
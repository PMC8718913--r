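# Synthetic incremental-test generator with planted thresholds.

#' Parameters of the synthetic test generator
#'
#' The generator emulates a progressive cycle test: VO2 follows the
#' protocol's work rate through a first-order on-kinetics response
#' (time constant `tau`), VCO2 is piecewise-linear in the metabolic VO2
#' drive with a slope break at `vt1_frac * peak_vo2` (the planted VT1),
#' and VE is piecewise-linear in noise-free VCO2 with a gain break at the
#' VCO2 value reached when the drive crosses `vt2_frac * peak_vo2` (the
#' planted VT2); both knots are continuous. Independent Gaussian noise is
#' added per channel. Measured VO2 is truncated at `peak_vo2`, while the
#' drive keeps rising during the final stage, so the test shows a VO2
#' plateau with RER still climbing through 1.0 -- the signature of a
#' maximal effort.
#'
#' Defaults place VT1 at 58\% and VT2 at 79\% of peak VO2, the
#' whole-cohort positions reported for incremental cycle tests, with
#' V-slope slopes below/above VT1 of 0.85/1.20 and ventilatory gains
#' below/above VT2 of 27/40 L VE per L VCO2.
#'
#' @param protocol a [cpet_protocol()].
#' @param peak_vo2 peak oxygen uptake, L/min.
#' @param vo2_rest resting VO2, L/min.
#' @param vo2_gain steady-state VO2 per watt, L/min/W.
#' @param tau on-kinetics time constant, s.
#' @param vt1_frac,vt2_frac planted thresholds as fractions of peak VO2
#'   (`0 < vt1_frac < vt2_frac < 1`).
#' @param slope_below_vt1,slope_above_vt1 VCO2-vs-VO2 slopes around VT1
#'   (must straddle 1).
#' @param ve_gain_below_vt2,ve_gain_above_vt2 VE-vs-VCO2 gains around VT2
#'   (increasing).
#' @param noise_sd_vo2,noise_sd_vco2,noise_sd_ve per-channel Gaussian
#'   noise SDs, L/min.
#' @param hr_rest,hr_slope heart-rate intercept (beat/min) and slope per
#'   watt; HR is capped at the age-predicted maximum.
#' @param age subject age, years.
#' @param mass body mass, kg.
#' @param seed default RNG seed used by [simulate_test()].
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(protocol = cpet_protocol("nominal"),
                       peak_vo2 = 3.3, vo2_rest = 0.5, vo2_gain = 0.010,
                       tau = 30, vt1_frac = 0.58, vt2_frac = 0.79,
                       slope_below_vt1 = 0.85, slope_above_vt1 = 1.20,
                       ve_gain_below_vt2 = 27, ve_gain_above_vt2 = 40,
                       noise_sd_vo2 = 0.05, noise_sd_vco2 = 0.05,
                       noise_sd_ve = 2.0, hr_rest = 70, hr_slope = 0.35,
                       age = 41, mass = 76.8, seed = NULL) {
  stopifnot(inherits(protocol, "cpet_protocol"))
  if (!(vt1_frac > 0 && vt1_frac < vt2_frac && vt2_frac < 1)) {
    stop("need 0 < vt1_frac < vt2_frac < 1", call. = FALSE)
  }
  if (!(slope_below_vt1 < 1 && slope_above_vt1 > 1)) {
    stop("V-slope slopes must straddle 1", call. = FALSE)
  }
  if (ve_gain_above_vt2 <= ve_gain_below_vt2) {
    stop("ventilatory gains must increase across VT2", call. = FALSE)
  }
  if (any(c(noise_sd_vo2, noise_sd_vco2, noise_sd_ve) < 0)) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  structure(list(protocol = protocol, peak_vo2 = peak_vo2,
                 vo2_rest = vo2_rest, vo2_gain = vo2_gain, tau = tau,
                 vt1_frac = vt1_frac, vt2_frac = vt2_frac,
                 slope_below_vt1 = slope_below_vt1,
                 slope_above_vt1 = slope_above_vt1,
                 ve_gain_below_vt2 = ve_gain_below_vt2,
                 ve_gain_above_vt2 = ve_gain_above_vt2,
                 noise_sd_vo2 = noise_sd_vo2, noise_sd_vco2 = noise_sd_vco2,
                 noise_sd_ve = noise_sd_ve, hr_rest = hr_rest,
                 hr_slope = hr_slope, age = age, mass = mass, seed = seed),
            class = "sim_params")
}

#' Simulate one incremental test with known thresholds
#'
#' See [sim_params()] for the generative model. The test ends one stage
#' after the noise-free VO2 drive reaches `peak_vo2`. Ground truth records
#' the grid times at which the drive crosses the VT1/VT2 knots. Identical
#' seeds give bit-identical output.
#'
#' @param params a [sim_params()].
#' @param seed RNG seed; defaults to `params$seed`. `NULL` leaves the RNG
#'   state alone.
#' @return A list with `series` (a [cpet_series()]), `truth` (class
#'   `cpet_truth`: `vt1_time`, `vt2_time`, `vt1_vo2`, `vt2_vo2`,
#'   `vt1_work`, `vt2_work`, `peak_reached`, `end_time`) and `params`.
#' @examples
#' sim <- simulate_test(sim_params(seed = 1))
#' sim$truth$vt1_time
#' @export
simulate_test <- function(params = sim_params(), seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params$protocol
  dt <- 10
  horizon <- 7200
  t <- seq(dt, horizon, by = dt)
  W <- work_rate_at_time(t, p)
  ss <- params$vo2_rest + params$vo2_gain * W
  a <- 1 - exp(-dt / params$tau)
  drive <- as.numeric(stats::filter(a * ss, 1 - a, method = "recursive",
                                    init = params$vo2_rest))
  i_peak <- which(drive >= params$peak_vo2)[1]
  if (is.na(i_peak)) {
    stop("parameters never reach peak_vo2 within the 2-h horizon",
         call. = FALSE)
  }
  end_time <- t[i_peak] + p$stage_duration
  keep <- t <= end_time
  t <- t[keep]
  W <- W[keep]
  drive <- drive[keep]
  vo2_nf <- pmin(drive, params$peak_vo2)

  k1 <- params$vt1_frac * params$peak_vo2
  k2_vo2 <- params$vt2_frac * params$peak_vo2
  vco2_nf <- ifelse(drive <= k1,
                    params$slope_below_vt1 * drive,
                    params$slope_below_vt1 * k1 +
                      params$slope_above_vt1 * (drive - k1))
  k2_vco2 <- params$slope_below_vt1 * k1 +
    params$slope_above_vt1 * (k2_vo2 - k1)
  ve_nf <- ifelse(vco2_nf <= k2_vco2,
                  params$ve_gain_below_vt2 * vco2_nf,
                  params$ve_gain_below_vt2 * k2_vco2 +
                    params$ve_gain_above_vt2 * (vco2_nf - k2_vco2))

  vt1_time <- t[which(drive >= k1)[1]]
  vt2_time <- t[which(drive >= k2_vo2)[1]]
  if (is.na(vt1_time) || is.na(vt2_time) || vt2_time >= end_time) {
    stop("planted thresholds fall beyond the test end", call. = FALSE)
  }

  n <- length(t)
  vo2 <- pmax(vo2_nf + stats::rnorm(n, 0, params$noise_sd_vo2), 0.01)
  vco2 <- pmax(vco2_nf + stats::rnorm(n, 0, params$noise_sd_vco2), 0.01)
  ve <- pmax(ve_nf + stats::rnorm(n, 0, params$noise_sd_ve), 0.1)
  hr <- pmin(params$hr_rest + params$hr_slope * W,
             predicted_hrmax(params$age))

  series <- cpet_series(time = t, vo2 = vo2, vco2 = vco2, ve = ve, hr = hr,
                        work = W, subject_age = params$age)
  truth <- structure(list(vt1_time = vt1_time, vt2_time = vt2_time,
                          vt1_vo2 = k1, vt2_vo2 = k2_vo2,
                          vt1_work = work_rate_at_time(vt1_time, p),
                          vt2_work = work_rate_at_time(vt2_time, p),
                          peak_reached = TRUE, end_time = end_time),
                     class = "cpet_truth")
  list(series = series, truth = truth, params = params)
}

#' Noise-free channels of a simulated test
#'
#' Returns the deterministic part of the generative model (no noise, same
#' end-of-test rule), useful for verifying the planted structure.
#'
#' @param params a [sim_params()].
#' @return As [simulate_test()] but with zero noise, plus a `drive` column
#'   (the untruncated metabolic VO2 drive) in `series`.
#' @export
simulate_noise_free <- function(params = sim_params()) {
  q <- params
  q$noise_sd_vo2 <- 0
  q$noise_sd_vco2 <- 0
  q$noise_sd_ve <- 0
  class(q) <- "sim_params"
  sim <- simulate_test(q, seed = NULL)
  p <- params$protocol
  ss <- params$vo2_rest + params$vo2_gain * sim$series$work
  a <- 1 - exp(-10 / params$tau)
  sim$series$drive <- as.numeric(stats::filter(a * ss, 1 - a,
                                               method = "recursive",
                                               init = params$vo2_rest))
  sim
}

#' Threshold-recovery experiment over seeded synthetic tests
#'
#' Simulates `n_tests` tests (each with its own reproducible seed derived
#' from `seed` and the test index), runs [detect_vt1()]/[detect_vt2()],
#' and summarises how often each combined estimate lands within
#' `tolerance_stages` stages of the planted truth, together with the
#' median and IQR absolute error in seconds and watts, the number of
#' indeterminate detections, and how often VT1 precedes VT2.
#'
#' @param params a [sim_params()] describing the simulated cohort.
#' @param n_tests number of tests.
#' @param tolerance_stages tolerance in protocol stages.
#' @param seed base seed for the batch.
#' @return A list of class `recovery_summary` with `per_test` (data frame)
#'   and per-threshold summaries `vt1`, `vt2`, plus `ordering_frac`.
#' @export
recovery_experiment <- function(params = sim_params(), n_tests = 100,
                                tolerance_stages = 1, seed = 1) {
  stopifnot(n_tests >= 1)
  p <- params$protocol
  tol_s <- tolerance_stages * p$stage_duration
  base <- as.integer(seed)
  rows <- vector("list", n_tests)
  for (i in seq_len(n_tests)) {
    seed_i <- (abs(base) %% 20000L) * 100000L + i
    sim <- simulate_test(params, seed = seed_i)
    r1 <- detect_vt1(sim$series, p, body_mass = params$mass)
    r2 <- detect_vt2(sim$series, p, body_mass = params$mass)
    rows[[i]] <- data.frame(
      test = i, seed = seed_i,
      vt1_true = sim$truth$vt1_time, vt1_det = r1$time,
      vt1_indet = r1$indeterminate,
      vt2_true = sim$truth$vt2_time, vt2_det = r2$time,
      vt2_indet = r2$indeterminate,
      vt1_err_w = abs(work_rate_at_time(r1$time, p) - sim$truth$vt1_work),
      vt2_err_w = abs(work_rate_at_time(r2$time, p) - sim$truth$vt2_work))
  }
  per <- do.call(rbind, rows)
  summarise <- function(det, true, indet, err_w) {
    ok <- !indet
    err <- abs(det - true)[ok]
    list(n_determinate = sum(ok), n_indeterminate = sum(indet),
         frac_within = if (any(ok)) mean(err <= tol_s) else NA_real_,
         median_abs_err_s = if (any(ok)) stats::median(err) else NA_real_,
         iqr_abs_err_s = if (any(ok)) stats::IQR(err) else NA_real_,
         median_abs_err_w = if (any(ok)) stats::median(err_w[ok]) else NA_real_,
         iqr_abs_err_w = if (any(ok)) stats::IQR(err_w[ok]) else NA_real_)
  }
  both <- !per$vt1_indet & !per$vt2_indet
  structure(list(
    per_test = per,
    vt1 = summarise(per$vt1_det, per$vt1_true, per$vt1_indet, per$vt1_err_w),
    vt2 = summarise(per$vt2_det, per$vt2_true, per$vt2_indet, per$vt2_err_w),
    ordering_frac = if (any(both)) {
      mean(per$vt1_det[both] < per$vt2_det[both])
    } else NA_real_,
    n_tests = n_tests, tolerance_s = tol_s),
    class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Recovery over %d synthetic tests (tolerance %g s):\n",
              x$n_tests, x$tolerance_s))
  line <- function(lab, s) {
    cat(sprintf("  %s: %.0f%% within tolerance, median |err| %.0f s / %.1f W (IQR %.0f s), %d indeterminate\n",
                lab, 100 * s$frac_within, s$median_abs_err_s,
                s$median_abs_err_w, s$iqr_abs_err_s, s$n_indeterminate))
  }
  line("VT1", x$vt1)
  line("VT2", x$vt2)
  cat(sprintf("  VT1 < VT2 in %.0f%% of determinate runs\n",
              100 * x$ordering_frac))
  invisible(x)
}
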
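# Detection signals derived from the gas-exchange channels.

new_derived_signal <- function(name, values, time, x = NULL, x_name = NULL) {
  structure(list(name = name, values = as.numeric(values),
                 time = as.numeric(time), x = x, x_name = x_name),
            class = "derived_signal")
}

#' @export
print.derived_signal <- function(x, ...) {
  cat(sprintf("derived signal '%s': %d samples", x$name, length(x$values)))
  if (!is.null(x$x_name)) cat(sprintf(" (x-variable: %s)", x$x_name))
  cat("\n")
  invisible(x)
}

#' Excess CO2 output
#'
#' `ExCO2 = VCO2^2 / VO2 - VCO2 = VCO2 * (RER - 1)`: negative while fat and
#' carbohydrate oxidation keep RER below 1, zero at RER = 1, and growing
#' once buffering of lactic acidosis adds non-metabolic CO2. Its inflection
#' marks VT1.
#'
#' @param x a `cpet_series` (normally already warm-up-excluded).
#' @return A `derived_signal` aligned with `x`.
#' @examples
#' s <- exclude_warmup(simulate_test(sim_params(seed = 1))$series,
#'                     cpet_protocol("nominal"))
#' excess_co2(s)
#' @export
excess_co2 <- function(x) {
  stopifnot(inherits(x, "cpet_series"))
  bad <- which(x$vo2 <= 0)
  if (length(bad)) stop("vo2 <= 0 at sample ", bad[1], call. = FALSE)
  new_derived_signal("exco2", x$vco2^2 / x$vo2 - x$vco2, x$time)
}

#' Excess ventilation
#'
#' `ExVE = VE^2 / VCO2 - VE = VE * (VE/VCO2 - 1)`: the ventilation analogue
#' of [excess_co2()]. Once respiratory compensation for metabolic acidosis
#' drives VE out of proportion to VCO2 the signal accelerates; its
#' inflection marks VT2.
#'
#' @inheritParams excess_co2
#' @return A `derived_signal` aligned with `x`.
#' @export
excess_ve <- function(x) {
  stopifnot(inherits(x, "cpet_series"))
  bad <- which(x$vco2 <= 0)
  if (length(bad)) stop("vco2 <= 0 at sample ", bad[1], call. = FALSE)
  new_derived_signal("exve", x$ve^2 / x$vco2 - x$ve, x$time)
}

#' V-slope input signals
#'
#' The V-slope method looks for the slope break in VCO2-vs-VO2 (VT1) or
#' VE-vs-VCO2 (VT2). Because work rate and VO2 rise monotonically during a
#' ramp, the y-variable in time order carries the same break, so the
#' changepoint detector consumes the plain `vco2` (VT1) or `ve` (VT2)
#' sequence; the paired x-variable is retained as metadata for plotting.
#'
#' @inheritParams excess_co2
#' @param which `"vt1"` (VCO2 vs VO2) or `"vt2"` (VE vs VCO2).
#' @return A `derived_signal` whose `values` are the y-channel and whose
#'   `x`/`x_name` record the paired x-channel.
#' @export
vslope_signal <- function(x, which = c("vt1", "vt2")) {
  stopifnot(inherits(x, "cpet_series"))
  which <- match.arg(which)
  if (which == "vt1") {
    new_derived_signal("vslope_vt1", x$vco2, x$time, x = x$vo2, x_name = "vo2")
  } else {
    new_derived_signal("vslope_vt2", x$ve, x$time, x = x$vco2, x_name = "vco2")
  }
}

#' Ventilatory equivalents
#'
#' `VE/VO2` and `VE/VCO2`, the breathing cost per litre of gas exchanged.
#' They are used for display and visual quality control: VT1 shows as the
#' first sustained rise of VE/VO2 without a concurrent VE/VCO2 rise, VT2 as
#' a rise in both.
#'
#' @inheritParams excess_co2
#' @return A list with `derived_signal`s `ve_over_vo2` and `ve_over_vco2`.
#' @export
ventilatory_equivalents <- function(x) {
  stopifnot(inherits(x, "cpet_series"))
  if (any(x$vo2 <= 0)) stop("vo2 <= 0", call. = FALSE)
  bad <- which(x$vco2 <= 0)
  if (length(bad)) stop("vco2 <= 0 at sample ", bad[1], call. = FALSE)
  list(ve_over_vo2 = new_derived_signal("ve_over_vo2", x$ve / x$vo2, x$time),
       ve_over_vco2 = new_derived_signal("ve_over_vco2", x$ve / x$vco2, x$time))
}
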
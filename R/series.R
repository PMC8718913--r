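#' Construct a gas-exchange series
#'
#' A `cpet_series` holds the breath-averaged channels of one incremental
#' test on a uniform 10-s grid. Timestamps mark the *end* of each averaging
#' interval, so the first sample of a test sits at `time = 10` s and the
#' warm-up is included. `vo2`, `vco2` and `ve` are mandatory; the remaining
#' channels are optional. The respiratory exchange ratio is recomputed as
#' `vco2 / vo2` when not supplied, and the work-rate channel is filled from
#' `protocol` when one is given.
#'
#' @param time seconds from test start; strictly increasing, constant 10-s
#'   step.
#' @param vo2 oxygen uptake, L/min (> 0).
#' @param vco2 carbon-dioxide output, L/min (>= 0).
#' @param ve minute ventilation, L/min (> 0).
#' @param hr heart rate, beats/min (optional).
#' @param rer respiratory exchange ratio (optional; must equal `vco2/vo2`
#'   within 1e-6 when supplied).
#' @param peto2,petco2 end-tidal O2/CO2 pressures, mmHg (optional).
#' @param work instantaneous work rate, W (optional; filled from `protocol`).
#' @param rpe Borg 6-20 rating of perceived exertion (optional, sparse).
#' @param subject_age subject age in years, stored as an attribute
#'   (optional; used by [check_maximality()]).
#' @param protocol optional [cpet_protocol()] used to fill `work`.
#'
#' @return A data frame of class `cpet_series` with one row per 10-s sample.
#' @seealso [read_cpet_csv()], [exclude_warmup()], [simulate_test()]
#' @export
cpet_series <- function(time, vo2, vco2, ve, hr = NULL, rer = NULL,
                        peto2 = NULL, petco2 = NULL, work = NULL,
                        rpe = NULL, subject_age = NULL, protocol = NULL) {
  n <- length(time)
  if (is.null(rer)) rer <- vco2 / vo2
  if (is.null(work) && !is.null(protocol)) {
    work <- work_rate_at_time(time, protocol)
  }
  pad <- function(x) if (is.null(x)) rep(NA_real_, n) else as.numeric(x)
  x <- data.frame(time = as.numeric(time), vo2 = as.numeric(vo2),
                  vco2 = as.numeric(vco2), ve = as.numeric(ve),
                  hr = pad(hr), rer = as.numeric(rer),
                  peto2 = pad(peto2), petco2 = pad(petco2),
                  work = pad(work), rpe = pad(rpe))
  class(x) <- c("cpet_series", "data.frame")
  attr(x, "subject_age") <- subject_age
  validate_cpet_series(x)
  x
}

#' Validate the invariants of a gas-exchange series
#'
#' Checks the time grid (strictly increasing, constant 10-s step),
#' channel positivity (`vo2 > 0`, `vco2 >= 0`, `ve > 0`) and RER
#' consistency (`|rer - vco2/vo2| <= 1e-6`). Errors name the first
#' offending row.
#'
#' @param x a `cpet_series`.
#' @param dt expected sampling interval in seconds.
#' @return `x`, invisibly, when valid.
#' @export
validate_cpet_series <- function(x, dt = 10) {
  stopifnot(is.data.frame(x))
  n <- nrow(x)
  if (n == 0) stop("series is empty", call. = FALSE)
  if (n > 1) {
    steps <- diff(x$time)
    bad <- which(abs(steps - dt) > 1e-6)
    if (length(bad)) {
      stop(sprintf("non-uniform time grid: step of %g s at row %d (expected %g s)",
                   steps[bad[1]], bad[1] + 1, dt), call. = FALSE)
    }
  }
  chk <- function(cond, what) {
    bad <- which(!cond)
    if (length(bad)) {
      stop(sprintf("invalid series: %s at row %d", what, bad[1]), call. = FALSE)
    }
  }
  chk(x$vo2 > 0, "vo2 <= 0")
  chk(x$vco2 >= 0, "vco2 < 0")
  chk(x$ve > 0, "ve <= 0")
  ok <- is.na(x$rer) | abs(x$rer - x$vco2 / x$vo2) <= 1e-6
  chk(ok, "rer inconsistent with vco2/vo2")
  invisible(x)
}

#' @export
print.cpet_series <- function(x, ...) {
  cat(sprintf("CPET gas-exchange series: %d samples, %g-%g s\n",
              nrow(x), x$time[1], x$time[nrow(x)]))
  opt <- c("hr", "peto2", "petco2", "work", "rpe")
  have <- opt[vapply(opt, function(ch) !all(is.na(x[[ch]])), TRUE)]
  cat("  channels: time vo2 vco2 ve rer",
      if (length(have)) paste(have, collapse = " "), "\n")
  print.data.frame(utils::head(as.data.frame(x), 4), row.names = FALSE)
  if (nrow(x) > 4) cat(sprintf("  ... %d more rows\n", nrow(x) - 4))
  invisible(x)
}

# canonical CSV dialect: comma separator, dot decimal, named header row
.cpet_channels <- c("time", "vo2", "vco2", "ve", "hr", "rer",
                    "peto2", "petco2", "work", "rpe")

#' Read a gas-exchange test from the canonical CSV dialect
#'
#' The canonical dialect is comma-separated with a dot decimal mark and a
#' header row naming at least `time`, `vo2`, `vco2` and `ve` (case is
#' ignored). Vendor exports with other column names can be read by giving
#' `col_map`, a named character vector mapping canonical names to the
#' file's column names, e.g. `c(vo2 = "VO2 STPD", ve = "VE BTPS")`.
#'
#' @param path path to a CSV file.
#' @param protocol optional [cpet_protocol()]; fills the work channel when
#'   the file has none.
#' @param col_map optional named character vector renaming vendor columns
#'   to canonical ones.
#' @return A validated [cpet_series()].
#' @export
read_cpet_csv <- function(path, protocol = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(tolower(col_map[[canon]]), names(raw))
      if (!is.na(j)) names(raw)[j] <- canon
    }
  }
  mandatory <- c("time", "vo2", "vco2", "ve")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  get <- function(ch) if (ch %in% names(raw)) raw[[ch]] else NULL
  cpet_series(time = raw$time, vo2 = raw$vo2, vco2 = raw$vco2, ve = raw$ve,
              hr = get("hr"), rer = get("rer"), peto2 = get("peto2"),
              petco2 = get("petco2"), work = get("work"), rpe = get("rpe"),
              protocol = protocol)
}

#' Write a gas-exchange series in the canonical CSV dialect
#'
#' Values are written with 17 significant digits so that a
#' read-write-read round trip reproduces every channel bit-identically.
#'
#' @param x a `cpet_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cpet_csv <- function(x, path) {
  stopifnot(inherits(x, "cpet_series"))
  keep <- .cpet_channels[vapply(.cpet_channels,
                                function(ch) !all(is.na(x[[ch]])), TRUE)]
  out <- as.data.frame(x)[keep]
  fmt <- lapply(out, function(col) {
    s <- vapply(col, function(v) {
      if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
    }, "")
    s
  })
  txt <- do.call(paste, c(fmt, sep = ","))
  writeLines(c(paste(keep, collapse = ","), txt), path)
  invisible(path)
}

#' Drop the warm-up portion of a test
#'
#' Returns the samples with `time > warmup_duration`; the input is left
#' untouched. The warm-up is excluded from all threshold analysis.
#'
#' @param x a `cpet_series`.
#' @param protocol the [cpet_protocol()] defining the warm-up duration.
#' @return A `cpet_series` containing only post-warm-up samples.
#' @examples
#' sim <- simulate_test(sim_params(seed = 1))
#' post <- exclude_warmup(sim$series, sim$params$protocol)
#' @export
exclude_warmup <- function(x, protocol) {
  stopifnot(inherits(x, "cpet_series"), inherits(protocol, "cpet_protocol"))
  keep <- x$time > protocol$warmup_duration
  if (!any(keep)) {
    stop("test ends before the warm-up does: nothing left after excluding ",
         protocol$warmup_duration, " s", call. = FALSE)
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpet_series", "data.frame")
  attr(out, "subject_age") <- attr(x, "subject_age")
  out
}

#' Apply a centred rolling mean to the gas channels
#'
#' Optional pre-smoothing for noisier data than the usual 10-s cart
#' averages; the detection pipeline does not smooth by default.
#'
#' @param x a `cpet_series`.
#' @param window odd window length in samples; `1` is a no-op.
#' @return A smoothed `cpet_series` (edges keep the original values).
#' @export
smooth_series <- function(x, window = 3) {
  stopifnot(inherits(x, "cpet_series"), window >= 1)
  if (window == 1) return(x)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  sm <- function(v) {
    if (all(is.na(v))) return(v)
    f <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
    ifelse(is.na(f), v, f)
  }
  for (ch in c("vo2", "vco2", "ve")) x[[ch]] <- sm(x[[ch]])
  x$rer <- x$vco2 / x$vo2
  validate_cpet_series(x)
  x
}
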
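#' Describe an incremental cycle-ergometer protocol
#'
#' A protocol is a constant-wattage warm-up followed by stepwise wattage
#' increases at fixed intervals until exhaustion. Two standard variants are
#' built in: `"nominal"` (50 W warm-up for 3 min, then +25 W every minute)
#' and `"light"` (45 W warm-up for 3 min, then +15 W every minute), the
#' latter intended for lighter subjects. Use `variant = "custom"` to supply
#' all four numbers yourself.
#'
#' @param variant `"nominal"`, `"light"` or `"custom"`.
#' @param warmup_watts warm-up work rate in watts (custom protocols).
#' @param warmup_duration warm-up duration in seconds (custom protocols).
#' @param increment wattage increase per stage in watts (custom protocols).
#' @param stage_duration stage length in seconds (custom protocols).
#'
#' @return An object of class `cpet_protocol`: a list with fields
#'   `variant`, `warmup_watts`, `warmup_duration`, `increment`,
#'   `stage_duration`.
#' @examples
#' cpet_protocol("nominal")
#' cpet_protocol("custom", warmup_watts = 60, warmup_duration = 120,
#'               increment = 20, stage_duration = 60)
#' @export
cpet_protocol <- function(variant = c("nominal", "light", "custom"),
                          warmup_watts = NULL, warmup_duration = NULL,
                          increment = NULL, stage_duration = NULL) {
  variant <- match.arg(variant)
  p <- switch(variant,
    nominal = list(warmup_watts = 50, warmup_duration = 180,
                   increment = 25, stage_duration = 60),
    light   = list(warmup_watts = 45, warmup_duration = 180,
                   increment = 15, stage_duration = 60),
    custom  = {
      if (is.null(warmup_watts) || is.null(warmup_duration) ||
          is.null(increment) || is.null(stage_duration)) {
        stop("custom protocols need warmup_watts, warmup_duration, ",
             "increment and stage_duration", call. = FALSE)
      }
      list(warmup_watts = as.numeric(warmup_watts),
           warmup_duration = as.numeric(warmup_duration),
           increment = as.numeric(increment),
           stage_duration = as.numeric(stage_duration))
    })
  if (p$warmup_duration <= 0) stop("warmup_duration must be > 0", call. = FALSE)
  if (p$increment <= 0) stop("increment must be > 0", call. = FALSE)
  if (p$stage_duration <= 0) stop("stage_duration must be > 0", call. = FALSE)
  structure(c(list(variant = variant), p), class = "cpet_protocol")
}

#' @export
print.cpet_protocol <- function(x, ...) {
  cat(sprintf("CPET protocol (%s): %g W warm-up for %g s, then +%g W every %g s\n",
              x$variant, x$warmup_watts, x$warmup_duration,
              x$increment, x$stage_duration))
  invisible(x)
}

#' Work rate prescribed by a protocol at a given time
#'
#' During the warm-up (`t <= warmup_duration`) the warm-up wattage applies.
#' Afterwards the work rate is
#' `warmup_watts + increment * (1 + floor((t - warmup_duration - eps) / stage_duration))`,
#' i.e. the first post-warm-up stage already sits one increment above the
#' warm-up wattage.
#'
#' @param t time in seconds from test start; vectorised.
#' @param protocol a [cpet_protocol()].
#' @return Work rate(s) in watts, same length as `t`.
#' @examples
#' p <- cpet_protocol("nominal")
#' work_rate_at_time(c(100, 200, 400), p)  # 50 75 150
#' @export
work_rate_at_time <- function(t, protocol) {
  stopifnot(inherits(protocol, "cpet_protocol"))
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  p <- protocol
  stage <- 1 + floor((t - p$warmup_duration - 1e-9) / p$stage_duration)
  ifelse(t <= p$warmup_duration, p$warmup_watts,
         p$warmup_watts + p$increment * stage)
}

#' Read or write a protocol as plain-text key/value pairs
#'
#' The run-config format is one `key = value` pair per line with the fields
#' of [cpet_protocol()].
#'
#' @param path file path.
#' @return `read_protocol()` returns a `cpet_protocol`;
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  get <- function(k) vals[match(k, keys)]
  variant <- get("variant")
  if (!is.na(variant) && variant %in% c("nominal", "light")) {
    return(cpet_protocol(variant))
  }
  cpet_protocol("custom",
                warmup_watts = as.numeric(get("warmup_watts")),
                warmup_duration = as.numeric(get("warmup_duration")),
                increment = as.numeric(get("increment")),
                stage_duration = as.numeric(get("stage_duration")))
}

#' @param protocol a [cpet_protocol()] to serialize.
#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "cpet_protocol"))
  writeLines(c(paste("variant =", protocol$variant),
               paste("warmup_watts =", protocol$warmup_watts),
               paste("warmup_duration =", protocol$warmup_duration),
               paste("increment =", protocol$increment),
               paste("stage_duration =", protocol$stage_duration)),
             path)
  invisible(path)
}
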
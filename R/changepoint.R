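# Single changepoint detection by Gaussian variance-cost minimisation.
#
# The cost of a segment is n * log(max(sigma2_hat, eps)), with sigma2_hat
# the maximum-likelihood variance about the segment's own mean, so both
# mean shifts and spread changes register. A single split is placed at the
# argmin of the summed two-segment cost.

.var_floor <- 1e-12

#' Variance cost of one segment
#'
#' Returns `n * log(max(sigma2, eps))` where `sigma2` is the
#' maximum-likelihood variance (denominator `n`) of `y` about its own mean
#' and `eps = 1e-12` guards zero-variance segments.
#'
#' @param y numeric vector.
#' @param min_seg minimum admissible segment length.
#' @return The segment cost (scalar).
#' @examples
#' segment_cost_std(c(0, 2, 4))  # 3 * log(8/3)
#' @export
segment_cost_std <- function(y, min_seg = 3) {
  n <- length(y)
  if (n < min_seg) {
    stop("segment shorter than min_seg (", min_seg, ")", call. = FALSE)
  }
  v <- mean((y - mean(y))^2)
  n * log(max(v, .var_floor))
}

#' Locate the single most significant distribution change
#'
#' Exhaustively minimises the two-segment variance cost
#' `cost(y[1..k-1]) + cost(y[k..n])` over all split points `k` that leave
#' at least `min_seg` samples on each side. `index` is the first sample of
#' the second segment; ties break to the smallest index. The split is
#' flagged `significant` when its cost undercuts the unsplit cost by more
#' than `tolerance`; downstream code still uses the argmin when it is not,
#' but propagates an indeterminate flag.
#'
#' @param y numeric vector of length at least `2 * min_seg`.
#' @param min_seg minimum segment length (default 3: the variance needs two
#'   points and a third adds stability at 10-s sampling).
#' @param tolerance significance margin on the cost difference.
#' @param offset added to `index` to produce `global_index`, mapping a
#'   changepoint found in a trimmed window back to the parent series
#'   (pass `window$lo_index - 1`).
#' @return An object of class `changepoint_result` with fields `index`,
#'   `global_index`, `cost_split`, `cost_nosplit`, `significant`.
#' @examples
#' single_changepoint_std(c(1, 1.1, 0.9, 1, 9, 9.2, 8.8, 9))$index  # 5
#' @export
single_changepoint_std <- function(y, min_seg = 3, tolerance = 1e-9,
                                   offset = 0L) {
  n <- length(y)
  if (n < 2 * min_seg) {
    stop("need at least 2 * min_seg = ", 2 * min_seg, " samples, got ", n,
         call. = FALSE)
  }
  cs <- cumsum(y)
  cq <- cumsum(y^2)
  ks <- seq.int(min_seg + 1L, n - min_seg + 1L)
  n1 <- ks - 1L
  n2 <- n - n1
  s1 <- cs[n1]
  q1 <- cq[n1]
  s2 <- cs[n] - s1
  q2 <- cq[n] - q1
  v1 <- pmax(q1 / n1 - (s1 / n1)^2, 0)
  v2 <- pmax(q2 / n2 - (s2 / n2)^2, 0)
  cost <- n1 * log(pmax(v1, .var_floor)) + n2 * log(pmax(v2, .var_floor))
  best <- which.min(cost)  # first minimum = smallest k
  cost_nosplit <- segment_cost_std(y, min_seg = min_seg)
  structure(list(index = ks[best],
                 global_index = ks[best] + as.integer(offset),
                 cost_split = cost[best],
                 cost_nosplit = cost_nosplit,
                 significant = cost[best] < cost_nosplit - tolerance,
                 min_seg = min_seg, n = n),
            class = "changepoint_result")
}

#' @export
print.changepoint_result <- function(x, ...) {
  cat(sprintf("changepoint at index %d (global %d) of %d; cost %.4f vs %.4f unsplit; %s\n",
              x$index, x$global_index, x$n, x$cost_split, x$cost_nosplit,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Trim a signal to a percentile window of its samples
#'
#' Restricting the changepoint search to where a threshold can plausibly
#' lie protects the argmin from end-of-test noise. The window covers rows
#' `floor(lo_fraction * n) + 1` through `floor(hi_fraction * n)` (capped at
#' `n`), fractions being of the sample count.
#'
#' @param y numeric vector.
#' @param lo_fraction,hi_fraction window bounds, `0 <= lo < hi <= 1`.
#' @param min_seg minimum segment length of the downstream changepoint
#'   search; the window must hold at least `2 * min_seg` samples.
#' @return A list with `values` (the subsequence) and `window` (a list with
#'   `lo_fraction`, `hi_fraction`, `lo_index`, `hi_index`).
#' @examples
#' trim_signal(1:100, 0.30, 0.80)$window  # rows 31..80
#' @export
trim_signal <- function(y, lo_fraction, hi_fraction, min_seg = 3) {
  if (!(lo_fraction >= 0 && lo_fraction < hi_fraction && hi_fraction <= 1)) {
    stop("need 0 <= lo_fraction < hi_fraction <= 1", call. = FALSE)
  }
  n <- length(y)
  lo_index <- floor(lo_fraction * n) + 1L
  hi_index <- min(n, as.integer(floor(hi_fraction * n)))
  if (hi_index - lo_index + 1L < 2L * min_seg) {
    stop("trimmed window holds fewer than 2 * min_seg samples", call. = FALSE)
  }
  list(values = y[lo_index:hi_index],
       window = list(lo_fraction = lo_fraction, hi_fraction = hi_fraction,
                     lo_index = lo_index, hi_index = hi_index))
}
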
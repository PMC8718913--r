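# Quality-control rules for combining independent evaluator annotations
# and pairing visual with automated threshold values.

new_consensus <- function(values, value, accepted, rule, reason, unit) {
  structure(list(values = values, value = value, accepted = accepted,
                 rule = rule, reason = reason, unit = unit),
            class = "vt_consensus")
}

#' Combine three evaluator annotations into a consensus value
#'
#' Implements the four-rule quality-control cascade used when three
#' trained evaluators independently annotate one threshold of one test:
#' \enumerate{
#'   \item any evaluator marking the threshold indeterminate (`NA`) rejects
#'     the test;
#'   \item if the three values agree within one exercise stage
#'     (`stage_tolerance`, 50 W) or within `relative_tolerance` (15\%) of
#'     their mean, the three are averaged;
#'   \item otherwise, if a pair of evaluators agrees within
#'     `relative_tolerance` of each other, that pair is averaged and the
#'     outlier dropped; with no agreeing pair the test is rejected;
#'   \item a consensus earlier than the first credible stage
#'     (work below `min_value` = 75 W, or time at/below 240 s) is rejected
#'     as indeterminate.
#' }
#' The cascade is invariant to the order of the three values.
#'
#' @param values numeric vector of three annotations (work rates in W or
#'   times in s); `NA` marks an indeterminate call.
#' @param stage_tolerance absolute agreement tolerance (W) for rule 2.
#' @param relative_tolerance relative agreement tolerance (fraction).
#' @param min_value earliest credible consensus; defaults to 75 W or 240 s
#'   according to `unit`.
#' @param unit `"watts"` or `"seconds"`; selects the rule-4 default.
#' @return A list of class `vt_consensus`: `value` (NA when rejected),
#'   `accepted`, `rule` (`"all_three"` or `"best_pair"`), `reason`
#'   (`"indeterminate"`, `"spread"`, `"min_work"` or `"min_time"` when
#'   rejected).
#' @examples
#' combine_annotations(c(150, 160, 170))  # consensus 160 W
#' combine_annotations(c(100, 200, 300))  # rejected: spread
#' combine_annotations(c(70, 70, 70))     # rejected: before 75 W
#' @export
combine_annotations <- function(values, stage_tolerance = 50,
                                relative_tolerance = 0.15,
                                min_value = NULL,
                                unit = c("watts", "seconds")) {
  unit <- match.arg(unit)
  if (length(values) != 3) stop("exactly three annotations expected", call. = FALSE)
  if (stage_tolerance <= 0 || relative_tolerance <= 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  if (is.null(min_value)) min_value <- if (unit == "watts") 75 else 240
  if (any(is.na(values))) {
    return(new_consensus(values, NA_real_, FALSE, NA_character_,
                         "indeterminate", unit))
  }
  spread <- max(values) - min(values)
  if (spread <= stage_tolerance || spread < relative_tolerance * mean(values)) {
    value <- mean(values)
    rule <- "all_three"
  } else {
    pairs <- utils::combn(3, 2)
    reldiff <- apply(pairs, 2, function(ij) {
      abs(values[ij[1]] - values[ij[2]]) / mean(values[ij])
    })
    ok <- which(reldiff <= relative_tolerance)
    if (!length(ok)) {
      return(new_consensus(values, NA_real_, FALSE, NA_character_,
                           "spread", unit))
    }
    best <- ok[which.min(reldiff[ok])]
    value <- mean(values[pairs[, best]])
    rule <- "best_pair"
  }
  if (value < min_value) {
    return(new_consensus(values, value, FALSE, rule,
                         if (unit == "watts") "min_work" else "min_time", unit))
  }
  new_consensus(values, value, TRUE, rule, NA_character_, unit)
}

#' @export
print.vt_consensus <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf("consensus %s %.1f (%s rule) from (%s)\n", x$unit, x$value,
                x$rule, paste(x$values, collapse = ", ")))
  } else {
    cat(sprintf("rejected (%s) from (%s)\n", x$reason,
                paste(x$values, collapse = ", ")))
  }
  invisible(x)
}

#' Apply the consensus cascade to a table of annotations
#'
#' @param annotations data frame with columns `test_id`, `threshold`
#'   (`"vt1"`/`"vt2"`), `evaluator`, `value` (`NA` = indeterminate).
#' @param ... passed on to [combine_annotations()].
#' @return A data frame with one row per `(test_id, threshold)`:
#'   `consensus`, `accepted`, `rule`, `reason`.
#' @export
combine_annotation_table <- function(annotations, ...) {
  need <- c("test_id", "threshold", "value")
  if (!all(need %in% names(annotations))) {
    stop("annotations need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(annotations$test_id, annotations$threshold, drop = TRUE)
  rows <- lapply(split(annotations, key), function(g) {
    if (nrow(g) != 3) {
      stop("test ", g$test_id[1], " / ", g$threshold[1],
           " has ", nrow(g), " annotations; expected 3", call. = FALSE)
    }
    cons <- combine_annotations(g$value, ...)
    data.frame(test_id = g$test_id[1], threshold = g$threshold[1],
               consensus = cons$value, accepted = cons$accepted,
               rule = if (is.na(cons$rule)) NA_character_ else cons$rule,
               reason = cons$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$test_id, out$threshold), , drop = FALSE]
}

#' Pair visual consensus values with automated estimates
#'
#' Inner-joins the two tables on `(test_id, threshold)` after dropping
#' rejected visual rows and indeterminate automated rows, so only the
#' paired matches enter agreement statistics.
#'
#' @param visual data frame with `test_id`, `threshold`, `value` and
#'   optionally `accepted` (rows with `accepted == FALSE` or `NA` values
#'   are dropped).
#' @param automated data frame with `test_id`, `threshold`, `value` and
#'   optionally `indeterminate` (rows flagged `TRUE` or with `NA` values
#'   are dropped).
#' @return A data frame with columns `test_id`, `threshold`, `visual`,
#'   `automated`, one row per retained pair.
#' @export
pair_visual_automated <- function(visual, automated) {
  need <- c("test_id", "threshold", "value")
  stopifnot(all(need %in% names(visual)), all(need %in% names(automated)))
  v <- visual
  if ("accepted" %in% names(v)) v <- v[isTRUE_vec(v$accepted), , drop = FALSE]
  v <- v[!is.na(v$value), , drop = FALSE]
  a <- automated
  if ("indeterminate" %in% names(a)) {
    a <- a[!isTRUE_vec(a$indeterminate), , drop = FALSE]
  }
  a <- a[!is.na(a$value), , drop = FALSE]
  dup <- function(d, lab) {
    key <- paste(d$test_id, d$threshold)
    if (anyDuplicated(key)) {
      stop("duplicate test id in ", lab, " table: ",
           key[duplicated(key)][1], call. = FALSE)
    }
  }
  dup(v, "visual")
  dup(a, "automated")
  m <- merge(v[c("test_id", "threshold", "value")],
             a[c("test_id", "threshold", "value")],
             by = c("test_id", "threshold"),
             suffixes = c("_visual", "_automated"))
  out <- data.frame(test_id = m$test_id, threshold = m$threshold,
                    visual = m$value_visual, automated = m$value_automated,
                    stringsAsFactors = FALSE)
  out[order(out$test_id, out$threshold), , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & x
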
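#' Fallback defaults for fully non-visualized slots
#'
#' When every rater marks a grade slot "not visualized", a predefined default
#' is used so the rules engine always receives a resolved exam. The shipped
#' defaults are the least-pathological values that trigger no diagnostic
#' question on their own: INV 0, IT 1 (at both timepoints, hence zero
#' decongestant response), DNS 0, polyp 0. Every application of a default is
#' recorded in the aggregation audit.
#'
#' @param inv,it,dns,polyp default grade per scale; each must lie in its
#'   scale's domain.
#' @return named numeric vector of class `fallback_defaults`.
#' @export
fallback_defaults <- function(inv = 0, it = 1, dns = 0, polyp = 0) {
  out <- c(inv = inv, it = it, dns = dns, polyp = polyp)
  for (scale in SCALES) {
    if (is.na(out[[scale]]) || !is_valid_grade(out[[scale]], scale)) {
      stop(sprintf("fallback default for %s (%s) is outside the scale domain",
                   scale, format(out[[scale]])), call. = FALSE)
    }
  }
  structure(out, class = "fallback_defaults")
}

#' Aggregate one grade slot across raters
#'
#' The consensus rule for a single grade slot: drop "not visualized" (`NA`)
#' values; if none remain, use the predefined default; if a unique
#' most-frequent value exists among the valid grades, use that mode; otherwise
#' (a tie for most frequent) use the arithmetic mean of the valid grades.
#' Means are not rounded back to the scale — downstream rules compare
#' numerically.
#'
#' @param values numeric vector of grades, `NA` for not visualized; non-empty.
#' @param default grade to use when all values are `NA`.
#' @return list with `value` (numeric consensus grade) and `rule` (one of
#'   `"mode"`, `"average"`, `"default"`).
#' @export
#' @examples
#' aggregate_grade(c(2, 2, 3, NA), default = 1)$value # 2 (mode)
#' aggregate_grade(c(1, 2, NA, NA), default = 1)$value # 1.5 (tie -> mean)
aggregate_grade <- function(values, default) {
  stopifnot(length(values) >= 1)
  valid <- values[!is.na(values)]
  if (length(valid) == 0) {
    return(list(value = as.numeric(default), rule = "default"))
  }
  ## key on a fixed-precision rendering so the fractional INV thirds group
  ## exactly
  counts <- table(sprintf("%.9f", valid))
  top <- counts[counts == max(counts)]
  if (length(top) == 1) {
    list(value = valid[match(names(top), sprintf("%.9f", valid))], rule = "mode")
  } else {
    list(value = mean(valid), rule = "average")
  }
}

#' Aggregate a rater panel into one consensus exam
#'
#' Applies [aggregate_grade()] independently to each of the 16 grade slots
#' (4 scales x 2 sides x 2 timepoints). The result contains no `NA` grades
#' and is ready for [diagnose()]. The aggregation audit (which rule fired per
#' slot) is attached as attribute `"audit"`.
#'
#' @param panel list of [exam_grading()] objects for one participant, one per
#'   rater; all must share the participant id.
#' @param defaults [fallback_defaults()].
#' @return consensus [exam_grading()] with `rater_id = "consensus"`.
#' @export
aggregate_exam <- function(panel, defaults = fallback_defaults()) {
  stopifnot(length(panel) >= 1)
  for (e in panel) stopifnot(inherits(e, "exam_grading"))
  pid <- unique(vapply(panel, function(e) e$participant_id, ""))
  if (length(pid) != 1) {
    stop(sprintf("panel mixes participants: %s", paste(pid, collapse = ", ")),
         call. = FALSE)
  }
  audit <- list()
  slots <- list()
  for (slot in SLOTS) {
    g <- side_grades()
    for (scale in SCALES) {
      values <- vapply(panel, function(e) e[[slot]][[scale]], numeric(1))
      agg <- aggregate_grade(values, defaults[[scale]])
      g[[scale]] <- agg$value
      audit[[length(audit) + 1L]] <- data.frame(
        slot = slot, scale = scale, rule = agg$rule,
        n_valid = sum(!is.na(values)), stringsAsFactors = FALSE)
    }
    slots[[slot]] <- g
  }
  out <- exam_grading(pid, "consensus",
                      pre_left = slots$pre_left, pre_right = slots$pre_right,
                      post_left = slots$post_left, post_right = slots$post_right)
  attr(out, "audit") <- do.call(rbind, audit)
  out
}

#' Consensus visual diagnosis across raters
#'
#' A condition enters the consensus diagnosis when at least `min_votes`
#' raters independently identified it (default 2 specialists). The empty
#' result denotes Controls.
#'
#' @param votes list of [diagnosis_set()] objects (or character vectors of
#'   condition labels), one per rater; non-empty.
#' @param min_votes minimum number of raters naming a condition (>= 1).
#' @return a [diagnosis_set()].
#' @export
#' @examples
#' consensus_visual_diagnosis(list(
#'   diagnosis_set("AR"), diagnosis_set(c("AR", "DNS")),
#'   diagnosis_set("DNS"), diagnosis_set()
#' )) # AR, DNS
consensus_visual_diagnosis <- function(votes, min_votes = 2) {
  if (!is.numeric(min_votes) || min_votes < 1) {
    stop("min_votes must be a positive integer", call. = FALSE)
  }
  stopifnot(length(votes) >= 1)
  tallies <- vapply(CONDITIONS, function(cond) {
    sum(vapply(votes, function(v) cond %in% unclass(diagnosis_set(unclass(v))),
               logical(1)))
  }, numeric(1))
  diagnosis_set(CONDITIONS[tallies >= min_votes])
}
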
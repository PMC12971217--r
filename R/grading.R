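#' @keywords internal
"_PACKAGE"

## Closed enumerations of the study design: two sides, two timepoints,
## four grading scales per nostril.
SIDES <- c("L", "R")
TIMEPOINTS <- c("pre", "post")
SCALES <- c("inv", "it", "dns", "polyp")
SLOTS <- c("pre_left", "pre_right", "post_left", "post_right")

## Comparison tolerance for the fractional INV certainty grades (exact thirds
## are not representable in binary floating point).
GRADE_TOL <- 1e-9

#' Grading scale domains
#'
#' The four endoscopic grading scales used by the rules engine:
#'
#' * `inv` — internal nasal valve, graded by visibility of the middle
#'   turbinate: 0 (seen clearly), 1 (partially blocked), 2 (cannot be seen),
#'   extended with the certainty levels "maybe 0" (1/3) and "maybe 1" (2/3).
#' * `it` — inferior turbinate, graded 1–4 by the quartile of airway space
#'   occupied (grade × 25%).
#' * `dns` — septal deviation, graded 0 (straight) to 3 (covers more than
#'   two-thirds of the cavity).
#' * `polyp` — nasal polyps, graded 0 (none visualized) to 4 (filling the
#'   entire cavity).
#'
#' A grade may also be `NA`, the explicit "not visualized" (NV) marker: the
#' structure could not be assessed, which is distinct from a clear view
#' showing no pathology (grade 0).
#'
#' @return A named list of numeric vectors, one per scale, giving the legal
#'   grade values.
#' @export
#' @examples
#' grade_domains()$inv
grade_domains <- function() {
  list(
    inv   = c(0, 1 / 3, 2 / 3, 1, 2),
    it    = c(1, 2, 3, 4),
    dns   = c(0, 1, 2, 3),
    polyp = c(0, 1, 2, 3, 4)
  )
}

#' Test whether a value is a legal grade on a scale
#'
#' `NA` (not visualized) is always legal. Scale membership is tested with a
#' 1e-9 tolerance so the fractional INV grades compare exactly.
#'
#' @param value numeric value (or `NA`).
#' @param scale one of `"inv"`, `"it"`, `"dns"`, `"polyp"`.
#' @return logical scalar.
#' @export
is_valid_grade <- function(value, scale) {
  scale <- match.arg(scale, SCALES)
  if (is.na(value)) return(TRUE)
  if (!is.numeric(value)) return(FALSE)
  any(abs(grade_domains()[[scale]] - value) < GRADE_TOL)
}

#' Parse an internal nasal valve grade label
#'
#' Accepts the labels used on grading forms, case-insensitively and ignoring
#' surrounding whitespace: `"0"`, `"maybe 0"`/`"maybe0"` (certainty level,
#' value 1/3), `"maybe 1"`/`"maybe1"` (value 2/3), `"1"`, `"2"`, and `"NV"`
#' (not visualized, returned as `NA`).
#'
#' @param label character scalar.
#' @return numeric INV grade in `{0, 1/3, 2/3, 1, 2}` or `NA` for `"NV"`.
#' @seealso [format_inv_label()] for the inverse.
#' @export
#' @examples
#' parse_inv_label("maybe 0") # 1/3
#' parse_inv_label("NV")      # NA
parse_inv_label <- function(label) {
  stopifnot(length(label) == 1)
  key <- gsub("\\s+", "", tolower(as.character(label)))
  out <- switch(key,
    "0"      = 0,
    "maybe0" = 1 / 3,
    "maybe1" = 2 / 3,
    "1"      = 1,
    "2"      = 2,
    "nv"     = NA_real_,
    stop(sprintf("unrecognized INV grade label: '%s'", label), call. = FALSE)
  )
  out
}

#' Format an internal nasal valve grade as its label
#'
#' Inverse of [parse_inv_label()]: maps `{0, 1/3, 2/3, 1, 2, NA}` back to
#' `"0"`, `"maybe 0"`, `"maybe 1"`, `"1"`, `"2"`, `"NV"`.
#'
#' @param value numeric INV grade or `NA`.
#' @return character scalar label.
#' @export
format_inv_label <- function(value) {
  if (is.na(value)) return("NV")
  dom <- grade_domains()$inv
  labels <- c("0", "maybe 0", "maybe 1", "1", "2")
  i <- which(abs(dom - value) < GRADE_TOL)
  if (length(i) != 1) {
    stop(sprintf("value %s is not on the INV scale", format(value)), call. = FALSE)
  }
  labels[i]
}

#' Inferior turbinate airway occupancy fraction
#'
#' The IT scale is linear in airway occupancy: grade g corresponds to up to
#' g x 25% of the airway space occupied.
#'
#' @param grade integer IT grade in 1..4 (not `NA`).
#' @return occupancy fraction in (0, 1].
#' @export
#' @examples
#' it_occupancy_fraction(2) # 0.5
it_occupancy_fraction <- function(grade) {
  if (is.na(grade)) {
    stop("IT grade is missing (NV); resolve missingness (consensus/fallback) first",
         call. = FALSE)
  }
  if (!is_valid_grade(grade, "it")) {
    stop(sprintf("invalid IT grade %s (legal: 1..4)", format(grade)), call. = FALSE)
  }
  grade * 0.25
}

#' Construct the grades for one nostril at one timepoint
#'
#' @param inv,it,dns,polyp numeric grades on their respective scales, or `NA`
#'   for "not visualized".
#' @return named numeric vector with elements `inv`, `it`, `dns`, `polyp`.
#' @export
side_grades <- function(inv = NA, it = NA, dns = NA, polyp = NA) {
  c(inv = as.numeric(inv), it = as.numeric(it),
    dns = as.numeric(dns), polyp = as.numeric(polyp))
}

#' Construct one rater's complete grading of one participant
#'
#' An exam holds the four [side_grades()] slots of the study design: left and
#' right nostril, before and 10 minutes after topical decongestant.
#'
#' @param participant_id,rater_id identifiers.
#' @param pre_left,pre_right,post_left,post_right [side_grades()] vectors.
#' @return object of class `exam_grading`.
#' @export
exam_grading <- function(participant_id, rater_id,
                         pre_left = side_grades(), pre_right = side_grades(),
                         post_left = side_grades(), post_right = side_grades()) {
  for (s in list(pre_left, pre_right, post_left, post_right)) {
    stopifnot(is.numeric(s), identical(names(s), SCALES))
  }
  structure(
    list(participant_id = as.character(participant_id),
         rater_id = as.character(rater_id),
         pre_left = pre_left, pre_right = pre_right,
         post_left = post_left, post_right = post_right),
    class = "exam_grading"
  )
}

#' @export
print.exam_grading <- function(x, ...) {
  cat(sprintf("<exam_grading> participant %s, rater %s\n",
              x$participant_id, x$rater_id))
  m <- do.call(rbind, x[SLOTS])
  print(round(m, 3))
  invisible(x)
}

#' Validate an exam's grades against the scale domains
#'
#' Violations are returned as data, not raised as errors, so a whole file can
#' be screened in one pass. `NA` (not visualized) is always legal.
#'
#' @param exam an [exam_grading()] object.
#' @return data frame with columns `slot`, `scale`, `value`, `domain` (one row
#'   per out-of-domain grade); zero rows when the exam is clean.
#' @export
validate_exam <- function(exam) {
  stopifnot(inherits(exam, "exam_grading"))
  doms <- grade_domains()
  rows <- list()
  for (slot in SLOTS) {
    for (scale in SCALES) {
      v <- exam[[slot]][[scale]]
      if (!is_valid_grade(v, scale)) {
        rows[[length(rows) + 1L]] <- data.frame(
          slot = slot, scale = scale, value = v,
          domain = paste(format(doms[[scale]], digits = 4), collapse = ", "),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    data.frame(slot = character(), scale = character(),
               value = numeric(), domain = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
}

## Map (timepoint, side) to an exam slot name.
slot_name <- function(timepoint, side) {
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  side <- match.arg(side, SIDES)
  paste0(timepoint, "_", if (side == "L") "left" else "right")
}
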
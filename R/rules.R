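## The four nasal-obstruction conditions, in canonical serialization order.
CONDITIONS <- c("AR", "CRSsNP", "CRSwNP", "DNS")

#' Construct a multi-label diagnosis set
#'
#' A diagnosis is an unordered subset of AR, CRSsNP, CRSwNP, DNS; the empty
#' set denotes a control participant. Sets are stored canonically sorted in
#' the fixed order AR, CRSsNP, CRSwNP, DNS.
#'
#' @param conditions character vector of condition labels (may be empty).
#' @return canonical character vector (class `diagnosis_set`).
#' @export
#' @examples
#' diagnosis_set(c("DNS", "AR"))  # AR, DNS
#' diagnosis_set(character())     # Controls (empty)
diagnosis_set <- function(conditions = character()) {
  conditions <- unique(as.character(conditions))
  bad <- setdiff(conditions, CONDITIONS)
  if (length(bad) > 0) {
    stop(sprintf("unknown condition label(s): %s (legal: %s)",
                 paste(bad, collapse = ", "),
                 paste(CONDITIONS, collapse = ", ")), call. = FALSE)
  }
  structure(CONDITIONS[CONDITIONS %in% conditions], class = "diagnosis_set")
}

#' Serialize a diagnosis set to its label
#'
#' Conditions are joined with `"+"` in canonical order; the empty set is
#' rendered as `"Controls"`.
#'
#' @param x a [diagnosis_set()] (or plain character vector of conditions).
#' @return character scalar, e.g. `"AR+DNS"` or `"Controls"`.
#' @export
format_diagnosis <- function(x) {
  x <- diagnosis_set(unclass(x))
  if (length(x) == 0) "Controls" else paste(unclass(x), collapse = "+")
}

#' Parse a diagnosis label
#'
#' Inverse of [format_diagnosis()]. `"Controls"` (case-insensitive), the empty
#' string, and `NA` all denote the empty set.
#'
#' @param label character scalar such as `"AR+DNS"`.
#' @return a [diagnosis_set()].
#' @export
parse_diagnosis <- function(label) {
  stopifnot(length(label) == 1)
  if (is.na(label) || !nzchar(trimws(label)) ||
      tolower(trimws(label)) == "controls") {
    return(diagnosis_set())
  }
  diagnosis_set(trimws(strsplit(as.character(label), "\\+")[[1]]))
}

#' @export
print.diagnosis_set <- function(x, ...) {
  cat("<diagnosis_set>", format_diagnosis(x), "\n")
  invisible(x)
}

#' Rule parameters for the expert system
#'
#' Thresholds of the five diagnostic questions. All comparisons are
#' greater-or-equal.
#'
#' @param it_reduction_threshold minimum fractional inferior-turbinate size
#'   reduction after decongestant, required bilaterally, for a positive
#'   decongestant response (default 0.35).
#' @param inv_pathology_threshold minimum internal-nasal-valve grade, required
#'   bilaterally, to count as obstructed (default 1; the certainty grades 1/3
#'   and 2/3 fall below it).
#' @param dns_asymmetry_min_diff minimum absolute left-right difference in
#'   post-decongestant septal grade to count as asymmetric (default 1).
#' @param polyp_presence_min minimum polyp grade to count as polyps present
#'   (default 1).
#' @param polyp_timepoint timepoint(s) at which bilateral polyps are assessed:
#'   `"pre"` (default; decongestion does not remove polyps) or
#'   `"pre_or_post"`.
#' @return list of class `rule_params`.
#' @export
rule_params <- function(it_reduction_threshold = 0.35,
                        inv_pathology_threshold = 1,
                        dns_asymmetry_min_diff = 1,
                        polyp_presence_min = 1,
                        polyp_timepoint = c("pre", "pre_or_post")) {
  polyp_timepoint <- match.arg(polyp_timepoint)
  stopifnot(it_reduction_threshold > 0, inv_pathology_threshold > 0,
            dns_asymmetry_min_diff > 0, polyp_presence_min > 0)
  structure(
    list(it_reduction_threshold = it_reduction_threshold,
         inv_pathology_threshold = inv_pathology_threshold,
         dns_asymmetry_min_diff = dns_asymmetry_min_diff,
         polyp_presence_min = polyp_presence_min,
         polyp_timepoint = polyp_timepoint),
    class = "rule_params"
  )
}

## >= with tolerance so consensus-averaged thirds compare exactly.
geq <- function(x, y) x >= y - GRADE_TOL

## Pull one scale's grade from an exam slot, erroring on NV: the rules engine
## only runs on resolved exams (after consensus/fallback).
resolved_grade <- function(exam, slot, scale, question) {
  v <- exam[[slot]][[scale]]
  if (is.na(v)) {
    stop(sprintf(
      "%s: %s.%s is not visualized; apply consensus/fallback (aggregate_exam) before diagnosing",
      question, slot, scale), call. = FALSE)
  }
  v
}

#' Question 1: bilateral nasal polyps
#'
#' TRUE when the polyp grade reaches `polyp_presence_min` on both sides at the
#' pre-decongestant timepoint (or at either timepoint when
#' `polyp_timepoint = "pre_or_post"`). Bilateral polyps indicate CRSwNP;
#' unilateral polyps may indicate other pathologies (including tumors) and
#' yield FALSE with a warning flagging the participant for exclusion review.
#'
#' @param exam a resolved [exam_grading()] (no `NA` grades).
#' @param params [rule_params()].
#' @return logical scalar.
#' @export
q1_bilateral_polyps <- function(exam, params = rule_params()) {
  present_at <- function(tp) {
    l <- resolved_grade(exam, slot_name(tp, "L"), "polyp", "q1")
    r <- resolved_grade(exam, slot_name(tp, "R"), "polyp", "q1")
    c(geq(l, params$polyp_presence_min), geq(r, params$polyp_presence_min))
  }
  tps <- if (params$polyp_timepoint == "pre") "pre" else TIMEPOINTS
  per_tp <- vapply(tps, present_at, logical(2))
  bilateral <- any(apply(per_tp, 2, all))
  unilateral <- !bilateral && any(per_tp)
  if (unilateral) {
    warning(sprintf(
      "participant %s: unilateral polyps; flagged for exclusion review (possible non-inflammatory mass)",
      exam$participant_id), call. = FALSE)
  }
  bilateral
}

#' Question 2: bilateral decongestant response of the inferior turbinates
#'
#' The fractional reduction on each side is (pre - post) / pre on the IT
#' grade scale (identical to the reduction in airway occupancy, since the
#' scale is linear). Negative reductions (post larger than pre) count as zero
#' response. TRUE when the reduction reaches `it_reduction_threshold`
#' (default 35%) on both sides, the reversible-congestion signature of
#' allergic rhinitis.
#'
#' @inheritParams q1_bilateral_polyps
#' @return logical scalar.
#' @export
q2_decongestant_response <- function(exam, params = rule_params()) {
  red <- function(side) {
    pre <- resolved_grade(exam, slot_name("pre", side), "it", "q2")
    post <- resolved_grade(exam, slot_name("post", side), "it", "q2")
    max(0, (pre - post) / pre)
  }
  geq(red("L"), params$it_reduction_threshold) &&
    geq(red("R"), params$it_reduction_threshold)
}

#' Question 3: post-decongestant septal asymmetry
#'
#' TRUE when the left and right post-decongestant septal-deviation grades
#' differ by at least `dns_asymmetry_min_diff`. Assessing asymmetry after
#' decongestion minimizes the influence of the nasal cycle.
#'
#' @inheritParams q1_bilateral_polyps
#' @return logical scalar.
#' @export
q3_dns_asymmetry <- function(exam, params = rule_params()) {
  l <- resolved_grade(exam, "post_left", "dns", "q3")
  r <- resolved_grade(exam, "post_right", "dns", "q3")
  geq(abs(l - r), params$dns_asymmetry_min_diff)
}

inv_bilateral_at <- function(exam, timepoint, params, question) {
  l <- resolved_grade(exam, slot_name(timepoint, "L"), "inv", question)
  r <- resolved_grade(exam, slot_name(timepoint, "R"), "inv", question)
  geq(l, params$inv_pathology_threshold) && geq(r, params$inv_pathology_threshold)
}

#' Questions 4 and 5: bilateral internal nasal valve obstruction
#'
#' TRUE when the INV grade reaches `inv_pathology_threshold` on both sides at
#' the pre-decongestant (`q4_inv_pre`) or post-decongestant (`q5_inv_post`)
#' timepoint. The certainty grades "maybe 0" (1/3) and "maybe 1" (2/3) fall
#' below the default threshold of 1 (control range).
#'
#' @inheritParams q1_bilateral_polyps
#' @return logical scalar.
#' @export
q4_inv_pre <- function(exam, params = rule_params()) {
  inv_bilateral_at(exam, "pre", params, "q4")
}

#' @rdname q4_inv_pre
#' @export
q5_inv_post <- function(exam, params = rule_params()) {
  inv_bilateral_at(exam, "post", params, "q5")
}

#' Evaluate the five diagnostic questions
#'
#' @inheritParams q1_bilateral_polyps
#' @return named logical vector `c(q1, q2, q3, q4, q5)`.
#' @export
evaluate_questions <- function(exam, params = rule_params()) {
  c(q1 = q1_bilateral_polyps(exam, params),
    q2 = q2_decongestant_response(exam, params),
    q3 = q3_dns_asymmetry(exam, params),
    q4 = q4_inv_pre(exam, params),
    q5 = q5_inv_post(exam, params))
}

## The verbatim 32-row decision table: rows ordered q1 = T first, then q2,
## q3, q4, q5, mirroring the published layout. The CSV shipped in
## inst/extdata/decision_table.csv is checked against this embedded copy at
## load time.
DECISION_TABLE_ROWS <- c(
  "TTTTT" = "AR+CRSwNP+DNS",
  "TTTTF" = "AR+CRSwNP+DNS",
  "TTTFT" = "CRSwNP+DNS",
  "TTTFF" = "CRSwNP+DNS",
  "TTFTT" = "AR+CRSwNP",
  "TTFTF" = "AR+CRSwNP",
  "TTFFT" = "CRSwNP",
  "TTFFF" = "CRSwNP",
  "TFTTT" = "CRSwNP+DNS",
  "TFTTF" = "CRSwNP+DNS",
  "TFTFT" = "CRSwNP+DNS",
  "TFTFF" = "CRSwNP+DNS",
  "TFFTT" = "CRSwNP",
  "TFFTF" = "CRSwNP",
  "TFFFT" = "CRSwNP",
  "TFFFF" = "CRSwNP",
  "FTTTT" = "AR+CRSsNP+DNS",
  "FTTTF" = "AR+DNS",
  "FTTFT" = "DNS",
  "FTTFF" = "DNS",
  "FTFTT" = "AR+CRSsNP",
  "FTFTF" = "AR",
  "FTFFT" = "Controls",
  "FTFFF" = "Controls",
  "FFTTT" = "CRSsNP+DNS",
  "FFTTF" = "CRSsNP+DNS",
  "FFTFT" = "DNS",
  "FFTFF" = "DNS",
  "FFFTT" = "CRSsNP",
  "FFFTF" = "CRSsNP",
  "FFFFT" = "Controls",
  "FFFFF" = "Controls"
)

qv_key <- function(qv) {
  stopifnot(is.logical(qv), length(qv) == 5, !anyNA(qv))
  paste(ifelse(qv, "T", "F"), collapse = "")
}

#' The full decision table
#'
#' Expert-consensus mapping from every combination of the five question
#' outcomes (32 rows) to a multi-label diagnosis; control rows map to the
#' empty set.
#'
#' @return data frame with logical columns `q1`..`q5` and character column
#'   `diagnosis` (canonical `"+"`-joined labels, `"Controls"` for the empty
#'   set), 32 rows.
#' @export
#' @examples
#' head(decision_table())
decision_table <- function() {
  keys <- names(DECISION_TABLE_ROWS)
  qm <- t(vapply(strsplit(keys, ""), function(x) x == "T", logical(5)))
  out <- data.frame(qm, diagnosis = unname(DECISION_TABLE_ROWS),
                    stringsAsFactors = FALSE)
  names(out) <- c(paste0("q", 1:5), "diagnosis")
  out
}

#' Read a decision table from its CSV asset
#'
#' The table ships as a version-controlled CSV (columns `q1`..`q5` coded
#' `T`/`F`, `diagnosis` as `"+"`-joined labels, `"Controls"` for the empty
#' set). The loaded table is verified row-for-row against the embedded copy;
#' any divergence is an error.
#'
#' @param path CSV path; defaults to the copy installed with the package.
#' @return data frame as [decision_table()].
#' @export
read_decision_table <- function(path = system.file("extdata", "decision_table.csv",
                                                   package = "rhinorules")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c(paste0("q", 1:5), "diagnosis")
  if (!identical(names(raw), need)) {
    stop("decision table CSV must have columns q1..q5, diagnosis", call. = FALSE)
  }
  for (q in paste0("q", 1:5)) {
    if (!all(raw[[q]] %in% c("T", "F"))) {
      stop(sprintf("decision table column %s must be coded T/F", q), call. = FALSE)
    }
    raw[[q]] <- raw[[q]] == "T"
  }
  key <- apply(raw[paste0("q", 1:5)], 1, function(r) qv_key(as.logical(r)))
  if (anyDuplicated(key) || length(key) != 32) {
    stop("decision table must contain each of the 32 question vectors exactly once",
         call. = FALSE)
  }
  ## canonicalize diagnosis labels, then verify against the embedded copy
  raw$diagnosis <- vapply(raw$diagnosis,
                          function(d) format_diagnosis(parse_diagnosis(d)), "")
  embedded <- DECISION_TABLE_ROWS[key]
  if (!identical(unname(embedded), raw$diagnosis)) {
    bad <- key[raw$diagnosis != unname(embedded)]
    stop(sprintf("decision table CSV diverges from the embedded copy at row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  raw
}

#' Look up the diagnosis for a question vector
#'
#' Total over all 32 question vectors.
#'
#' @param qv logical vector of length 5 (`q1`..`q5`), no `NA`.
#' @param table a decision table as returned by [decision_table()].
#' @return a [diagnosis_set()] (empty for control rows).
#' @export
#' @examples
#' lookup_diagnosis(c(TRUE, TRUE, FALSE, FALSE, FALSE)) # CRSwNP
lookup_diagnosis <- function(qv, table = decision_table()) {
  key <- qv_key(qv)
  tkey <- apply(table[paste0("q", 1:5)], 1, function(r) qv_key(as.logical(r)))
  i <- match(key, tkey)
  if (is.na(i)) stop(sprintf("question vector %s not in decision table", key),
                     call. = FALSE)
  parse_diagnosis(table$diagnosis[i])
}

#' Diagnose a resolved exam
#'
#' Runs the five diagnostic questions on the exam and maps the resulting
#' vector through the decision table.
#'
#' @inheritParams q1_bilateral_polyps
#' @param table a decision table as returned by [decision_table()].
#' @return a [diagnosis_set()].
#' @export
diagnose <- function(exam, params = rule_params(), table = decision_table()) {
  lookup_diagnosis(evaluate_questions(exam, params), table)
}
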
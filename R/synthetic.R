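#' Reference cohort composition (specific condition combinations)
#'
#' Counts of the 71 study participants by specific diagnosis combination:
#' controls plus the eleven observed combinations of AR, CRSsNP, CRSwNP and
#' DNS. These counts are the default prevalence pattern of the synthetic
#' cohort generator.
#'
#' @return named integer vector; names are diagnosis labels
#'   (`"Controls"`, `"AR"`, ..., `"AR+CRSwNP+DNS"`), values are counts
#'   summing to 71.
#' @export
study_prevalence <- function() {
  c("Controls" = 6L,
    "AR" = 11L,
    "CRSsNP" = 5L,
    "CRSwNP" = 9L,
    "DNS" = 16L,
    "AR+CRSsNP" = 2L,
    "AR+CRSwNP" = 3L,
    "AR+DNS" = 15L,
    "CRSsNP+DNS" = 1L,
    "CRSwNP+DNS" = 2L,
    "AR+CRSsNP+DNS" = 1L,
    "AR+CRSwNP+DNS" = 0L)
}

#' Condition-inclusive composition from combination counts
#'
#' Recomputes the condition-inclusive groups (participants whose diagnosis
#' set includes each condition, plus controls and the condition-inclusive
#' total) from counts of specific diagnosis combinations.
#'
#' @param counts named vector of combination counts as in
#'   [study_prevalence()].
#' @return data frame with columns `group`, `n`, `percentage` (of the total,
#'   in percent).
#' @export
#' @examples
#' condition_inclusive(study_prevalence())
condition_inclusive <- function(counts = study_prevalence()) {
  total <- sum(counts)
  sets <- lapply(names(counts), parse_diagnosis)
  inc <- function(cond) sum(counts[vapply(sets, function(s) cond %in% s, logical(1))])
  n_controls <- sum(counts[vapply(sets, function(s) length(s) == 0, logical(1))])
  groups <- c("Controls", "Condition inclusive",
              paste("Includes", CONDITIONS))
  n <- c(n_controls, total - n_controls, vapply(CONDITIONS, inc, numeric(1)))
  data.frame(group = groups, n = as.integer(n),
             percentage = 100 * n / total,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Specification of a synthetic cohort
#'
#' Defines a simulated study: participants with known multi-label gold
#' diagnoses, a panel of raters whose gradings follow the condition patterns
#' the rules engine expects, plus rater disagreement noise and
#' "not visualized" missingness.
#'
#' @param n_participants cohort size (default 71, the study size).
#' @param prevalence named numeric vector mapping diagnosis labels to
#'   probabilities (normalized internally); defaults to the published
#'   combination counts of [study_prevalence()].
#' @param n_raters number of raters per participant (default 4 specialists).
#' @param noise per-slot probability that a rater's grade is perturbed by one
#'   scale step (symmetric, clipped at the scale bounds). Default 0.1.
#' @param nv_rate per-slot probability that a rater marks a grade
#'   "not visualized" (default 0.02).
#' @param seed integer RNG seed making the cohort reproducible.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 71,
                        prevalence = study_prevalence(),
                        n_raters = 4, noise = 0.1, nv_rate = 0.02,
                        seed = 20250728) {
  stopifnot(n_participants >= 1, n_raters >= 1,
            noise >= 0, noise <= 1, nv_rate >= 0, nv_rate <= 1,
            is.numeric(prevalence), !is.null(names(prevalence)),
            all(prevalence >= 0), sum(prevalence) > 0)
  ## validate labels and reachability up front
  for (lab in names(prevalence)) {
    if (prevalence[[lab]] > 0) reachable_rows(parse_diagnosis(lab))
  }
  structure(
    list(n_participants = as.integer(n_participants),
         prevalence = prevalence / sum(prevalence),
         n_raters = as.integer(n_raters),
         noise = noise, nv_rate = nv_rate, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

## Decision-table rows whose diagnosis equals the given set; errors with the
## list of reachable sets when none does.
reachable_rows <- function(diagnosis) {
  label <- format_diagnosis(diagnosis)
  rows <- which(unname(DECISION_TABLE_ROWS) == label)
  if (length(rows) == 0) {
    stop(sprintf("diagnosis set %s is not an output of the decision table; reachable sets: %s",
                 label, paste(sort(unique(unname(DECISION_TABLE_ROWS))),
                              collapse = ", ")), call. = FALSE)
  }
  rows
}

## Sample one element from a vector or list (sample() treats a scalar as 1:n).
pick <- function(x) x[[sample.int(length(x), 1)]]

## Grade patterns realizing each question outcome. Sub-threshold IT pairs on
## both sides guarantee q2 = FALSE; both INV grades below 1 guarantee
## q4/q5 = FALSE.
IT_RESPONSIVE_PAIRS <- list(c(2, 1), c(3, 1), c(4, 1), c(4, 2))
IT_FLAT_PAIRS <- list(c(1, 1), c(2, 2), c(3, 3), c(4, 4), c(3, 2), c(4, 3))

#' Generate a noiseless exam realizing a diagnosis
#'
#' Picks uniformly among the decision-table rows mapping to the requested
#' diagnosis set, then samples grades realizing that row's question vector:
#' bilateral polyps iff q1; bilateral >=35% inferior-turbinate reduction iff
#' q2; post-decongestant septal asymmetry of at least one grade iff q3
#' (septal grades are structural and identical pre/post); bilateral internal
#' nasal valve grade >=1 at the pre/post timepoint iff q4/q5. Uses the
#' current RNG state; seed upstream for reproducibility.
#'
#' @param diagnosis a [diagnosis_set()] (or character vector / label) that is
#'   an output of the decision table.
#' @param participant_id,rater_id identifiers for the generated exam.
#' @return a noiseless [exam_grading()] whose [diagnose()] equals
#'   `diagnosis`.
#' @export
truth_exam_for <- function(diagnosis, participant_id = "truth",
                           rater_id = "truth") {
  diagnosis <- if (is.character(diagnosis) && length(diagnosis) == 1 &&
                   grepl("\\+|^Controls$", diagnosis)) {
    parse_diagnosis(diagnosis)
  } else {
    diagnosis_set(unclass(diagnosis))
  }
  row <- pick(reachable_rows(diagnosis))
  qv <- strsplit(names(DECISION_TABLE_ROWS)[row], "")[[1]] == "T"

  g <- list()
  for (slot in SLOTS) g[[slot]] <- side_grades()

  ## q1: polyps, identical pre/post (decongestion does not remove polyps)
  polyp <- if (qv[1]) c(pick(1:4), pick(1:4)) else c(0, 0)
  ## q2: per-side (pre, post) inferior turbinate pair
  it_l <- pick(if (qv[2]) IT_RESPONSIVE_PAIRS else IT_FLAT_PAIRS)
  it_r <- pick(if (qv[2]) IT_RESPONSIVE_PAIRS else IT_FLAT_PAIRS)
  ## q3: post-decongestant septal asymmetry; deviation is structural so the
  ## pre grades mirror the post grades
  if (qv[3]) {
    d <- pick(1:3)
    lo <- pick(0:(3 - d))
    dns <- if (sample.int(2, 1) == 1) c(lo + d, lo) else c(lo, lo + d)
  } else {
    dns <- rep(pick(0:3), 2)
  }
  ## q4/q5: internal nasal valve, per timepoint
  inv_at <- function(q) {
    if (q) c(pick(c(1, 2)), pick(c(1, 2)))
    else c(pick(c(0, 1 / 3, 2 / 3)), pick(c(0, 1 / 3, 2 / 3)))
  }
  inv_pre <- inv_at(qv[4])
  inv_post <- inv_at(qv[5])

  for (i in 1:2) { # 1 = L, 2 = R
    pre <- side_grades(inv = inv_pre[i], it = it_l[1], dns = dns[i],
                       polyp = polyp[i])
    post <- side_grades(inv = inv_post[i], it = it_l[2], dns = dns[i],
                        polyp = polyp[i])
    if (i == 2) {
      pre[["it"]] <- it_r[1]
      post[["it"]] <- it_r[2]
    }
    g[[slot_name("pre", SIDES[i])]] <- pre
    g[[slot_name("post", SIDES[i])]] <- post
  }
  exam_grading(participant_id, rater_id,
               pre_left = g$pre_left, pre_right = g$pre_right,
               post_left = g$post_left, post_right = g$post_right)
}

## One scale step up or down, clipped to the domain.
perturb_grade <- function(value, scale) {
  dom <- grade_domains()[[scale]]
  i <- which(abs(dom - value) < GRADE_TOL)
  if (length(i) != 1) return(value) # off-scale values (shouldn't occur) pass through
  j <- i + pick(c(-1L, 1L))
  dom[min(max(j, 1L), length(dom))]
}

## Apply rater noise and missingness to a truth exam.
perturb_exam <- function(exam, rater_id, noise, nv_rate) {
  out <- exam
  out$rater_id <- as.character(rater_id)
  for (slot in SLOTS) {
    for (scale in SCALES) {
      v <- out[[slot]][[scale]]
      if (noise > 0 && stats::runif(1) < noise) v <- perturb_grade(v, scale)
      if (nv_rate > 0 && stats::runif(1) < nv_rate) v <- NA_real_
      out[[slot]][[scale]] <- v
    }
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws each participant's gold diagnosis from the prevalence distribution,
#' builds a noiseless truth exam realizing it (self-checked: the rules engine
#' must recover the gold diagnosis from every truth exam), then derives each
#' rater's exam by independent per-slot perturbation and missingness.
#' Reproducible given the spec's seed; the global RNG state is restored on
#' exit.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort` with elements `spec`, `gold`
#'   (named list of [diagnosis_set()]), `truth_exams` (named list of
#'   noiseless [exam_grading()]), `panels` (named list of per-rater exam
#'   lists).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  restore <- save_rng_state()
  set.seed(spec$seed)
  on.exit(restore(), add = TRUE)

  labels <- sample(names(spec$prevalence), spec$n_participants,
                   replace = TRUE, prob = spec$prevalence)
  pids <- sprintf("P%03d", seq_len(spec$n_participants))
  gold <- stats::setNames(lapply(labels, parse_diagnosis), pids)
  raters <- sprintf("R%d", seq_len(spec$n_raters))

  truth_exams <- list()
  panels <- list()
  for (i in seq_along(pids)) {
    truth <- truth_exam_for(gold[[i]], participant_id = pids[i])
    recovered <- diagnose(truth)
    if (!identical(unclass(recovered), unclass(gold[[i]]))) {
      stop(sprintf("generator self-check failed for %s: built %s, diagnosed %s",
                   pids[i], format_diagnosis(gold[[i]]),
                   format_diagnosis(recovered)), call. = FALSE)
    }
    truth_exams[[pids[i]]] <- truth
    panels[[pids[i]]] <- lapply(raters, function(r) {
      perturb_exam(truth, r, spec$noise, spec$nv_rate)
    })
  }
  structure(
    list(spec = spec, gold = gold, truth_exams = truth_exams, panels = panels),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants, %d raters, noise=%.2f, nv_rate=%.2f, seed=%d\n",
              x$spec$n_participants, x$spec$n_raters, x$spec$noise,
              x$spec$nv_rate, x$spec$seed))
  comp <- table(vapply(x$gold, format_diagnosis, ""))
  print(comp)
  invisible(x)
}

#' Consensus diagnoses and recovery rate for a synthetic cohort
#'
#' Runs the full pipeline on every participant — consensus aggregation of the
#' rater panel, then the rules engine — and compares against the gold
#' diagnoses.
#'
#' @param cohort a [generate_cohort()] result.
#' @param params [rule_params()].
#' @param defaults [fallback_defaults()].
#' @return list with `predicted` (named list of [diagnosis_set()]),
#'   `recovery` (fraction of participants whose predicted set equals gold
#'   exactly).
#' @export
cohort_recovery <- function(cohort, params = rule_params(),
                            defaults = fallback_defaults()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  predicted <- lapply(cohort$panels, function(panel) {
    suppressWarnings(diagnose(aggregate_exam(panel, defaults), params))
  })
  exact <- mapply(function(p, g) identical(unclass(p), unclass(g)),
                  predicted, cohort$gold)
  list(predicted = predicted, recovery = mean(exact))
}
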
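## ---- long-format grading CSV ------------------------------------------
## One row per (participant, rater, timepoint, side); columns participant_id,
## rater_id, timepoint (pre/post), side (L/R), inv, it, dns, polyp; grades
## rendered numerically ("0.333333333" for maybe 0 is also accepted, but the
## writer emits the form labels for INV) and "NV" for not visualized.

GRADING_COLUMNS <- c("participant_id", "rater_id", "timepoint", "side", SCALES)

format_grade <- function(value, scale) {
  if (scale == "inv") return(format_inv_label(value))
  if (is.na(value)) "NV" else format(value)
}

parse_grade <- function(token, scale, row) {
  token <- trimws(as.character(token))
  if (toupper(token) == "NV" || token == "") return(NA_real_)
  if (scale == "inv") {
    out <- tryCatch(parse_inv_label(token), error = function(e) {
      ## also accept a plain numeric rendering of the scale values
      v <- suppressWarnings(as.numeric(token))
      if (!is.na(v) && is_valid_grade(v, "inv")) v else
        stop(sprintf("row %d: unrecognized inv grade '%s'", row, token),
             call. = FALSE)
    })
    return(out)
  }
  v <- suppressWarnings(as.numeric(token))
  if (is.na(v)) {
    stop(sprintf("row %d: unrecognized %s grade '%s'", row, scale, token),
         call. = FALSE)
  }
  v
}

#' Read a long-format grading CSV
#'
#' Schema: header row with columns `participant_id`, `rater_id`,
#' `timepoint` (`pre`/`post`), `side` (`L`/`R`), `inv`, `it`, `dns`, `polyp`;
#' one row per (participant, rater, timepoint, side); `"NV"` for
#' not-visualized grades; INV accepts the form labels (`"maybe 0"` etc.) or
#' numeric values. Schema violations are reported with row numbers.
#'
#' @param path CSV path.
#' @return data frame with numeric grade columns (`NA` = not visualized).
#' @export
read_gradings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(GRADING_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("grading CSV is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[GRADING_COLUMNS]
  if (nrow(df) == 0) {
    for (scale in SCALES) df[[scale]] <- numeric(0)
    return(df)
  }
  bad_tp <- which(!df$timepoint %in% TIMEPOINTS)
  if (length(bad_tp) > 0) {
    stop(sprintf("row %d: timepoint must be pre or post (got '%s')",
                 bad_tp[1] + 1L, df$timepoint[bad_tp[1]]), call. = FALSE)
  }
  bad_side <- which(!df$side %in% SIDES)
  if (length(bad_side) > 0) {
    stop(sprintf("row %d: side must be L or R (got '%s')",
                 bad_side[1] + 1L, df$side[bad_side[1]]), call. = FALSE)
  }
  for (scale in SCALES) {
    df[[scale]] <- vapply(seq_len(nrow(df)), function(i) {
      v <- parse_grade(df[[scale]][i], scale, i + 1L) # +1: header row
      if (!is_valid_grade(v, scale)) {
        stop(sprintf("row %d: %s grade %s outside domain {%s}",
                     i + 1L, scale, format(v),
                     paste(format(grade_domains()[[scale]], digits = 4),
                           collapse = ", ")), call. = FALSE)
      }
      v
    }, numeric(1))
  }
  df
}

#' Write a long-format grading CSV
#'
#' Inverse of [read_gradings_csv()]; INV grades are written as form labels
#' (`"maybe 0"`, ...), all missing grades as `"NV"`.
#'
#' @param exams list of [exam_grading()] objects, or a `synthetic_cohort`
#'   (whose rater panels are written).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gradings_csv <- function(exams, path) {
  if (inherits(exams, "synthetic_cohort")) {
    exams <- unlist(unname(exams$panels), recursive = FALSE)
  }
  rows <- list()
  for (e in exams) {
    stopifnot(inherits(e, "exam_grading"))
    for (tp in TIMEPOINTS) {
      for (side in SIDES) {
        g <- e[[slot_name(tp, side)]]
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = e$participant_id, rater_id = e$rater_id,
          timepoint = tp, side = side,
          inv = format_grade(g[["inv"]], "inv"),
          it = format_grade(g[["it"]], "it"),
          dns = format_grade(g[["dns"]], "dns"),
          polyp = format_grade(g[["polyp"]], "polyp"),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) == 0) {
    stats::setNames(as.data.frame(matrix(character(), 0, length(GRADING_COLUMNS))),
                    GRADING_COLUMNS)
  } else {
    do.call(rbind, rows)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Convert a long-format grading data frame to exam objects
#'
#' @param df data frame from [read_gradings_csv()].
#' @return named list of [exam_grading()] objects, one per
#'   (participant, rater), grouped so that `exams_by_participant[[pid]]` is
#'   that participant's rater panel.
#' @export
gradings_to_panels <- function(df) {
  if (nrow(df) == 0) return(list())
  key <- paste(df$participant_id, df$rater_id, sep = "\r")
  panels <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    slots <- stats::setNames(vector("list", 4), SLOTS)
    for (slot in SLOTS) slots[[slot]] <- side_grades()
    for (i in seq_len(nrow(sub))) {
      slot <- slot_name(sub$timepoint[i], sub$side[i])
      slots[[slot]] <- side_grades(inv = sub$inv[i], it = sub$it[i],
                                   dns = sub$dns[i], polyp = sub$polyp[i])
    }
    exam <- exam_grading(sub$participant_id[1], sub$rater_id[1],
                         pre_left = slots$pre_left, pre_right = slots$pre_right,
                         post_left = slots$post_left,
                         post_right = slots$post_right)
    pid <- sub$participant_id[1]
    panels[[pid]] <- c(panels[[pid]], list(exam))
  }
  panels
}

## ---- diagnosis CSVs ----------------------------------------------------

#' Read a diagnosis CSV
#'
#' Columns `participant_id`, `diagnosis` (conditions joined with `"+"`; an
#' empty field or `"Controls"` denotes the empty set), optionally `rater_id`
#' for per-rater files.
#'
#' @param path CSV path.
#' @return data frame with a `sets` list-column of [diagnosis_set()] objects.
#' @export
read_diagnoses_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("participant_id", "diagnosis") %in% names(df))) {
    stop("diagnosis CSV needs columns participant_id, diagnosis", call. = FALSE)
  }
  df$sets <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(parse_diagnosis(df$diagnosis[i]), error = function(e) {
      stop(sprintf("row %d: %s", i + 1L, conditionMessage(e)), call. = FALSE)
    })
  })
  df
}

#' Write a diagnosis CSV
#'
#' @param diagnoses named list of [diagnosis_set()] objects (names are
#'   participant ids).
#' @param path output CSV path.
#' @param empty_as how to render the empty set: `""` (default) or
#'   `"Controls"`.
#' @return `path`, invisibly.
#' @export
write_diagnoses_csv <- function(diagnoses, path, empty_as = "") {
  labels <- vapply(diagnoses, function(d) {
    lab <- format_diagnosis(d)
    if (lab == "Controls") empty_as else lab
  }, "")
  utils::write.csv(
    data.frame(participant_id = names(diagnoses), diagnosis = labels,
               stringsAsFactors = FALSE),
    path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

## ---- configuration -----------------------------------------------------

#' Read a YAML run configuration
#'
#' Recognized keys (all optional, shown with defaults):
#' `rules: {it_reduction_threshold: 0.35, inv_pathology_threshold: 1,
#' dns_asymmetry_min_diff: 1, polyp_presence_min: 1, polyp_timepoint: pre}`,
#' `consensus: {min_votes: 2, defaults: {inv: 0, it: 1, dns: 0, polyp: 0}}`,
#' `ci: {level: 0.95, method: wilson}`,
#' `bootstrap: {n_boot: 1000, level: 0.95}`, `seed`.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return list of class `run_config` with elements `rules` ([rule_params()]),
#'   `defaults` ([fallback_defaults()]), `min_votes`, `ci_level`,
#'   `ci_method`, `n_boot`, `boot_level`, `seed`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  grab <- function(x, key, default) if (is.null(x[[key]])) default else x[[key]]
  rules <- grab(raw, "rules", list())
  cons <- grab(raw, "consensus", list())
  defs <- grab(cons, "defaults", list())
  ci <- grab(raw, "ci", list())
  boot <- grab(raw, "bootstrap", list())
  structure(
    list(
      rules = rule_params(
        it_reduction_threshold = grab(rules, "it_reduction_threshold", 0.35),
        inv_pathology_threshold = grab(rules, "inv_pathology_threshold", 1),
        dns_asymmetry_min_diff = grab(rules, "dns_asymmetry_min_diff", 1),
        polyp_presence_min = grab(rules, "polyp_presence_min", 1),
        polyp_timepoint = grab(rules, "polyp_timepoint", "pre")),
      defaults = fallback_defaults(
        inv = grab(defs, "inv", 0), it = grab(defs, "it", 1),
        dns = grab(defs, "dns", 0), polyp = grab(defs, "polyp", 0)),
      min_votes = grab(cons, "min_votes", 2),
      ci_level = grab(ci, "level", 0.95),
      ci_method = grab(ci, "method", "wilson"),
      n_boot = grab(boot, "n_boot", 1000),
      boot_level = grab(boot, "level", 0.95),
      seed = grab(raw, "seed", 1L)),
    class = "run_config"
  )
}

## ---- workflow commands -------------------------------------------------

#' Diagnose all participants in a grading file
#'
#' The rules-engine workflow: read the long-format grading CSV, aggregate
#' each participant's rater panel into a consensus exam, evaluate the five
#' diagnostic questions, and map through the decision table. Optionally also
#' runs the rules engine per rater (specialist-specific results).
#'
#' @param gradings_csv input grading CSV path.
#' @param out_csv output path; columns `participant_id`, `q1`..`q5` (`T`/`F`),
#'   `diagnosis`.
#' @param config a [read_run_config()] result.
#' @param per_rater if `TRUE`, output one row per (participant, rater) with a
#'   `rater_id` column, applying fallback defaults to individual missing
#'   grades.
#' @return the output data frame, invisibly.
#' @export
cmd_diagnose <- function(gradings_csv, out_csv, config = read_run_config(),
                         per_rater = FALSE) {
  df <- read_gradings_csv(gradings_csv)
  panels <- gradings_to_panels(df)
  rows <- list()
  run_one <- function(exam, rater_id = NULL) {
    qv <- suppressWarnings(evaluate_questions(exam, config$rules))
    d <- lookup_diagnosis(qv)
    row <- data.frame(participant_id = exam$participant_id,
                      stringsAsFactors = FALSE)
    if (!is.null(rater_id)) row$rater_id <- rater_id
    for (q in paste0("q", 1:5)) row[[q]] <- ifelse(qv[[q]], "T", "F")
    row$diagnosis <- format_diagnosis(d)
    row
  }
  for (pid in names(panels)) {
    if (per_rater) {
      for (exam in panels[[pid]]) {
        resolved <- aggregate_exam(list(exam), config$defaults)
        rows[[length(rows) + 1L]] <- run_one(resolved, exam$rater_id)
      }
    } else {
      consensus <- aggregate_exam(panels[[pid]], config$defaults)
      rows[[length(rows) + 1L]] <- run_one(consensus)
    }
  }
  out <- if (length(rows) == 0) {
    cols <- c("participant_id", if (per_rater) "rater_id",
              paste0("q", 1:5), "diagnosis")
    stats::setNames(as.data.frame(matrix(character(), 0, length(cols))), cols)
  } else {
    do.call(rbind, rows)
  }
  utils::write.csv(out, out_csv, row.names = FALSE, quote = TRUE)
  invisible(out)
}

#' Evaluate two diagnosis files against a gold standard
#'
#' Produces the full diagnostic-accuracy report: per condition and method,
#' sensitivity and specificity with CIs; per condition and stratum, the
#' paired matched-pair comparison of the two methods; and the power block
#' for the cohort size.
#'
#' @param diagnoses_a_csv,diagnoses_b_csv diagnosis CSVs for the two methods
#'   (e.g. visual-consensus and rules-engine), aligned by participant id.
#' @param gold_csv gold-standard diagnosis CSV.
#' @param out_json output JSON report path (optional).
#' @param config a [read_run_config()] result.
#' @param effect_size,power_target power-block settings.
#' @return the report as a list, invisibly if `out_json` is given.
#' @export
cmd_evaluate <- function(diagnoses_a_csv, diagnoses_b_csv, gold_csv,
                         out_json = NULL, config = read_run_config(),
                         effect_size = 0.3, power_target = 0.80) {
  gold_df <- read_diagnoses_csv(gold_csv)
  a_df <- read_diagnoses_csv(diagnoses_a_csv)
  b_df <- read_diagnoses_csv(diagnoses_b_csv)
  align <- function(df, who) {
    miss <- setdiff(gold_df$participant_id, df$participant_id)
    if (length(miss) > 0) {
      stop(sprintf("%s is missing participant id(s): %s", who,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    df$sets[match(gold_df$participant_id, df$participant_id)]
  }
  gold <- gold_df$sets
  pred_a <- align(a_df, "method A file")
  pred_b <- align(b_df, "method B file")
  n <- length(gold)

  report <- list(n_participants = n, conditions = list())
  for (cond in ACCURACY_LABELS) {
    acc <- lapply(list(a = pred_a, b = pred_b), function(p) {
      r <- sens_spec_ci(confusion_one_vs_rest(p, gold, cond),
                        level = config$ci_level, method = config$ci_method)
      list(sensitivity = r$sensitivity, specificity = r$specificity,
           ci_sens = as.list(r$ci_sens), ci_spec = as.list(r$ci_spec),
           n_pos = r$n_pos, n_neg = r$n_neg, ci_method = r$ci_method)
    })
    cmp <- lapply(c(sensitivity = "sensitivity", specificity = "specificity"),
                  function(s) {
      pc <- paired_method_comparison(pred_a, pred_b, gold, cond, s)
      list(n10 = pc$n10, n01 = pc$n01, log_odds = pc$log_odds,
           or_estimate = pc$or_estimate, p_value = pc$p_value, flag = pc$flag)
    })
    report$conditions[[cond]] <- list(method_a = acc$a, method_b = acc$b,
                                      comparison = cmp)
  }
  report$power <- list(
    effect_size = effect_size, alpha = 1 - config$ci_level,
    n_total = n,
    achieved_power = achieved_power(effect_size, 1 - config$ci_level, n),
    n_required = required_total_n(effect_size, 1 - config$ci_level,
                                  power_target),
    power_target = power_target)
  report$config <- list(ci_method = config$ci_method,
                        ci_level = config$ci_level, seed = config$seed)
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(report))
  }
  report
}

#' Inter-rater agreement workflow
#'
#' Reads the long-format grading CSV (and optionally a per-rater diagnosis
#' CSV) and writes the agreement table: Krippendorff's alpha with bootstrap
#' CI and agreement band per grading scale and per one-vs-rest diagnosis
#' label.
#'
#' @param gradings_csv grading CSV path.
#' @param diagnoses_csv optional per-rater diagnosis CSV (columns
#'   `participant_id`, `rater_id`, `diagnosis`).
#' @param out_csv output CSV path (optional).
#' @param config a [read_run_config()] result.
#' @return the agreement data frame, invisibly if `out_csv` is given.
#' @export
cmd_agreement <- function(gradings_csv, diagnoses_csv = NULL, out_csv = NULL,
                          config = read_run_config()) {
  gradings <- read_gradings_csv(gradings_csv)
  diagnoses <- if (!is.null(diagnoses_csv)) {
    df <- read_diagnoses_csv(diagnoses_csv)
    if (!"rater_id" %in% names(df)) {
      stop("per-rater diagnosis CSV needs a rater_id column", call. = FALSE)
    }
    df
  }
  out <- interrater_agreement(gradings, diagnoses,
                              n_boot = config$n_boot,
                              level = config$boot_level, seed = config$seed)
  if (!is.null(out_csv)) {
    utils::write.csv(out, out_csv, row.names = FALSE, quote = TRUE)
    return(invisible(out))
  }
  out
}

#' Simulation workflow
#'
#' Generates a synthetic cohort and writes its three artifacts: the
#' long-format grading CSV of all rater panels, the gold-label CSV, and a
#' manifest JSON recording the generating spec and seed.
#'
#' @param out_dir output directory (created if needed).
#' @param spec a [cohort_spec()].
#' @return named list of written paths, invisibly.
#' @export
cmd_simulate <- function(out_dir, spec = cohort_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(spec)
  paths <- list(
    gradings = file.path(out_dir, "gradings.csv"),
    gold = file.path(out_dir, "gold.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_gradings_csv(cohort, paths$gradings)
  write_diagnoses_csv(cohort$gold, paths$gold)
  manifest <- c(unclass(spec)[setdiff(names(unclass(spec)), "prevalence")],
                list(prevalence = as.list(spec$prevalence),
                     tool = "rhinorules",
                     version = as.character(utils::packageVersion("rhinorules"))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
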
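#' Krippendorff's alpha for multi-rater data
#'
#' Chance-corrected inter-rater agreement via the coincidence-matrix
#' formulation: `alpha = 1 - D_observed / D_expected`, valid with any number
#' of raters and with missing ratings. Units with fewer than two non-missing
#' ratings carry no pairable information and are excluded.
#'
#' The difference function depends on the metric:
#' * `nominal` — 0 for identical categories, 1 otherwise;
#' * `ordinal` — squared difference of cumulative coincidence margins
#'   between the two categories' ranks;
#' * `interval` — squared numeric difference.
#'
#' @param ratings units x raters matrix (or data frame) of ratings; `NA` for
#'   missing. Values may be character for the nominal metric; ordinal and
#'   interval require numeric (ordinal uses the sorted unique values as
#'   ranks).
#' @param metric `"nominal"`, `"ordinal"` or `"interval"`.
#' @return numeric alpha (<= 1). When every pairable rating is identical,
#'   expected disagreement is zero and alpha is defined as 1 with attribute
#'   `degenerate = TRUE`.
#' @export
#' @examples
#' m <- rbind(c(1, 1, 1), c(2, 2, 2), c(1, 2, 1))
#' krippendorff_alpha(m, metric = "nominal")
krippendorff_alpha <- function(ratings,
                               metric = c("nominal", "ordinal", "interval")) {
  metric <- match.arg(metric)
  m <- as.matrix(ratings)
  if (ncol(m) < 2) stop("need at least 2 raters", call. = FALSE)
  keep <- rowSums(!is.na(m)) >= 2
  if (!any(keep)) {
    stop("no unit has 2 or more non-missing ratings", call. = FALSE)
  }
  m <- m[keep, , drop = FALSE]

  values <- sort(unique(as.vector(m[!is.na(m)])))
  if (metric %in% c("ordinal", "interval") && !is.numeric(m)) {
    stop(sprintf("%s metric requires numeric ratings", metric), call. = FALSE)
  }
  k <- length(values)

  ## coincidence matrix: o[c, d] = sum over units of
  ## (pairs of (c, d) within the unit) / (m_u - 1)
  o <- matrix(0, k, k)
  for (u in seq_len(nrow(m))) {
    row <- m[u, ]
    row <- row[!is.na(row)]
    mu <- length(row)
    counts <- tabulate(match(row, values), nbins = k)
    contrib <- outer(counts, counts) - diag(counts, k)
    o <- o + contrib / (mu - 1)
  }
  nc <- rowSums(o)
  n <- sum(nc)

  delta2 <- switch(metric,
    nominal = 1 - diag(k),
    interval = outer(values, values, function(a, b) (a - b)^2),
    ordinal = {
      ## cumulative-margin distance between ranks c..d
      d2 <- matrix(0, k, k)
      for (c in seq_len(k)) {
        for (d in seq_len(k)) {
          if (c != d) {
            lo <- min(c, d); hi <- max(c, d)
            d2[c, d] <- (sum(nc[lo:hi]) - (nc[c] + nc[d]) / 2)^2
          }
        }
      }
      d2
    }
  )

  d_obs <- sum(o * delta2)
  d_exp <- sum(outer(nc, nc) * delta2) / (n - 1)
  if (d_exp <= 0) {
    return(structure(1, degenerate = TRUE))
  }
  1 - d_obs / d_exp
}

#' Bootstrap confidence interval for Krippendorff's alpha
#'
#' Resamples units (rows: the sampling units, e.g. participants) with
#' replacement, recomputes alpha on each resample, and returns the percentile
#' interval. Degenerate resamples (zero expected disagreement or fewer than
#' two pairable units) are skipped and counted.
#'
#' @inheritParams krippendorff_alpha
#' @param n_boot number of bootstrap iterations (>= 100; default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed making the interval reproducible.
#' @return list of class `agreement_ci`: `lower`, `upper`, `n_boot`,
#'   `n_skipped`, `level`, `seed`.
#' @export
bootstrap_alpha_ci <- function(ratings, n_boot = 1000, level = 0.95, seed,
                               metric = c("nominal", "ordinal", "interval")) {
  metric <- match.arg(metric)
  stopifnot(n_boot >= 100)
  m <- as.matrix(ratings)
  restore <- save_rng_state()
  set.seed(seed)
  on.exit(restore(), add = TRUE)
  stats_ <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
    a <- tryCatch(krippendorff_alpha(m[idx, , drop = FALSE], metric = metric),
                  error = function(e) NA_real_)
    if (!is.na(a) && isTRUE(attr(a, "degenerate"))) a <- NA_real_
    ## a perfect-agreement original matrix is legitimately degenerate: keep 1
    stats_[b] <- as.numeric(a)
  }
  full <- krippendorff_alpha(m, metric = metric)
  if (isTRUE(attr(full, "degenerate"))) {
    ## no variability is possible: the interval collapses at 1
    stats_[is.na(stats_)] <- 1
  }
  ok <- stats_[!is.na(stats_)]
  if (length(ok) == 0) stop("all bootstrap resamples were degenerate", call. = FALSE)
  qs <- stats::quantile(ok, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(
    list(lower = qs[1], upper = qs[2], n_boot = n_boot,
         n_skipped = sum(is.na(stats_)), level = level, seed = seed),
    class = "agreement_ci"
  )
}

## save/restore the global RNG state around seeded helpers
save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() suppressWarnings(
      rm(".Random.seed", envir = globalenv())
    )
  }
}

#' Classify an agreement coefficient into the study's bands
#'
#' Bands: poor (alpha < 0.667), moderate (0.667 <= alpha < 0.800),
#' satisfactory (0.800 <= alpha < 1.000), perfect (alpha = 1.000 within
#' 1e-12). The bands partition (-Inf, 1].
#'
#' @param alpha agreement coefficient (<= 1).
#' @return one of `"poor"`, `"moderate"`, `"satisfactory"`, `"perfect"`.
#' @export
#' @examples
#' classify_agreement(0.863) # satisfactory
classify_agreement <- function(alpha) {
  alpha <- as.numeric(alpha)
  stopifnot(length(alpha) == 1, !is.na(alpha), alpha <= 1 + 1e-12)
  if (abs(alpha - 1) < 1e-12) "perfect"
  else if (alpha >= 0.800) "satisfactory"
  else if (alpha >= 0.667) "moderate"
  else "poor"
}

#' Full agreement analysis for one ratings matrix
#'
#' Convenience wrapper combining [krippendorff_alpha()],
#' [bootstrap_alpha_ci()] and [classify_agreement()].
#'
#' @inheritParams bootstrap_alpha_ci
#' @return list of class `agreement_result`: `alpha`, `ci` (lower, upper),
#'   `n_boot`, `n_skipped`, `seed`, `level` (band label), `metric`.
#' @export
agreement_result <- function(ratings, metric = c("nominal", "ordinal", "interval"),
                             n_boot = 1000, level = 0.95, seed = 1L) {
  metric <- match.arg(metric)
  alpha <- krippendorff_alpha(ratings, metric = metric)
  ci <- bootstrap_alpha_ci(ratings, n_boot = n_boot, level = level,
                           seed = seed, metric = metric)
  structure(
    list(alpha = as.numeric(alpha), ci = c(lower = ci$lower, upper = ci$upper),
         n_boot = n_boot, n_skipped = ci$n_skipped, seed = seed,
         level = classify_agreement(alpha), metric = metric),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> alpha=%.3f (%.3f-%.3f), %s agreement [%s, %d boot]\n",
              x$alpha, x$ci["lower"], x$ci["upper"], x$level, x$metric, x$n_boot))
  invisible(x)
}

#' Inter-rater agreement report for gradings and diagnoses
#'
#' Builds one ratings matrix per grading scale (units are
#' participant x side x timepoint observations; ordinal metric) and one per
#' one-vs-rest diagnosis label (units are participants, values are presence
#' indicators; nominal metric), and computes alpha with a bootstrap CI and
#' agreement band for each.
#'
#' @param gradings long-format grading data frame (see
#'   [read_gradings_csv()]).
#' @param diagnoses optional per-rater diagnosis data frame with columns
#'   `participant_id`, `rater_id`, `diagnosis`.
#' @param n_boot,level,seed bootstrap settings (see [bootstrap_alpha_ci()]).
#' @param grade_metric metric for the grading scales (default `"ordinal"`).
#' @return data frame with columns `category`, `alpha`, `ci_lower`,
#'   `ci_upper`, `agreement`.
#' @export
interrater_agreement <- function(gradings, diagnoses = NULL,
                                 n_boot = 1000, level = 0.95, seed = 1L,
                                 grade_metric = "ordinal") {
  raters <- sort(unique(gradings$rater_id))
  rows <- list()
  unit_key <- with(gradings, paste(participant_id, timepoint, side, sep = "|"))
  units <- unique(unit_key)
  for (scale in SCALES) {
    mat <- matrix(NA_real_, length(units), length(raters),
                  dimnames = list(units, raters))
    idx <- cbind(match(unit_key, units), match(gradings$rater_id, raters))
    mat[idx] <- gradings[[scale]]
    res <- agreement_result(mat, metric = grade_metric, n_boot = n_boot,
                            level = level, seed = seed)
    rows[[length(rows) + 1L]] <- data.frame(
      category = scale, alpha = res$alpha,
      ci_lower = unname(res$ci["lower"]), ci_upper = unname(res$ci["upper"]),
      agreement = res$level, stringsAsFactors = FALSE)
  }
  if (!is.null(diagnoses)) {
    pids <- sort(unique(diagnoses$participant_id))
    draters <- sort(unique(diagnoses$rater_id))
    sets <- lapply(diagnoses$diagnosis, parse_diagnosis)
    for (label in ACCURACY_LABELS) {
      mat <- matrix(NA_real_, length(pids), length(draters),
                    dimnames = list(pids, draters))
      ind <- vapply(sets, label_positive, logical(1), condition = label)
      idx <- cbind(match(diagnoses$participant_id, pids),
                   match(diagnoses$rater_id, draters))
      mat[idx] <- as.numeric(ind)
      res <- agreement_result(mat, metric = "nominal", n_boot = n_boot,
                              level = level, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        category = label, alpha = res$alpha,
        ci_lower = unname(res$ci["lower"]), ci_upper = unname(res$ci["upper"]),
        agreement = res$level, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
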
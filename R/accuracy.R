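## One-vs-rest labels: the four conditions plus "Controls" (positive when the
## diagnosis set is empty).
ACCURACY_LABELS <- c("AR", "CRSsNP", "CRSwNP", "DNS", "Controls")

## Does this diagnosis set count as positive for a one-vs-rest label?
label_positive <- function(dset, condition) {
  dset <- unclass(diagnosis_set(unclass(dset)))
  if (condition == "Controls") length(dset) == 0 else condition %in% dset
}

#' One-vs-rest confusion counts for a condition
#'
#' Reduces multi-label predictions to a binary problem for one condition.
#' `"Controls"` is treated as its own one-vs-rest label: a participant is
#' gold-positive for Controls when the gold diagnosis set is empty.
#'
#' @param predicted,gold lists of [diagnosis_set()] objects (or character
#'   vectors), aligned by participant and of equal length.
#' @param condition one of `"AR"`, `"CRSsNP"`, `"CRSwNP"`, `"DNS"`,
#'   `"Controls"`.
#' @return list of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`,
#'   `condition`.
#' @export
confusion_one_vs_rest <- function(predicted, gold, condition) {
  condition <- match.arg(condition, ACCURACY_LABELS)
  if (length(predicted) != length(gold)) {
    stop(sprintf("predicted (%d) and gold (%d) differ in length",
                 length(predicted), length(gold)), call. = FALSE)
  }
  p <- vapply(predicted, label_positive, logical(1), condition = condition)
  g <- vapply(gold, label_positive, logical(1), condition = condition)
  structure(
    list(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g),
         tn = sum(!p & !g), condition = condition),
    class = "confusion_counts"
  )
}

## Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

## Clopper-Pearson exact interval via the beta quantile form.
clopper_pearson_ci <- function(x, n, level) {
  a <- (1 - level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Sensitivity and specificity with confidence intervals
#'
#' Point estimates are tp/(tp+fn) and tn/(tn+fp); intervals are Wilson score
#' (default) or Clopper-Pearson exact. An interval whose denominator is zero
#' is flagged undefined (`NA` estimates) rather than raising an error.
#'
#' @param counts a [confusion_one_vs_rest()] result.
#' @param level confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"clopper-pearson"`.
#' @return list of class `accuracy_result`: `sensitivity`, `specificity`,
#'   `ci_sens`, `ci_spec` (each `c(lower, upper)`), `n_pos`, `n_neg`,
#'   `ci_method`, `condition`, and logical flags `sens_defined`,
#'   `spec_defined`.
#' @export
sens_spec_ci <- function(counts, level = 0.95,
                         method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "confusion_counts"))
  ci_fun <- if (method == "wilson") wilson_ci else clopper_pearson_ci
  n_pos <- counts$tp + counts$fn
  n_neg <- counts$tn + counts$fp
  one <- function(x, n) {
    if (n == 0) {
      list(est = NA_real_, ci = c(lower = NA_real_, upper = NA_real_),
           defined = FALSE)
    } else {
      list(est = x / n, ci = ci_fun(x, n, level), defined = TRUE)
    }
  }
  sens <- one(counts$tp, n_pos)
  spec <- one(counts$tn, n_neg)
  structure(
    list(sensitivity = sens$est, specificity = spec$est,
         ci_sens = sens$ci, ci_spec = spec$ci,
         n_pos = n_pos, n_neg = n_neg,
         sens_defined = sens$defined, spec_defined = spec$defined,
         ci_method = method, level = level, condition = counts$condition),
    class = "accuracy_result"
  )
}

#' @export
print.accuracy_result <- function(x, ...) {
  fmt <- function(e, ci) {
    if (is.na(e)) "undefined" else
      sprintf("%.1f%% (%.1f-%.1f%%)", 100 * e, 100 * ci[1], 100 * ci[2])
  }
  cat(sprintf("<accuracy_result> %s: sens %s [n=%d], spec %s [n=%d], %s CI\n",
              x$condition, fmt(x$sensitivity, x$ci_sens), x$n_pos,
              fmt(x$specificity, x$ci_spec), x$n_neg, x$ci_method))
  invisible(x)
}

#' Paired comparison of two diagnostic methods
#'
#' Within the chosen gold stratum (gold-positives for sensitivity,
#' gold-negatives for specificity), each participant contributes a matched
#' pair: did method A classify them correctly, did method B? The
#' method-effect log odds ratio is estimated by conditional maximum
#' likelihood for 1:1 matched pairs, which depends on the discordant pairs
#' only: `log_odds = log(n10/n01)`, `se = sqrt(1/n10 + 1/n01)`, with a
#' two-sided Wald p-value. When the two methods make identical calls in the
#' stratum (`n10 = n01 = 0`) the comparison is flagged `"identical"`; an
#' empty stratum is flagged `"empty"`; one-sided discordance (exactly one of
#' `n10`, `n01` zero) is flagged `"one_sided"` (infinite log odds, p
#' undefined under the Wald form).
#'
#' @param pred_a,pred_b,gold aligned lists of [diagnosis_set()] objects.
#' @param condition one-vs-rest label (see [confusion_one_vs_rest()]).
#' @param stratum `"sensitivity"` (gold-positives) or `"specificity"`
#'   (gold-negatives).
#' @return list of class `paired_comparison`: `n11`, `n10`, `n01`, `n00`,
#'   `log_odds`, `or_estimate`, `se`, `p_value`, `flag` (`"ok"`,
#'   `"identical"`, `"one_sided"` or `"empty"`), `condition`, `stratum`.
#' @export
paired_method_comparison <- function(pred_a, pred_b, gold, condition,
                                     stratum = c("sensitivity", "specificity")) {
  stratum <- match.arg(stratum)
  condition <- match.arg(condition, ACCURACY_LABELS)
  if (length(pred_a) != length(gold) || length(pred_b) != length(gold)) {
    stop("pred_a, pred_b and gold must be aligned lists of equal length",
         call. = FALSE)
  }
  g <- vapply(gold, label_positive, logical(1), condition = condition)
  keep <- if (stratum == "sensitivity") g else !g
  ## a "hit" is a correct call: condition present for gold-positives, absent
  ## for gold-negatives
  hit <- function(preds) {
    p <- vapply(preds, label_positive, logical(1), condition = condition)
    if (stratum == "sensitivity") p[keep] else !p[keep]
  }
  a <- hit(pred_a)
  b <- hit(pred_b)
  n11 <- sum(a & b); n10 <- sum(a & !b); n01 <- sum(!a & b); n00 <- sum(!a & !b)
  base <- list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
               condition = condition, stratum = stratum)
  res <- if (length(a) == 0) {
    c(base, list(log_odds = NA_real_, or_estimate = NA_real_, se = NA_real_,
                 p_value = NA_real_, flag = "empty"))
  } else if (n10 == 0 && n01 == 0) {
    c(base, list(log_odds = NA_real_, or_estimate = NA_real_, se = NA_real_,
                 p_value = NA_real_, flag = "identical"))
  } else if (n10 == 0 || n01 == 0) {
    c(base, list(log_odds = ifelse(n10 > 0, Inf, -Inf),
                 or_estimate = ifelse(n10 > 0, Inf, 0), se = Inf,
                 p_value = NA_real_, flag = "one_sided"))
  } else {
    log_odds <- log(n10 / n01)
    se <- sqrt(1 / n10 + 1 / n01)
    c(base, list(log_odds = log_odds, or_estimate = n10 / n01, se = se,
                 p_value = 2 * stats::pnorm(-abs(log_odds / se)), flag = "ok"))
  }
  structure(res, class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s (%s): n10=%d n01=%d, flag=%s",
              x$condition, x$stratum, x$n10, x$n01, x$flag))
  if (identical(x$flag, "ok")) {
    cat(sprintf(", OR=%.3f, p=%.3g", x$or_estimate, x$p_value))
  }
  cat("\n")
  invisible(x)
}

#' Required total sample size for a two-group comparison of proportions
#'
#' Normal-approximation sample size for detecting a Cohen-type effect size
#' `h` between two equal groups at two-sided level `alpha` with the given
#' power: per-group n = ((z_(1-alpha/2) + z_power) / h)^2, total =
#' ceiling(2 x per-group n).
#'
#' @param effect_size Cohen-type effect size (default 0.3, a moderate
#'   difference).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.80).
#' @return integer total sample size.
#' @export
#' @examples
#' required_total_n() # 175
required_total_n <- function(effect_size = 0.3, alpha = 0.05, power = 0.80) {
  stopifnot(effect_size > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  per_group <- ((z_a + z_b) / effect_size)^2
  as.integer(ceiling(2 * per_group))
}

#' Achieved power at a given total sample size
#'
#' Power of the two-group proportion comparison at effect size `h` with
#' `n_total` participants split into two equal groups:
#' `power = pnorm(h * sqrt(n_total / 2) - z_(1-alpha/2))`.
#'
#' @param effect_size Cohen-type effect size.
#' @param alpha two-sided significance level.
#' @param n_total total sample size (>= 2).
#' @return power in (0, 1).
#' @export
#' @examples
#' achieved_power(n_total = 71) # about 0.43
achieved_power <- function(effect_size = 0.3, alpha = 0.05, n_total) {
  stopifnot(effect_size >= 0, alpha > 0, alpha < 1, n_total >= 2)
  z_a <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(effect_size * sqrt(n_total / 2) - z_a)
}
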
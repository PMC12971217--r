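dsets <- function(...) lapply(list(...), parse_diagnosis)

test_that("one-vs-rest confusion counts per condition and for Controls", {
  cc <- confusion_one_vs_rest(dsets("AR", "AR", ""), dsets("AR", "", ""), "AR")
  expect_equal(cc[c("tp", "fp", "fn", "tn")],
               list(tp = 1, fp = 1, fn = 0, tn = 1))

  gold <- dsets("AR+DNS", "CRSwNP", "", "DNS")
  same <- confusion_one_vs_rest(gold, gold, "DNS")
  expect_equal(same$fp + same$fn, 0)

  ctrl <- confusion_one_vs_rest(dsets("", "AR"), dsets("", ""), "Controls")
  expect_equal(ctrl[c("tp", "fn", "fp", "tn")],
               list(tp = 1, fn = 1, fp = 0, tn = 0))

  expect_error(confusion_one_vs_rest(dsets("AR"), dsets("AR", ""), "AR"),
               "length")
})

test_that("confusion margins always partition the cohort", {
  set.seed(11)
  labels <- c("", "AR", "DNS", "AR+DNS", "CRSwNP", "CRSsNP+DNS")
  for (i in 1:10) {
    n <- sample(5:30, 1)
    pred <- dsets_list <- lapply(sample(labels, n, TRUE), parse_diagnosis)
    gold <- lapply(sample(labels, n, TRUE), parse_diagnosis)
    for (cond in c("AR", "CRSsNP", "CRSwNP", "DNS", "Controls")) {
      cc <- confusion_one_vs_rest(pred, gold, cond)
      expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, n)
      gp <- sum(vapply(gold, function(g) {
        if (cond == "Controls") length(g) == 0 else cond %in% g
      }, logical(1)))
      expect_equal(cc$tp + cc$fn, gp)
    }
  }
})

test_that("sensitivity/specificity point estimates and Wilson interval", {
  cc <- structure(list(tp = 10, fn = 4, tn = 20, fp = 5, condition = "AR"),
                  class = "confusion_counts")
  r <- sens_spec_ci(cc)
  expect_equal(r$sensitivity, 10 / 14, tolerance = 1e-12)
  expect_equal(r$specificity, 20 / 25, tolerance = 1e-12)
  expect_equal(unname(r$ci_sens), c(0.4535, 0.8828), tolerance = 1e-3)
  expect_true(r$ci_sens[1] <= r$sensitivity && r$sensitivity <= r$ci_sens[2])

  r0 <- sens_spec_ci(structure(
    list(tp = 0, fn = 5, tn = 1, fp = 0, condition = "AR"),
    class = "confusion_counts"))
  expect_equal(r0$sensitivity, 0)
  expect_equal(unname(r0$ci_sens[1]), 0)
})

test_that("zero denominators are flagged undefined, not errors", {
  cc <- structure(list(tp = 0, fn = 0, tn = 3, fp = 1, condition = "AR"),
                  class = "confusion_counts")
  r <- sens_spec_ci(cc)
  expect_false(r$sens_defined)
  expect_true(is.na(r$sensitivity))
  expect_true(r$spec_defined)
})

test_that("Clopper-Pearson interval matches binom.test", {
  for (xn in list(c(10, 14), c(3, 20), c(0, 8), c(8, 8))) {
    cc <- structure(list(tp = xn[1], fn = xn[2] - xn[1], tn = 0, fp = 1,
                         condition = "AR"), class = "confusion_counts")
    r <- sens_spec_ci(cc, method = "clopper-pearson")
    bt <- binom.test(xn[1], xn[2])$conf.int
    expect_equal(unname(r$ci_sens), as.numeric(bt), tolerance = 1e-9)
  }
})

test_that("paired comparison reproduces the discordant-pair closed form", {
  # 10 gold-positives hit by A only, 5 by B only, plus concordant pairs
  gold <- rep(dsets("AR"), 20)
  pred_a <- c(rep(dsets("AR"), 12), rep(dsets(""), 8))
  pred_b <- c(rep(dsets("AR"), 2), rep(dsets(""), 10),
              rep(dsets("AR"), 5), rep(dsets(""), 3))
  pc <- paired_method_comparison(pred_a, pred_b, gold, "AR", "sensitivity")
  expect_equal(pc[c("n11", "n10", "n01", "n00")],
               list(n11 = 2, n10 = 10, n01 = 5, n00 = 3))
  expect_equal(pc$or_estimate, 2.0)
  expect_equal(pc$log_odds, log(2), tolerance = 1e-12)
  expect_equal(pc$se, sqrt(1 / 10 + 1 / 5), tolerance = 1e-12)
  expect_equal(pc$p_value, 0.205689, tolerance = 1e-5)
  expect_equal(pc$flag, "ok")
})

test_that("symmetric discordance gives p = 1 and swapping methods negates the log odds", {
  gold <- rep(dsets("DNS"), 14)
  pred_a <- c(rep(dsets("DNS"), 7), rep(dsets(""), 7))
  pred_b <- c(rep(dsets(""), 7), rep(dsets("DNS"), 7))
  pc <- paired_method_comparison(pred_a, pred_b, gold, "DNS", "sensitivity")
  expect_equal(pc$n10, 7)
  expect_equal(pc$n01, 7)
  expect_equal(pc$log_odds, 0)
  expect_equal(pc$p_value, 1.0)

  swapped <- paired_method_comparison(pred_b, pred_a, gold, "DNS", "sensitivity")
  expect_equal(swapped$log_odds, -pc$log_odds)
  expect_equal(swapped$p_value, pc$p_value)
})

test_that("identical predictions and empty strata are flagged", {
  gold <- dsets("CRSwNP", "CRSwNP", "")
  pred <- dsets("CRSwNP", "", "")
  pc <- paired_method_comparison(pred, pred, gold, "CRSwNP", "sensitivity")
  expect_equal(pc$flag, "identical")
  expect_true(is.na(pc$p_value))

  none <- paired_method_comparison(pred, pred, dsets("", "", ""), "CRSwNP",
                                   "sensitivity")
  expect_equal(none$flag, "empty")
})

test_that("specificity stratum scores absence of the condition as a hit", {
  gold <- dsets("", "", "AR")
  pred_a <- dsets("AR", "", "AR") # one false positive
  pred_b <- dsets("", "", "AR")   # clean
  pc <- paired_method_comparison(pred_a, pred_b, gold, "AR", "specificity")
  expect_equal(pc$n01, 1) # B correct where A was not
  expect_equal(pc$n10, 0)
  expect_equal(pc$flag, "one_sided")
})

test_that("closed-form matched-pair estimate equals clogit on the same data", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  n10 <- 9; n01 <- 4
  pairs <- data.frame(
    pair = rep(seq_len(n10 + n01), each = 2),
    method = rep(c(1, 0), times = n10 + n01),
    hit = c(rep(c(1, 0), n10), rep(c(0, 1), n01)))
  fit <- survival::clogit(hit ~ method + survival::strata(pair), data = pairs)
  expect_equal(unname(coef(fit)), log(n10 / n01), tolerance = 1e-6)
  expect_equal(unname(sqrt(vcov(fit)[1, 1])), sqrt(1 / n10 + 1 / n01),
               tolerance = 1e-6)
})

test_that("power closed forms reproduce the study design anchors", {
  expect_equal(required_total_n(0.3, 0.05, 0.80), 175L)
  expect_equal(required_total_n(0.6, 0.05, 0.80), 44L)
  expect_equal(round(100 * achieved_power(0.3, 0.05, 71)), 43)
  expect_equal(achieved_power(0.3, 0.05, 175), 0.80, tolerance = 0.005)
  # null effect: power collapses to the one-sided type-I mass
  expect_equal(achieved_power(0, 0.05, 100), 0.025, tolerance = 1e-10)
})

test_that("power is monotone and inverse-consistent with the sample size", {
  for (h in c(0.2, 0.3, 0.5)) {
    for (target in c(0.7, 0.8, 0.9)) {
      n <- required_total_n(h, 0.05, target)
      expect_gte(achieved_power(h, 0.05, n), target)
    }
  }
  ns <- c(20, 50, 100, 200, 400)
  expect_true(all(diff(achieved_power(0.3, 0.05, ns)) > 0))
  hs <- c(0.1, 0.2, 0.3, 0.5, 0.8)
  expect_true(all(diff(vapply(hs, achieved_power, 0, alpha = 0.05,
                              n_total = 100)) > 0))
})
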
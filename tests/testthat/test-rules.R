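test_that("q1 requires polyps on both sides at the pre timepoint", {
  expect_true(q1_bilateral_polyps(make_exam(polyp_pre = c(2, 1))))
  expect_false(q1_bilateral_polyps(make_exam(polyp_pre = c(0, 0))))
  # unilateral polyps: FALSE plus an exclusion-review warning
  expect_warning(
    res <- q1_bilateral_polyps(make_exam(polyp_pre = c(3, 0))),
    "unilateral"
  )
  expect_false(res)
})

test_that("q1 can optionally consider the post timepoint", {
  e <- make_exam(polyp_pre = c(0, 0), polyp_post = c(1, 1))
  expect_false(suppressWarnings(q1_bilateral_polyps(e)))
  expect_true(q1_bilateral_polyps(e, rule_params(polyp_timepoint = "pre_or_post")))
})

test_that("q2 applies the 35% bilateral reduction threshold", {
  expect_true(q2_decongestant_response(
    make_exam(it_pre = c(4, 3), it_post = c(2, 1)))) # 0.50, 0.667
  expect_false(q2_decongestant_response(
    make_exam(it_pre = c(3, 4), it_post = c(2, 2)))) # 0.333 on the left
  expect_false(q2_decongestant_response(
    make_exam(it_pre = c(2, 2), it_post = c(2, 2)))) # zero reduction
  # rebound congestion (post > pre) counts as zero response
  expect_false(q2_decongestant_response(
    make_exam(it_pre = c(2, 4), it_post = c(3, 1))))
  # unilateral response is not enough
  expect_false(q2_decongestant_response(
    make_exam(it_pre = c(4, 2), it_post = c(1, 2))))
})

test_that("q2 threshold is monotone: raising it never turns FALSE into TRUE", {
  exams <- list(
    make_exam(it_pre = c(4, 3), it_post = c(2, 1)),
    make_exam(it_pre = c(3, 3), it_post = c(2, 2)),
    make_exam(it_pre = c(2, 2), it_post = c(1, 1)),
    make_exam(it_pre = c(4, 4), it_post = c(3, 3))
  )
  thresholds <- c(0.1, 0.25, 0.35, 0.5, 0.75, 0.9)
  for (e in exams) {
    vals <- vapply(thresholds, function(t) {
      q2_decongestant_response(e, rule_params(it_reduction_threshold = t))
    }, logical(1))
    expect_true(all(diff(as.integer(vals)) <= 0)) # non-increasing in threshold
  }
})

test_that("q3 detects post-decongestant septal asymmetry of one grade or more", {
  expect_true(q3_dns_asymmetry(make_exam(dns_post = c(2, 0))))
  expect_true(q3_dns_asymmetry(make_exam(dns_post = c(0, 3))))
  expect_false(q3_dns_asymmetry(make_exam(dns_post = c(1, 1))))
  expect_false(q3_dns_asymmetry(make_exam(dns_post = c(0, 0))))
  # consensus averaging can produce fractional differences
  expect_false(q3_dns_asymmetry(make_exam(dns_post = c(1.5, 1))))
  expect_true(q3_dns_asymmetry(make_exam(dns_post = c(2.5, 1.5))))
})

test_that("q4/q5 require INV >= 1 bilaterally; certainty grades stay below", {
  expect_true(q4_inv_pre(make_exam(inv_pre = c(1, 2))))
  expect_false(q4_inv_pre(make_exam(inv_pre = c(2 / 3, 2 / 3))))
  expect_false(q4_inv_pre(make_exam(inv_pre = c(1, 0))))
  expect_true(q5_inv_post(make_exam(inv_post = c(2, 1))))
  expect_false(q5_inv_post(make_exam(inv_post = c(1, 1 / 3))))
})

test_that("questions demand resolved grades and name the failing question", {
  e <- make_exam()
  e$pre_left[["it"]] <- NA_real_
  expect_error(q2_decongestant_response(e), "q2.*not visualized")
  e2 <- make_exam()
  e2$post_right[["dns"]] <- NA_real_
  expect_error(q3_dns_asymmetry(e2), "q3")
  expect_error(evaluate_questions(e), "q2")
})

test_that("the noiseless single-condition patterns yield their question vectors", {
  expect_equal(unname(evaluate_questions(control_exam())), rep(FALSE, 5))
  expect_equal(unname(evaluate_questions(ar_exam())),
               c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(evaluate_questions(crswnp_exam())),
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(unname(evaluate_questions(crssnp_exam())),
               c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(evaluate_questions(dns_exam())),
               c(FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("single-condition exams map to their single-condition diagnoses", {
  expect_equal(format_diagnosis(diagnose(control_exam())), "Controls")
  expect_equal(format_diagnosis(diagnose(ar_exam())), "AR")
  expect_equal(format_diagnosis(diagnose(crswnp_exam())), "CRSwNP")
  expect_equal(format_diagnosis(diagnose(crssnp_exam())), "CRSsNP")
  expect_equal(format_diagnosis(diagnose(dns_exam())), "DNS")
})

test_that("the decision table is total and the lookup matches selected rows", {
  tbl <- decision_table()
  expect_equal(nrow(tbl), 32)
  keys <- apply(tbl[paste0("q", 1:5)], 1, paste, collapse = "")
  expect_equal(anyDuplicated(keys), 0L)

  expect_equal(format_diagnosis(lookup_diagnosis(c(T, T, F, F, F))), "CRSwNP")
  expect_equal(format_diagnosis(lookup_diagnosis(c(F, T, T, T, T))),
               "AR+CRSsNP+DNS")
  expect_equal(format_diagnosis(lookup_diagnosis(c(F, F, F, F, F))), "Controls")
  expect_equal(format_diagnosis(lookup_diagnosis(c(F, T, T, T, F))), "AR+DNS")
})

test_that("with q1 TRUE the diagnosis is invariant to q4 and q5", {
  for (q2 in c(TRUE, FALSE)) {
    for (q3 in c(TRUE, FALSE)) {
      outs <- character()
      for (q4 in c(TRUE, FALSE)) {
        for (q5 in c(TRUE, FALSE)) {
          d <- lookup_diagnosis(c(TRUE, q2, q3, q4, q5))
          outs <- c(outs, format_diagnosis(d))
        }
      }
      # q4/q5 only matter through AR (q2 & q4); with q2 fixed the only
      # variation allowed is the AR component
      expect_true(length(unique(gsub("AR\\+?", "", outs))) == 1)
    }
  }
})

test_that("the shipped decision-table CSV matches the embedded copy", {
  path <- system.file("extdata", "decision_table.csv", package = "rhinorules")
  expect_true(nzchar(path))
  tbl <- read_decision_table(path)
  expect_equal(tbl, decision_table(), ignore_attr = TRUE)

  # a tampered copy is rejected
  tmp <- withr::local_tempfile(fileext = ".csv")
  raw <- read.csv(path, colClasses = "character")
  raw$diagnosis[raw$diagnosis == "AR"] <- "DNS"
  write.csv(raw, tmp, row.names = FALSE)
  expect_error(read_decision_table(tmp), "diverges")
})

test_that("diagnosis sets are canonical, unordered, and serialize stably", {
  expect_equal(unclass(diagnosis_set(c("DNS", "AR"))), c("AR", "DNS"),
               ignore_attr = TRUE)
  expect_equal(format_diagnosis(diagnosis_set(c("DNS", "CRSwNP", "AR"))),
               "AR+CRSwNP+DNS")
  expect_equal(format_diagnosis(diagnosis_set()), "Controls")
  expect_equal(unclass(parse_diagnosis("Controls")), character(),
               ignore_attr = TRUE)
  expect_equal(unclass(parse_diagnosis("")), character(), ignore_attr = TRUE)
  expect_equal(unclass(parse_diagnosis("DNS+AR")), c("AR", "DNS"),
               ignore_attr = TRUE)
  expect_error(diagnosis_set("NasalPolyps"), "unknown condition")
})

test_that("diagnose is pure: identical inputs give identical outputs", {
  e <- ar_exam()
  expect_identical(diagnose(e), diagnose(e))
})
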
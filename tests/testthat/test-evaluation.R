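test_that("occurrence counting separates instances from encounters", {
  m <- rbind(ann(c("E1", "E1", "E2"), "headache"),
             ann("E3", "nausea"))
  occ <- count_occurrences(m, "headache")
  expect_equal(occ$concept_occurrences, 3L)
  expect_equal(occ$encounter_occurrences, 2L)

  expect_equal(count_occurrences(ann(character(), "headache"), "headache"),
               list(concept_id = "headache", concept_occurrences = 0L,
                    encounter_occurrences = 0L))

  solo <- ann(rep("E1", 5), "headache")
  occ5 <- count_occurrences(solo, "headache")
  expect_equal(c(occ5$concept_occurrences, occ5$encounter_occurrences), c(5L, 1L))

  # negated mentions never count
  neg <- ann(c("E1", "E2"), "headache", asserted = FALSE)
  expect_equal(count_occurrences(neg, "headache")$concept_occurrences, 0L)
})

test_that("encounter-level metrics follow the confusion-set arithmetic", {
  encs <- sprintf("E%02d", 1:20)
  ref <- ann(encs[1:10], "migraine")
  pred <- ann(c(encs[1:6], encs[11:12]), "migraine")
  m <- compute_metrics(pred, ref, "migraine", encs)
  expect_equal(c(m$tp, m$fn, m$fp), c(6L, 4L, 2L))
  expect_equal(m$recall, 0.6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 2 * 0.45 / 1.35)

  ident <- compute_metrics(ref, ref, "migraine", encs)
  expect_equal(c(ident$recall, ident$precision, ident$f1), c(1, 1, 1))

  # zero predictions against a nonempty reference: recall 0, precision NA, F1 0
  none <- compute_metrics(ann(character(), "migraine"), ref, "migraine", encs)
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
  expect_equal(none$f1, 0)

  # mismatched encounter universes are fatal
  expect_error(compute_metrics(ann("E99", "migraine"), ref, "migraine", encs),
               "universe")
})

test_that("metrics match a brute-force double-loop oracle on random sets", {
  set.seed(1234)
  encs <- sprintf("E%02d", 1:12)
  for (i in 1:120) {
    ref <- ann_from_presence(stats::runif(12) < stats::runif(1), encs, "x")
    pred <- ann_from_presence(stats::runif(12) < stats::runif(1), encs, "x")
    m <- compute_metrics(pred, ref, "x", encs)
    o <- metrics_oracle(pred, ref, "x", encs)
    expect_equal(list(tp = m$tp, fp = m$fp, fn = m$fn), o)
    # conservation: tp + fn equals reference encounter occurrences
    expect_equal(m$tp + m$fn, count_occurrences(ref, "x")$encounter_occurrences)
  }
})

test_that("F1 is the harmonic mean with the zero convention", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0.5, 0.5), 0.5)
  expect_equal(f1_score(0.75, 0.6), 2 * 0.45 / 1.35)
  expect_equal(f1_score(0, 0.9), 0)
  # bounded by min and max of its arguments when both positive
  set.seed(8)
  p <- stats::runif(30, 0.01, 1); r <- stats::runif(30, 0.01, 1)
  f <- mapply(f1_score, p, r)
  expect_true(all(f >= pmin(p, r) - 1e-12 & f <= pmax(p, r) + 1e-12))
})

test_that("arm comparison reproduces recall differences and the chi-square", {
  mt <- metric_result("migraine", "traditional", tp = 666, fp = 0, fn = 334)
  ma <- metric_result("migraine", "advanced", tp = 968, fp = 0, fn = 32)
  cmp <- compare_arms(mt, ma)
  expect_equal(cmp$abs_recall_difference, 30.2, tolerance = 1e-9)

  same <- compare_arms(metric_result("x", "traditional", 10, 0, 5),
                       metric_result("x", "advanced", 10, 0, 5))
  expect_equal(same$chi2_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$abs_recall_difference, 0)

  big <- compare_arms(metric_result("x", "traditional", 30, 0, 70),
                      metric_result("x", "advanced", 80, 0, 20))
  tab <- matrix(c(30, 70, 80, 20), 2, byrow = TRUE)
  expect_equal(big$chi2_statistic, chi2_closed_form(tab), tolerance = 1e-9)
  expect_lt(big$p_value, 0.001)
  expect_true(big$success)
})

test_that("protocol success requires 80% advanced recall or a 25-point gap", {
  # high advanced recall, small gap -> success
  s1 <- compare_arms(metric_result("x", "traditional", 80, 0, 20),
                     metric_result("x", "advanced", 90, 0, 10))
  expect_true(s1$success)
  # low advanced recall, large gap -> success
  s2 <- compare_arms(metric_result("x", "traditional", 10, 0, 90),
                     metric_result("x", "advanced", 60, 0, 40))
  expect_true(s2$success)
  # neither -> failure
  s3 <- compare_arms(metric_result("x", "traditional", 60, 0, 40),
                     metric_result("x", "advanced", 70, 0, 30))
  expect_false(s3$success)
})

test_that("evaluation reports are complete, deterministic, and render NA as null", {
  concepts <- c("migraine", "headache")
  metrics <- list(
    metric_result("migraine", "traditional", 5, 1, 5),
    metric_result("migraine", "advanced", 9, 0, 1),
    metric_result("headache", "traditional", 0, 0, 10),
    metric_result("headache", "advanced", 8, 1, 2))
  comparisons <- list(compare_arms(metrics[[1]], metrics[[2]]),
                      compare_arms(metrics[[3]], metrics[[4]]))
  occurrences <- list(
    list(concept_id = "migraine", concept_occurrences = 12L,
         encounter_occurrences = 10L),
    list(concept_id = "headache", concept_occurrences = 11L,
         encounter_occurrences = 10L))
  rep1 <- evaluation_report(metrics, comparisons, occurrences, concepts)
  expect_equal(nrow(rep1$metrics), 4L)
  expect_equal(nrow(rep1$comparisons), 2L)

  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, p1)
  write_report(evaluation_report(metrics, comparisons, occurrences, concepts), p2)
  expect_identical(readLines(p1), readLines(p2))

  # headache traditional has tp + fp = 0: precision must serialize as null
  json <- paste(readLines(p1), collapse = "")
  obj <- jsonlite::fromJSON(json)
  trad_ha <- obj$metrics[obj$metrics$concept_id == "headache" &
                           obj$metrics$arm == "traditional", ]
  expect_true(is.na(trad_ha$precision))
  expect_match(json, "null")

  # a missing concept x arm cell is fatal
  expect_error(evaluation_report(metrics[1:3], comparisons, occurrences,
                                 concepts),
               "missing metrics")
})
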
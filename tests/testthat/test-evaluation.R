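# Shorthand for annotation/detection tables in the tests.
iv <- function(starts, ends, type = "normal")
  step_intervals(starts, ends, step_type = type)

test_that("precision pass applies the midpoint-containment rule", {
  m <- match_precision_pass(iv(10, 30), iv(12, 40))
  expect_equal(nrow(m$pairs), 1)  # midpoint 20 in [12, 40)

  # two detections inside one annotation: all but one are false
  m2 <- match_precision_pass(iv(c(10, 20), c(30, 40)), iv(0, 50))
  expect_equal(nrow(m2$pairs), 1)
  expect_equal(unname(m2$pairs[1, "detected_index"]), 1L)
  expect_equal(m2$unmatched_detected, 2L)
})

test_that("recall pass is the symmetric rule", {
  m <- match_recall_pass(iv(10, 30), iv(12, 40))
  expect_equal(nrow(m$pairs), 1)  # annotated midpoint 26 in [10, 30)

  # two annotations inside one long detection: one detected, one missed
  m2 <- match_recall_pass(iv(0, 100), iv(c(10, 50), c(30, 80)))
  expect_equal(nrow(m2$pairs), 1)
  expect_equal(m2$unmatched_annotated, 2L)
})

test_that("hand-built toy sets reproduce precision 5/6 and recall 4/5", {
  ann <- iv(c(0, 100, 200, 300, 400), c(50, 150, 250, 350, 450))

  # precision 5/6: five clean hits plus one double claim on annotation 1
  # (detection midpoints 25, 39.5, 125, 225, 325, 425; 39.5 finds ann1
  # already claimed and is counted false)
  det <- iv(c(5, 30, 95, 210, 305, 390), c(45, 49, 155, 240, 345, 460))
  ev <- evaluate_detection(det, ann)
  expect_equal(ev$precision, 5 / 6)
  expect_equal(ev$recall, 1)

  # recall 4/5: annotation 4 (midpoint 325) falls in no detection
  det_b <- iv(c(5, 95, 210, 360), c(45, 155, 240, 460))
  ev_b <- evaluate_detection(det_b, ann)
  expect_equal(ev_b$recall, 4 / 5)
  expect_equal(ev_b$precision, 1)
})

test_that("delta metrics are signed sample differences", {
  d <- iv(10, 30); a <- iv(12, 30)
  dl <- delta_metrics(d, a, match_precision_pass(d, a)$pairs)
  expect_equal(dl$dstart, -2)
  expect_equal(dl$dend, 0)
  expect_equal(dl$dduration, 2)

  dl0 <- delta_metrics(a, a, match_precision_pass(a, a)$pairs)
  expect_equal(unlist(dl0[, 1:3]), c(dstart = 0, dend = 0, dduration = 0))
})

test_that("median absolute errors match a hand-computed fixture", {
  ann <- iv(c(0, 100, 200, 300, 400), c(60, 170, 260, 380, 470))
  det <- iv(c(3, 95, 210, 310, 390), c(65, 175, 255, 370, 480))
  # dstart: 3, -5, 10, 10, -10 -> |.| = 3,5,10,10,10 -> median 10
  # dend:   5,  5, -5, -10, 10 -> |.| = 5,5,5,10,10  -> median 5
  # ddur:   2, 10, -15, -20, 20 -> |.| = 2,10,15,20,20 -> median 15
  ev <- evaluate_detection(det, ann)
  expect_equal(ev$precision, 1)
  expect_equal(ev$median_abs$dstart, 10)
  expect_equal(ev$median_abs$dend, 5)
  expect_equal(ev$median_abs$dduration, 15)
})

test_that("evaluating an annotation set against itself is perfect", {
  set.seed(20)
  for (rep in 1:5) {
    n <- sample(3:12, 1)
    starts <- cumsum(sample(30:80, n))
    ann <- iv(starts, starts + sample(20:40, n, replace = TRUE),
              type = sample(c("normal", "uturn"), n, replace = TRUE))
    ev <- evaluate_detection(ann, ann)
    expect_equal(ev$precision, 1)
    expect_equal(ev$recall, 1)
    expect_true(all(ev$deltas$dstart == 0 & ev$deltas$dend == 0 &
                    ev$deltas$dduration == 0))
  }
})

test_that("shifting all detections shifts every dstart by the same amount", {
  set.seed(21)
  starts <- cumsum(sample(60:100, 8))
  ann <- iv(starts, starts + 40)
  for (s in c(-7, 3, 12)) {
    det <- iv(starts + s, starts + 40 + s)
    dl <- delta_metrics(det, ann, match_precision_pass(det, ann)$pairs)
    expect_true(all(dl$dstart == s))
    expect_true(all(dl$dduration == 0))
  }
})

test_that("precision and recall can split on the same input", {
  # one wide detection covers both annotations but can serve only one in
  # the recall pass; a second detection is a pure false alarm
  ann <- iv(c(0, 52), c(50, 110))
  det <- iv(c(0, 200), c(110, 220))
  ev <- evaluate_detection(det, ann)
  expect_equal(ev$precision, 1 / 2)  # det1 midpoint 55 in ann2; det2 false
  expect_equal(ev$recall, 1 / 2)    # ann1 mid 25 in det1; ann2 mid 81 finds it claimed
})

test_that("empty inputs give NA scores, not errors", {
  ev <- evaluate_detection(iv(integer(), integer()), iv(0, 10))
  expect_true(is.na(ev$precision))
  expect_equal(ev$recall, 0)
  ev2 <- evaluate_detection(iv(0, 10), iv(integer(), integer()))
  expect_true(is.na(ev2$recall))
  expect_equal(ev2$precision, 0)
})

test_that("summaries average per-recording scores and stratify deltas", {
  ann <- iv(c(0, 100), c(50, 150), type = c("normal", "uturn"))
  r1 <- evaluate_detection(ann, ann)                       # P = R = 1
  r2 <- evaluate_detection(iv(0, 50), ann)                 # P = 1, R = 0.5
  s <- summarize_evaluations(list(r1, r2))
  expect_equal(unname(s$precision["mean"]), 1)
  expect_equal(unname(s$recall["mean"]), 0.75)
  expect_setequal(s$median_abs$step_type, c("normal", "uturn"))
  # absent stratum stays absent
  expect_false("initiation" %in% s$median_abs$step_type)
  expect_output(print(s), "precision")
})

test_that("peak evaluation claims each annotation and peak once", {
  ann <- iv(c(0, 100), c(50, 150))
  ev <- evaluate_peaks(c(10, 20, 120), ann)
  expect_equal(ev$precision, 2 / 3)  # 10 claims ann1, 20 false, 120 claims ann2
  expect_equal(ev$recall, 1)
  ev2 <- evaluate_peaks(integer(), ann)
  expect_true(is.na(ev2$precision))
  expect_equal(ev2$recall, 0)
})
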
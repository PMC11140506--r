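# Breast-level outcome labeling and exam classification.

bh <- function(events, patient_events = NULL, side = "left") {
  breast_history("p1", side, events, patient_events)
}

test_that("negative-type labels require follow-up and a biopsy-free history", {
  # screening 1, next exam at +25 months, no biopsies -> N
  ev <- make_events(
    list("p1", "left", "2015-01-10", "screen_assess", "1"),
    list("p1", "left", "2017-02-10", "screen_assess", "1"))
  expect_identical(as.character(
    assign_breast_label(bh(ev), "2015-01-10")), "N")

  # screening 2 with follow-up -> S
  ev$value[1] <- "2"
  expect_identical(as.character(
    assign_breast_label(bh(ev), "2015-01-10")), "S")

  # follow-up at only +12 months -> U
  ev <- make_events(
    list("p1", "left", "2015-01-10", "screen_assess", "1"),
    list("p1", "left", "2016-01-10", "screen_assess", "1"))
  expect_identical(as.character(
    assign_breast_label(bh(ev), "2015-01-10")), "U")

  # biopsy anywhere in the patient history (other breast, years later) -> U
  ev <- make_events(
    list("p1", "left", "2015-01-10", "screen_assess", "1"),
    list("p1", "left", "2017-02-10", "screen_assess", "1"))
  pat <- rbind(ev, make_events(
    list("p1", "right", "2018-06-01", "biopsy", "benign")))
  expect_identical(as.character(
    assign_breast_label(bh(ev, pat), "2015-01-10")), "U")
})

test_that("callback pathway resolves to D, P, H or M by worst pathology", {
  base <- list("p1", "left", "2015-01-10", "screen_assess", "0")
  # BI-RADS 0 then negative diagnostic, follow-up present -> D
  ev <- make_events(base,
    list("p1", "left", "2015-02-10", "diag_assess", "1"),
    list("p1", "left", "2017-03-10", "screen_assess", "1"))
  expect_identical(as.character(
    assign_breast_label(bh(ev), "2015-01-10")), "D")

  # callback with no diagnostic resolution -> U
  ev <- make_events(base,
    list("p1", "left", "2017-03-10", "screen_assess", "1"))
  expect_identical(as.character(
    assign_breast_label(bh(ev), "2015-01-10")), "U")

  # benign pathology -> P ; high-risk -> H ; malignant -> M
  for (kind in c("benign", "high_risk", "malignant")) {
    ev <- make_events(base,
      list("p1", "left", "2015-02-20", "biopsy", kind))
    expect_identical(
      as.character(assign_breast_label(bh(ev), "2015-01-10")),
      c(benign = "P", high_risk = "H", malignant = "M")[[kind]])
  }

  # several same-window pathologies: the most severe wins
  ev <- make_events(base,
    list("p1", "left", "2015-02-20", "biopsy", "benign"),
    list("p1", "left", "2015-03-20", "biopsy", "malignant"))
  lab <- assign_breast_label(bh(ev), "2015-01-10")
  expect_identical(as.character(lab), "M")
  expect_identical(attr(lab, "cancer_date"), as.Date("2015-03-20"))

  # screening BI-RADS 3 (mapped UK) is callback-equivalent
  ev <- make_events(list("p1", "left", "2015-01-10", "screen_assess", "3"),
    list("p1", "left", "2015-02-10", "diag_assess", "2"),
    list("p1", "left", "2017-03-10", "screen_assess", "1"))
  expect_identical(as.character(
    assign_breast_label(bh(ev), "2015-01-10")), "D")
})

test_that("interval cancers need a negative screen and in-window malignancy", {
  # screening 2, malignant pathology at +10 months, interval 12 -> I
  ev <- make_events(
    list("p1", "left", "2015-01-10", "screen_assess", "2"),
    list("p1", "left", "2015-11-10", "biopsy", "malignant"))
  lab <- assign_breast_label(bh(ev), "2015-01-10", interval_months = 12)
  expect_identical(as.character(lab), "I")
  expect_identical(attr(lab, "cancer_date"), as.Date("2015-11-10"))

  # malignancy beyond the interval -> U (known cancer, not the pathway)
  lab <- assign_breast_label(bh(ev), "2015-01-10", interval_months = 6)
  expect_identical(as.character(lab), "U")

  # malignancy after the next screening examination belongs to that exam
  ev2 <- rbind(ev[1, ],
               make_events(list("p1", "left", "2015-10-01",
                                "screen_assess", "2")),
               ev[2, ])
  expect_identical(as.character(
    assign_breast_label(bh(ev2), "2015-01-10")), "U")
})

test_that("labeling rejects malformed histories", {
  ev <- make_events(list("p1", "left", "2015-01-10", "screen_assess", "1"))
  expect_error(assign_breast_label(bh(ev), "2015-03-01"),
               "no screening assessment")
  # conflicting same-day pathology entries
  ev <- make_events(
    list("p1", "left", "2015-01-10", "screen_assess", "0"),
    list("p1", "left", "2015-02-01", "biopsy", "benign"),
    list("p1", "left", "2015-02-01", "biopsy", "malignant"))
  expect_error(assign_breast_label(bh(ev), "2015-01-10"),
               "conflicting same-day pathology")
  # two screening assessments on one date for one side
  ev <- make_events(
    list("p1", "left", "2015-01-10", "screen_assess", "1"),
    list("p1", "left", "2015-01-10", "screen_assess", "2"))
  expect_error(bh(ev), "at most one screening assessment")
})

test_that("classification against a window partitions the cohort", {
  d0 <- as.Date("2015-01-10")
  labeled <- data.frame(
    exam_id = sprintf("e%d", 1:5),
    exam_date = d0,
    exam_label = c("M", "U", "S", "I", "M"),
    cancer_date = c(add_months(d0, 3), NA, NA, add_months(d0, 20),
                    add_months(d0, 14)))
  cls <- classify_exams(labeled, 12)
  expect_identical(cls$class,
                   c("positive", "excluded", "negative", "excluded",
                     "excluded"))
  # wider window captures the later cancers
  cls24 <- classify_exams(labeled, 24)
  expect_identical(cls24$class[4:5], c("positive", "positive"))
  # each exam falls in exactly one class
  expect_true(all(table(cls$class) >= 0))
  expect_identical(sum(table(cls$class)), nrow(labeled))
  # positive label without a cancer date is rejected
  labeled$cancer_date[1] <- NA
  expect_error(classify_exams(labeled, 12), "missing cancer_date")
})

test_that("cohort labeling is deterministic and matches per-breast labeling", {
  ch <- generate_cohort(quick_config(n = 500, seed = 11,
                                     enrichment_factor = 20))
  x <- ch$exams[c("exam_id", "patient_id", "exam_date", "assessment")]
  lab1 <- label_cohort(x, ch$events)
  lab2 <- label_cohort(x, ch$events)
  expect_identical(lab1, lab2)
  expect_identical(lab1$exam_label, ch$truth$subclass)
  # spot-check one exam against assign_breast_label
  i <- which(lab1$exam_label == "M")[1]
  pid <- lab1$patient_id[i]
  pe <- ch$events[ch$events$patient_id == pid, ]
  side <- pe$side[pe$event_type == "biopsy"][1]
  h <- breast_history(pid, side, pe[pe$side == side, -2], pe)
  expect_identical(
    as.character(assign_breast_label(h, lab1$exam_date[i])), "M")
})

test_that("exam-level fallback assessment is applied to both sides with a warning", {
  exams <- data.frame(exam_id = "e1", patient_id = "p1",
                      exam_date = as.Date("2015-01-10"), assessment = 1L)
  events <- make_events(
    list("p1", "left", "2017-02-10", "screen_assess", "1"),
    list("p1", "right", "2017-02-10", "screen_assess", "1"))
  expect_warning(lab <- label_cohort(exams, events),
                 "applying the examination-level assessment")
  expect_identical(lab$exam_label, "N")
})
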
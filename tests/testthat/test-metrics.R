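# Screening metrics, prevalence rebalancing and stratified summaries.

test_that("sensitivity metrics count detections and retained detections", {
  # 4 positives, 3 radiologist-detected, 2 of those retained at t = 0.5
  ex <- fixture_from_counts(n_pos = 4, n_detected = 3, n_retained = 2)
  expect_identical(radiologist_true_positive(ex), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(radiologist_sensitivity(ex), 3 / 4)
  expect_equal(relative_sensitivity(ex, 0.5), 2 / 3)
  expect_equal(workflow_sensitivity(ex, 0.5), 2 / 4)
  expect_equal(workflow_sensitivity(ex, 0.5),
               radiologist_sensitivity(ex) * relative_sensitivity(ex, 0.5))
  # absolute sensitivity ignores the radiologist
  ex2 <- data.frame(class = "positive", exam_label = "M", assessment = 0L,
                    device_score = c(0.9, 0.8, 0.2, 0.95))
  expect_equal(absolute_sensitivity(ex2, 0.5), 0.75)
  expect_equal(absolute_sensitivity(ex2, 0), 1.0)
  expect_equal(absolute_sensitivity(ex2, 0.99), 0.0)
  expect_error(radiologist_true_positive(
    data.frame(class = "negative", assessment = 1L)), "positive")
})

test_that("rate metrics are direct (weighted) proportions", {
  ex <- data.frame(
    exam_id = sprintf("e%02d", 1:10), class = "negative",
    exam_label = c("P", "H", "D", "D", rep("N", 6)),
    assessment = c(0L, 0L, 0L, 0L, rep(1L, 6)),
    device_score = c(0.1, 0.6, 0.2, 0.7, 0.05, 0.9, 0.4, 0.3, 0.8, 0.45))
  # 4 scores below 0.35 -> unweighted rule-out rate 0.4
  expect_equal(ruleout_rate(ex, 0.35), 0.4)
  expect_equal(ruleout_rate(ex, 0), 0)
  # FP callbacks are the four assessment-0 negatives; 2 ruled out
  expect_equal(fp_callback_reduction(ex, 0.35), 0.5)
  expect_equal(fp_callback_reduction(ex, 0), 0)
  # benign biopsies are P/H; one of two ruled out
  expect_equal(benign_biopsy_reduction(ex, 0.35), 0.5)
  expect_equal(benign_biopsy_reduction(ex, 0.05), 0)
  # specificity without and with the device
  expect_equal(specificity(ex), 0.6)
  expect_equal(specificity(ex, 0.35), 0.8)
  expect_equal(specificity(ex, 0), 0.6)
  expect_equal(specificity(ex, 1), 1.0)
  expect_error(fp_callback_reduction(ex[5:10, ], 0.5), "no false-positive")
  expect_error(benign_biopsy_reduction(ex[3:10, ], 0.5), "no benign-biopsy")
})

test_that("cdr counts detected cancers per 1000 weighted exams", {
  pos <- fixture_from_counts(n_pos = 2, n_detected = 2, n_retained = 2)
  neg <- data.frame(exam_id = sprintf("n%03d", 1:398), class = "negative",
                    exam_label = "N", assessment = 1L, device_score = 0.3)
  ex <- rbind(pos, neg)
  expect_equal(cdr(ex), 5.0)             # 2 of 400 -> 5 per 1000
  expect_equal(cdr(ex, 0), cdr(ex))      # threshold 0 changes nothing
  expect_equal(cdr(ex, 0.95), 0)         # everything ruled out
  expect_true(cdr(ex, 0.5) <= cdr(ex))   # device can only remove
})

test_that("prevalence weights rebalance subclass proportions exactly", {
  target <- c(N = 0.85, S = 0.05, D = 0.06, P = 0.02, H = 0.005,
              M = 0.01, I = 0.005)
  observed <- c(N = 500, S = 40, D = 35, P = 30, H = 15, M = 250, I = 130)
  w <- prevalence_weights(observed, target)
  # identity: weighted proportions equal the target
  wprop <- unclass(w) * observed[names(target)] / sum(observed)
  expect_equal(unname(wprop), unname(target))
  # observed proportions equal to target -> all weights 1
  obs2 <- round(target * 10000)
  expect_equal(unname(unclass(prevalence_weights(obs2, obs2 / sum(obs2)))),
               rep(1, 7))
  # enrichment by 10x shrinks cancer weights 10-fold relative to neutral
  expect_lt(w[["M"]], 0.1)
  expect_error(prevalence_weights(c(N = 10, M = 0), c(N = 0.99, M = 0.01)),
               "M")
  expect_error(prevalence_weights(observed, target * 2), "sum to 1")
})

test_that("weighted metrics equal plug-in estimates at the target mix", {
  # reweighting identity on a generated cohort: weighting the enriched
  # cohort to the natural mix reproduces the natural-cohort estimate
  cfg_nat <- quick_config(n = 30000, seed = 21)
  cfg_enr <- quick_config(n = 30000, seed = 22, enrichment_factor = 10)
  nat <- classify_exams(generate_cohort(cfg_nat)$exams, 12)
  enr <- classify_exams(generate_cohort(cfg_enr)$exams, 12)
  w <- prevalence_weights(subclass_counts(enr), effective_prevalence(cfg_nat))
  t <- 0.2
  for (m in c("ruleout_rate", "fp_callback_reduction")) {
    fn <- get(m)
    a <- fn(nat, t)
    b <- fn(enr, t, w)
    expect_lt(abs(a - b), 0.02)
  }
})

test_that("per-reader summaries honor the 10+10 inclusion rule", {
  ch <- generate_cohort(quick_config(n = 4000, seed = 31,
                                     enrichment_factor = 25, n_readers = 3))
  cls <- classify_exams(ch$exams, 12)
  # starve one reader of positives
  cls$reader_id[cls$reader_id == "R03" & cls$class == "positive"] <-
    sample(c("R01", "R02"), sum(cls$reader_id == "R03" &
                                  cls$class == "positive"), replace = TRUE)
  out <- stratify_and_summarize(cls, 0.2, by = "reader")
  expect_true("collective" %in% out$group)
  expect_false("R03" %in% out$group)
  expect_true(all(c("R01", "R02") %in% out$group))

  # single qualifying group: its rows equal the collective on its exams
  solo <- cls[cls$reader_id == "R01", ]
  out1 <- stratify_and_summarize(solo, 0.2, by = "reader")
  expect_equal(out1$value[out1$group == "R01"],
               out1$value[out1$group == "collective"])

  # scanner strata combine, exam-weighted, into the pooled estimate
  outs <- stratify_and_summarize(cls, 0.2, by = "scanner")
  pooled <- outs$value[outs$group == "collective" &
                         outs$metric == "ruleout_rate"]
  parts <- outs[outs$group != "collective" & outs$metric == "ruleout_rate", ]
  ns <- table(cls$scanner[cls$class != "excluded"])[parts$group]
  expect_equal(sum(parts$value * as.numeric(ns)) / sum(ns), pooled)
})

test_that("the flow table conserves examinations at every node", {
  ch <- generate_cohort(quick_config(n = 5000, seed = 41,
                                     enrichment_factor = 10))
  cls <- classify_exams(ch$exams, 12)
  fl <- flow_table(cls, 0.25)
  g <- function(node, col) fl[fl$node == node, col]
  for (col in c("standard", "ruleout")) {
    expect_equal(g("ruled_out", col) + g("radiologist_read", col),
                 g("total", col))
    expect_equal(g("callbacks", col) + g("screen_negatives", col),
                 g("radiologist_read", col))
    expect_lte(g("benign_biopsies", col), g("callbacks", col))
    expect_lte(g("cancers_detected", col), g("callbacks", col))
  }
  expect_equal(g("total", "standard"), 10000)
  expect_equal(g("total", "ruleout"), 10000)
  expect_equal(g("ruled_out", "standard"), 0)
})

test_that("reduction metrics are zero at threshold 0 and nondecreasing", {
  ch <- generate_cohort(quick_config(n = 3000, seed = 51,
                                     enrichment_factor = 10))
  cls <- classify_exams(ch$exams, 12)
  ts <- seq(0, 0.9, by = 0.15)
  for (m in c("ruleout_rate", "fp_callback_reduction",
              "benign_biopsy_reduction")) {
    fn <- get(m)
    vals <- vapply(ts, function(t) fn(cls, t), numeric(1))
    expect_equal(vals[1], 0)
    expect_true(all(diff(vals) >= 0))
  }
  cdrs <- vapply(ts, function(t) cdr(cls, t), numeric(1))
  expect_true(all(diff(cdrs) <= 0))
})
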
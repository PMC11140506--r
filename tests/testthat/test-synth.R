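# Synthetic cohort generator: determinism, conformance, closed forms.

test_that("the generator validates its configuration", {
  expect_error(generator_config(natural_prevalence = c(N = 1)), "named over")
  p <- c(N = 0.9, S = 0.04, D = 0.04, P = 0.01, H = 0.005, M = 0, I = 0)
  p["N"] <- 1 - sum(p[-1])
  expect_error(generator_config(natural_prevalence = p), "infeasible")
  expect_error(generator_config(enrichment_factor = 0.5), ">= 1")
  expect_error(generator_config(reader_sensitivity = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(scanner_mix = c(HSE = 0.5, SED = 0.6)),
               "summing to 1")
  expect_error(generator_config(double_read = TRUE, n_readers = 1),
               "two readers")
})

test_that("seeded generation is reproducible and unseeded runs differ", {
  c1 <- generate_cohort(quick_config(n = 300, seed = 77))
  c2 <- generate_cohort(quick_config(n = 300, seed = 77))
  expect_identical(c1$exams, c2$exams)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(quick_config(n = 300, seed = 78))
  expect_false(identical(c1$exams$device_score, c3$exams$device_score))
})

test_that("drawn subclass proportions follow the (tilted) prevalences", {
  cfg <- quick_config(n = 50000, seed = 85)
  ch <- generate_cohort(cfg)
  p <- cfg$natural_prevalence
  tab <- table(factor(ch$truth$drawn_subclass, levels = names(p))) / 50000
  for (cl in names(p)) {
    se <- sqrt(p[[cl]] * (1 - p[[cl]]) / 50000)
    expect_lt(abs(tab[[cl]] - p[[cl]]), 3 * se + 1e-12)
  }
  # enrichment tilts the cancer odds by the configured factor
  cfg10 <- quick_config(n = 50000, seed = 86, enrichment_factor = 10)
  ch10 <- generate_cohort(cfg10)
  pc <- p[["M"]] + p[["I"]]
  pc10 <- pc * 10 / (pc * 10 + 1 - pc)
  frac <- mean(ch10$truth$drawn_subclass %in% c("M", "I"))
  expect_lt(abs(frac - pc10), 3 * sqrt(pc10 * (1 - pc10) / 50000))
})

test_that("perfect readers miss no screen-detectable cancers", {
  cfg <- quick_config(n = 20000, seed = 91, reader_sensitivity = 1,
                      enrichment_factor = 50)
  ch <- generate_cohort(cfg)
  # every drawn M stays M; all I labels are true interval draws
  expect_identical(
    ch$truth$subclass[ch$truth$drawn_subclass == "M"],
    rep("M", sum(ch$truth$drawn_subclass == "M")))
  # with sensitivity s < 1 the miss route produces extra I labels
  cfg2 <- quick_config(n = 20000, seed = 92, reader_sensitivity = 0.7,
                       enrichment_factor = 50)
  ch2 <- generate_cohort(cfg2)
  expect_gt(sum(ch2$truth$subclass == "I" &
                  ch2$truth$drawn_subclass == "M"), 0)
})

test_that("relabeling generated event streams recovers the subclass", {
  ch <- generate_cohort(quick_config(n = 2000, seed = 95,
                                     enrichment_factor = 10))
  lab <- label_cohort(ch$exams[c("exam_id", "patient_id", "exam_date",
                                 "assessment")], ch$events)
  expect_identical(lab$exam_label, ch$truth$subclass)
  # cancer dates agree too
  expect_identical(lab$cancer_date, ch$exams$cancer_date)
})

test_that("closed-form expectations match trivial thresholds and reject junk", {
  cfg <- quick_config(n = 10)
  expect_equal(true_metric(cfg, "ruleout_rate", 0), 0)
  expect_equal(true_metric(cfg, "ruleout_rate", 1), 1)
  expect_equal(true_metric(cfg, "fp_callback_reduction", 0), 0)
  expect_equal(true_metric(cfg, "sensitivity_rel", 0), 1)
  expect_equal(true_metric(cfg, "cdr", 0),
               1000 * effective_prevalence(cfg)[["M"]])
  expect_error(true_metric(cfg, "auc", 0.5), "unsupported metric")
  expect_error(true_metric(generator_config(double_read = TRUE),
                           "ruleout_rate", 0.5), "single-read")
})

test_that("empirical metrics approach the closed forms at natural prevalence", {
  cfg <- quick_config(n = 100000, seed = 101)
  ch <- generate_cohort(cfg)
  cls <- classify_exams(ch$exams, 12)
  t <- 0.18
  est <- ruleout_rate(cls, t)
  truth <- true_metric(cfg, "ruleout_rate", t)
  se <- sqrt(truth * (1 - truth) / 100000)
  expect_lt(abs(est - truth), 3 * se)
})

test_that("reader callback-rate overrides re-tilt the cancer-free mix", {
  cfg <- quick_config(n = 60000, seed = 105,
                      reader_fp_callback_rate = 0.15)
  ch <- generate_cohort(cfg)
  free <- ch$truth$subclass %in% c("N", "S", "D", "P", "H")
  cb <- ch$truth$subclass %in% c("D", "P", "H")
  rate <- sum(cb) / sum(free)
  expect_lt(abs(rate - 0.15), 3 * sqrt(0.15 * 0.85 / sum(free)))
  # effective_prevalence reflects the override
  pe <- effective_prevalence(cfg)
  expect_equal(sum(pe[c("D", "P", "H")]) / sum(pe[c("N", "S", "D", "P", "H")]),
               0.15)
})

test_that("double-read cohorts carry first and final opinions", {
  cfg <- quick_config(n = 3000, seed = 111, double_read = TRUE,
                      enrichment_factor = 20)
  ch <- generate_cohort(cfg)
  expect_true(all(c("first_assessment", "first_reader_id", "reader_ids") %in%
                    names(ch$exams)))
  expect_true(all(grepl(";", ch$exams$reader_ids)))
  expect_false(any(ch$exams$first_reader_id == ch$exams$reader_id))
  # final opinion is authoritative for labels: relabeling still round-trips
  lab <- label_cohort(ch$exams[c("exam_id", "patient_id", "exam_date",
                                 "assessment")], ch$events)
  expect_identical(lab$exam_label, ch$truth$subclass)
})
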
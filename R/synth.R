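# Synthetic screening cohort generator with known ground truth.
#
# The generator emulates an enriched screening population: outcome
# subclasses drawn from a (possibly enrichment-tilted) prevalence vector,
# reader operating characteristics, interval cancers produced both by
# true interval draws and by reader misses of screen-detectable cancers,
# two scanner strata, and class-conditional Beta device scores. Event
# streams are emitted conformantly so that relabeling them recovers the
# generating subclass exactly, and every headline metric has a
# closed-form expectation (true_metric) for parameter-recovery tests.

#' Configuration for the synthetic cohort generator
#'
#' @param n_exams Number of screening examinations.
#' @param natural_prevalence Named vector over subclasses
#'   `N, S, D, P, H, M, I` summing to 1: the natural screening-population
#'   mix of drawn outcomes. The shipped default is illustrative of a
#'   screening programme with roughly a 9% callback rate, 1.2% biopsy
#'   rate and 5 cancers per 1000 examinations; it is not a published
#'   population vector.
#' @param enrichment_factor Multiplier (>= 1) on the cancer-subclass
#'   sampling odds, emulating case-enriched evaluation sets.
#' @param n_readers Number of readers; examinations are assigned
#'   uniformly.
#' @param reader_sensitivity Per-reader probability that a
#'   screen-detectable cancer (drawn M) is recalled; scalar recycled.
#'   Missed draws are relabeled interval cancers (I).
#' @param reader_fp_callback_rate Per-reader callback rate among
#'   cancer-free examinations; `NULL` (default) uses the rate implied by
#'   `natural_prevalence`, i.e. (D+P+H)/(N+S+D+P+H). Overriding re-tilts
#'   each reader's cancer-free subclass mix (callback classes scaled to
#'   the reader's rate).
#' @param biopsy_fraction_of_callbacks Fraction of callbacks that proceed
#'   to biopsy; `NULL` uses the implied (P+H)/(D+P+H).
#' @param score_shapes Named list of `c(shape1, shape2)` Beta parameters
#'   for the class-conditional device score laws on `[0, 1]`.
#' @param scanner_mix Named probabilities for scanner models `HSE`/`SED`.
#' @param double_read Generate UK-style first/final opinions (first
#'   reader opinion modelled by a simple concordance with the final
#'   opinion); closed-form oracles are not available in this mode.
#' @param first_reader_agreement In double-read mode, probability that
#'   the first reader flags an examination the final opinion recalls.
#' @param first_reader_fp_rate In double-read mode, probability that the
#'   first reader flags an examination the final opinion clears.
#' @param interval_months Screening interval (12 US-style, 36 UK-style).
#' @param followup_min_months Follow-up requirement for negative-type
#'   labels.
#' @param start_date First possible examination date; exam dates are
#'   uniform over the following two years.
#' @param seed Optional integer seed; seeded runs are reproducible.
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(n_exams = 10000,
                             natural_prevalence = c(N = 0.823, S = 0.080,
                                                    D = 0.080, P = 0.010,
                                                    H = 0.002, M = 0.004,
                                                    I = 0.001),
                             enrichment_factor = 1,
                             n_readers = 10,
                             reader_sensitivity = 0.85,
                             reader_fp_callback_rate = NULL,
                             biopsy_fraction_of_callbacks = NULL,
                             score_shapes = list(
                               N = c(1.5, 8), S = c(1.5, 8), D = c(2.5, 6),
                               P = c(3.5, 5), H = c(4, 4.5), I = c(3, 3),
                               M = c(11, 2)),
                             scanner_mix = c(HSE = 0.7, SED = 0.3),
                             double_read = FALSE,
                             first_reader_agreement = 0.75,
                             first_reader_fp_rate = 0.03,
                             interval_months = 12,
                             followup_min_months = 24,
                             start_date = "2014-01-01",
                             seed = NULL) {
  classes <- c("N", "S", "D", "P", "H", "M", "I")
  p <- natural_prevalence
  if (is.null(names(p)) || !setequal(names(p), classes)) {
    stop("natural_prevalence must be named over ",
         paste(classes, collapse = ", "))
  }
  p <- p[classes]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("natural_prevalence must be nonnegative and sum to 1")
  }
  if (p[["M"]] + p[["I"]] <= 0) {
    stop("infeasible config: cancer prevalence (M + I) must be positive")
  }
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  stopifnot(n_exams >= 1, n_readers >= 1)
  if (isTRUE(double_read) && n_readers < 2) {
    stop("double_read requires at least two readers")
  }
  s <- rep_len(reader_sensitivity, n_readers)
  if (any(s < 0 | s > 1)) stop("reader sensitivities must lie in [0, 1]")
  p_free <- 1 - p[["M"]] - p[["I"]]
  implied_cb <- (p[["D"]] + p[["P"]] + p[["H"]]) / p_free
  r <- if (is.null(reader_fp_callback_rate)) rep(implied_cb, n_readers)
       else rep_len(reader_fp_callback_rate, n_readers)
  if (any(r < 0 | r > 1)) stop("callback rates must lie in [0, 1]")
  bf <- if (is.null(biopsy_fraction_of_callbacks)) {
    cb <- p[["D"]] + p[["P"]] + p[["H"]]
    if (cb > 0) (p[["P"]] + p[["H"]]) / cb else 0
  } else biopsy_fraction_of_callbacks
  if (bf < 0 || bf > 1) stop("biopsy_fraction_of_callbacks must lie in [0, 1]")
  if (!setequal(names(score_shapes), classes)) {
    stop("score_shapes must be named over ", paste(classes, collapse = ", "))
  }
  for (cl in classes) {
    sh <- score_shapes[[cl]]
    if (length(sh) != 2L || any(sh <= 0)) {
      stop("score_shapes[['", cl, "']] must be two positive Beta shapes")
    }
  }
  if (!setequal(names(scanner_mix), c("HSE", "SED")) ||
      abs(sum(scanner_mix) - 1) > 1e-9 || any(scanner_mix < 0)) {
    stop("scanner_mix must be named probabilities for HSE and SED summing to 1")
  }
  structure(
    list(n_exams = as.integer(n_exams),
         natural_prevalence = p,
         enrichment_factor = enrichment_factor,
         n_readers = as.integer(n_readers),
         reader_sensitivity = s,
         reader_fp_callback_rate = r,
         biopsy_fraction_of_callbacks = bf,
         score_shapes = score_shapes[classes],
         scanner_mix = scanner_mix[c("HSE", "SED")],
         double_read = isTRUE(double_read),
         first_reader_agreement = first_reader_agreement,
         first_reader_fp_rate = first_reader_fp_rate,
         interval_months = as.integer(interval_months),
         followup_min_months = as.integer(followup_min_months),
         start_date = as.Date(start_date),
         seed = seed),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic screening cohort configuration\n")
  cat("  n_exams:", x$n_exams, " enrichment:", x$enrichment_factor,
      " readers:", x$n_readers,
      if (x$double_read) " (double read)" else "", "\n")
  cat("  natural prevalence:\n")
  print(round(x$natural_prevalence, 5))
  invisible(x)
}

# Per-reader cancer-free subclass distribution (columns N,S,D,P,H).
.reader_free_probs <- function(config) {
  p <- config$natural_prevalence
  bf <- config$biopsy_fraction_of_callbacks
  r <- config$reader_fp_callback_rate
  ph <- p[["P"]] + p[["H"]]
  ns <- p[["N"]] + p[["S"]]
  wP <- if (ph > 0) p[["P"]] / ph else 0.5
  wN <- if (ns > 0) p[["N"]] / ns else 0.5
  cbind(N = (1 - r) * wN, S = (1 - r) * (1 - wN),
        D = r * (1 - bf), P = r * bf * wP, H = r * bf * (1 - wP))
}

#' Effective subclass prevalence of a generator configuration
#'
#' The subclass distribution of generated examinations after reader
#' behaviour is applied: screen-detectable cancers (drawn M) missed by
#' readers become interval cancers (I), and per-reader callback rates
#' tilt the cancer-free mix. With `enriched = TRUE` the cancer-subclass
#' odds are multiplied by the enrichment factor first. This is the
#' prevalence vector that rebalancing weights should target when the
#' goal is natural-population metrics.
#'
#' @param config A [generator_config()].
#' @param enriched Apply the enrichment tilt (default `FALSE`).
#' @return Named prevalence vector over `N, S, D, P, H, M, I`.
#' @export
effective_prevalence <- function(config, enriched = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  p <- config$natural_prevalence
  pC <- p[["M"]] + p[["I"]]
  if (enriched) {
    e <- config$enrichment_factor
    pC <- pC * e / (pC * e + (1 - pC))
  }
  pM_C <- p[["M"]] / (p[["M"]] + p[["I"]])
  s_bar <- mean(config$reader_sensitivity)
  q <- colMeans(.reader_free_probs(config))
  out <- c(
    (1 - pC) * q[c("N", "S", "D", "P", "H")],
    M = pC * pM_C * s_bar,
    I = pC * ((1 - pM_C) + pM_C * (1 - s_bar))
  )
  names(out) <- c("N", "S", "D", "P", "H", "M", "I")
  out
}

#' Generate a synthetic screening cohort
#'
#' Draws examinations from the configured (enrichment-tilted) subclass
#' prevalences, assigns readers and scanners, produces conformant reader
#' assessments and event streams (callbacks with diagnostic resolutions,
#' biopsies with pathology, interval-cancer pathology inside the
#' screening interval, follow-up examinations for negative-type
#' outcomes), and draws device scores from the class-conditional Beta
#' laws. Relabeling the emitted events with [label_cohort()] recovers
#' the generating subclass for every examination.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_cohort`: list with `exams` (one row per
#'   examination, including the ground-truth `exam_label` and
#'   `cancer_date`), `events` (per-patient breast histories), `truth`
#'   (drawn and final subclass per examination) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(config$seed)
  }
  n <- config$n_exams
  p <- config$natural_prevalence
  classes <- c("N", "S", "D", "P", "H", "M", "I")

  pC0 <- p[["M"]] + p[["I"]]
  e <- config$enrichment_factor
  pC <- pC0 * e / (pC0 * e + (1 - pC0))
  pM_C <- p[["M"]] / pC0

  reader_idx <- sample.int(config$n_readers, n, replace = TRUE)
  reader_id <- sprintf("R%02d", reader_idx)
  is_cancer <- stats::runif(n) < pC
  drawn <- character(n)
  truth <- character(n)

  # cancers: drawn M may be missed and relabeled I
  ci <- which(is_cancer)
  drawnM <- stats::runif(length(ci)) < pM_C
  drawn[ci] <- ifelse(drawnM, "M", "I")
  if (config$double_read) {
    r2 <- ((reader_idx + sample.int(config$n_readers - 1L, n,
                                    replace = TRUE) - 1L) %%
             config$n_readers) + 1L
    s1 <- config$reader_sensitivity[reader_idx[ci]]
    s2 <- config$reader_sensitivity[r2[ci]]
    d1 <- stats::runif(length(ci)) < s1
    d2 <- stats::runif(length(ci)) < s2
    detected <- d1 | d2
  } else {
    detected <- stats::runif(length(ci)) <
      config$reader_sensitivity[reader_idx[ci]]
    d1 <- detected
  }
  truth[ci] <- ifelse(drawnM & detected, "M", "I")

  # cancer-free: per-reader conditional subclass draw
  fi <- which(!is_cancer)
  Q <- .reader_free_probs(config)
  cumQ <- t(apply(Q, 1L, cumsum))
  u <- stats::runif(length(fi))
  idx <- rowSums(u > cumQ[reader_idx[fi], , drop = FALSE]) + 1L
  idx <- pmin(idx, 5L)  # guard floating roundoff at the upper edge
  free_classes <- c("N", "S", "D", "P", "H")
  drawn[fi] <- free_classes[idx]
  truth[fi] <- drawn[fi]

  # assessments conformant with the final (truth) subclass
  assessment <- integer(n)
  assessment[truth == "N"] <- 1L
  assessment[truth == "S"] <- 2L
  assessment[truth %in% c("D", "P", "H", "M")] <- 0L
  ii <- truth == "I"
  assessment[ii] <- sample(c(1L, 2L), sum(ii), replace = TRUE)

  # class-conditional device scores
  device_score <- numeric(n)
  for (cl in classes) {
    k <- truth == cl
    if (any(k)) {
      sh <- config$score_shapes[[cl]]
      device_score[k] <- stats::rbeta(sum(k), sh[1], sh[2])
    }
  }

  scanner <- sample(c("HSE", "SED"), n, replace = TRUE,
                    prob = config$scanner_mix)
  exam_date <- config$start_date + sample.int(730L, n, replace = TRUE) - 1L
  patient_id <- sprintf("P%06d", seq_len(n))
  exam_id <- sprintf("E%06d", seq_len(n))
  affected <- sample(c("left", "right"), n, replace = TRUE)
  other <- ifelse(affected == "left", "right", "left")

  # cancer dates: detected M biopsied on the callback pathway one month
  # out; interval cancers surface within the screening interval
  cancer_date <- rep(as.Date(NA), n)
  mi <- which(truth == "M")
  cancer_date[mi] <- add_months(exam_date[mi], 1)
  iv <- which(truth == "I")
  cancer_date[iv] <- add_months(exam_date[iv],
                                sample.int(config$interval_months,
                                           length(iv), replace = TRUE))

  # event streams
  ev <- list(
    data.frame(patient_id = patient_id, side = affected, date = exam_date,
               event_type = "screen_assess",
               value = as.character(assessment), stringsAsFactors = FALSE),
    data.frame(patient_id = patient_id, side = other, date = exam_date,
               event_type = "screen_assess", value = "1",
               stringsAsFactors = FALSE)
  )
  di <- which(truth == "D")
  if (length(di)) {
    ev <- c(ev, list(data.frame(
      patient_id = patient_id[di], side = affected[di],
      date = add_months(exam_date[di], 1), event_type = "diag_assess",
      value = "1", stringsAsFactors = FALSE)))
  }
  for (cl in c("P", "H", "M")) {
    k <- which(truth == cl)
    if (length(k)) {
      ev <- c(ev, list(data.frame(
        patient_id = patient_id[k], side = affected[k],
        date = add_months(exam_date[k], 1), event_type = "biopsy",
        value = c(P = "benign", H = "high_risk", M = "malignant")[[cl]],
        stringsAsFactors = FALSE)))
    }
  }
  if (length(iv)) {
    ev <- c(ev, list(data.frame(
      patient_id = patient_id[iv], side = affected[iv],
      date = cancer_date[iv], event_type = "biopsy", value = "malignant",
      stringsAsFactors = FALSE)))
  }
  nb <- which(truth %in% c("N", "S", "D"))
  if (length(nb)) {
    fup <- add_months(exam_date[nb],
                      config$followup_min_months +
                        sample.int(6L, length(nb), replace = TRUE))
    ev <- c(ev, list(
      data.frame(patient_id = patient_id[nb], side = affected[nb],
                 date = fup, event_type = "screen_assess", value = "1",
                 stringsAsFactors = FALSE),
      data.frame(patient_id = patient_id[nb], side = other[nb],
                 date = fup, event_type = "screen_assess", value = "1",
                 stringsAsFactors = FALSE)))
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$patient_id, events$date), , drop = FALSE]
  rownames(events) <- NULL

  exams <- data.frame(
    exam_id = exam_id, patient_id = patient_id, exam_date = exam_date,
    assessment = assessment, reader_id = reader_id, scanner = scanner,
    device_score = device_score, exam_label = truth,
    cancer_date = cancer_date, stringsAsFactors = FALSE
  )
  if (config$double_read) {
    first_assessment <- assessment
    # cancers: first reader's own detection
    first_assessment[ci] <- ifelse(d1, 0L,
                                   sample(c(1L, 2L), length(ci),
                                          replace = TRUE))
    # cancer-free: simple concordance with the final opinion
    cb <- truth %in% c("D", "P", "H")
    fa_cb <- stats::runif(n) < config$first_reader_agreement
    fa_fp <- stats::runif(n) < config$first_reader_fp_rate
    first_assessment[fi] <- ifelse(cb[fi] & fa_cb[fi], 0L,
                            ifelse(!cb[fi] & fa_fp[fi], 0L,
                                   ifelse(truth[fi] == "S", 2L, 1L)))
    exams$first_assessment <- first_assessment
    exams$first_reader_id <- reader_id
    exams$reader_id <- sprintf("R%02d", r2)
    exams$reader_ids <- paste(exams$first_reader_id, exams$reader_id,
                              sep = ";")
  } else {
    exams$reader_ids <- reader_id
  }

  structure(
    list(exams = exams, events = events,
         truth = data.frame(exam_id = exam_id, drawn_subclass = drawn,
                            subclass = truth, stringsAsFactors = FALSE),
         config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic screening cohort:", nrow(x$exams), "examinations,",
      nrow(x$events), "events\n")
  print(table(factor(x$truth$subclass, levels = c("N", "S", "D", "P", "H",
                                                  "M", "I"))))
  invisible(x)
}

#' Closed-form metric expectation under a generator configuration
#'
#' Expected value of a screening metric at a given rule-out threshold on
#' a natural-prevalence population generated by `config`, computed from
#' the effective subclass prevalences and the Beta score distribution
#' functions — e.g. the rule-out rate is `sum_c pi(c) F_c(t)`. Serves as
#' the independent oracle for parameter-recovery tests of the
#' prevalence-weighted pipeline estimates. Available for single-read
#' configurations.
#'
#' @param config A [generator_config()].
#' @param metric_name One of `ruleout_rate`, `fp_callback_reduction`,
#'   `benign_biopsy_reduction`, `cdr`, `cdr_workflow`, `sensitivity_abs`,
#'   `sensitivity_rel`, `specificity`, `specificity_workflow`,
#'   `workflow_sensitivity`, `sensitivity_radiologist`.
#' @param threshold Rule-out threshold in `[0, 1]`.
#' @return The expected metric value (CDR per 1000 examinations).
#' @export
true_metric <- function(config, metric_name, threshold) {
  stopifnot(inherits(config, "generator_config"))
  if (config$double_read) {
    stop("closed-form expectations are available for single-read ",
         "configurations only")
  }
  stopifnot(length(threshold) == 1L, threshold >= 0, threshold <= 1)
  pi <- effective_prevalence(config)
  Fc <- vapply(names(pi), function(cl) {
    sh <- config$score_shapes[[cl]]
    stats::pbeta(threshold, sh[1], sh[2])
  }, numeric(1))
  neg <- c("N", "S", "D", "P", "H")
  cbk <- c("D", "P", "H")
  bio <- c("P", "H")
  switch(
    metric_name,
    ruleout_rate = sum(pi * Fc),
    fp_callback_reduction = sum(pi[cbk] * Fc[cbk]) / sum(pi[cbk]),
    benign_biopsy_reduction = sum(pi[bio] * Fc[bio]) / sum(pi[bio]),
    cdr = 1000 * pi[["M"]],
    cdr_workflow = 1000 * pi[["M"]] * (1 - Fc[["M"]]),
    sensitivity_abs = (pi[["M"]] * (1 - Fc[["M"]]) +
                         pi[["I"]] * (1 - Fc[["I"]])) /
      (pi[["M"]] + pi[["I"]]),
    sensitivity_rel = 1 - Fc[["M"]],
    specificity = (pi[["N"]] + pi[["S"]]) / sum(pi[neg]),
    specificity_workflow = (pi[["N"]] + pi[["S"]] +
                              sum(pi[cbk] * Fc[cbk])) / sum(pi[neg]),
    workflow_sensitivity = pi[["M"]] * (1 - Fc[["M"]]) /
      (pi[["M"]] + pi[["I"]]),
    sensitivity_radiologist = pi[["M"]] / (pi[["M"]] + pi[["I"]]),
    stop("unsupported metric: ", metric_name)
  )
}

#' Observed subclass counts of a labeled cohort
#'
#' @param exams Exam table with an `exam_label` column.
#' @return Named integer counts over `N, S, D, P, H, M, I` (U excluded).
#' @export
subclass_counts <- function(exams) {
  exams <- as.data.frame(exams)
  .check_metric_cols(exams, "exam_label")
  lv <- c("N", "S", "D", "P", "H", "M", "I")
  tab <- table(factor(as.character(exams$exam_label), levels = lv))
  stats::setNames(as.integer(tab), lv)
}
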
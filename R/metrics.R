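# Screening performance metrics on classified examination tables.
#
# All metric functions take a labeled, classified exam table (columns
# exam_label, class, assessment, device_score) plus an operating point,
# and optionally per-subclass prevalence weights. Weights compensate for
# case enrichment: a weighted proportion is sum(w * x) / sum(w) with w
# determined by each examination's outcome subclass.

.get_threshold <- function(point) {
  if (is.null(point)) return(NULL)
  if (inherits(point, "operating_point")) point$threshold else as.numeric(point)
}

.exam_weights <- function(exams, weights) {
  if (is.null(weights)) return(rep(1, nrow(exams)))
  w <- unclass(weights)
  lab <- as.character(exams$exam_label)
  present <- unique(lab[exams$class != "excluded"])
  missing <- setdiff(present, names(w))
  if (length(missing)) {
    stop("prevalence weights missing for subclass(es): ",
         paste(missing, collapse = ", "))
  }
  out <- unname(w[lab])
  out[is.na(out)] <- 0  # excluded subclasses carry no weight
  out
}

.check_metric_cols <- function(exams, cols) {
  if (!all(cols %in% names(exams))) {
    stop("exams must have columns: ", paste(cols, collapse = ", "))
  }
}

# A callback is any non-negative screening assessment (BI-RADS 0; mapped
# UK screening 3+ counts as callback-equivalent).
.is_callback <- function(assessment) !(as.integer(assessment) %in% c(1L, 2L))

#' Radiologist true positives
#'
#' A cancer-positive examination counts as a radiologist true positive
#' when its screening assessment is BI-RADS 0, 4, 5 or 6.
#'
#' @param exams Classified exam table restricted to, or containing,
#'   positive examinations; all rows passed must be class `"positive"`.
#' @return Logical vector.
#' @export
radiologist_true_positive <- function(exams) {
  exams <- as.data.frame(exams)
  .check_metric_cols(exams, c("class", "assessment"))
  if (!all(exams$class == "positive")) {
    stop("radiologist_true_positive is defined on cancer-positive ",
         "examinations only")
  }
  as.integer(exams$assessment) %in% c(0L, 4L, 5L, 6L)
}

#' Relative device sensitivity
#'
#' The fraction of radiologist-detected cancers also retained by the
#' device (score >= threshold): the intersection of device and
#' radiologist true positives over the radiologist true positives.
#' Sensitivity-type metrics condition on the cancer class and are not
#' prevalence-weighted.
#'
#' @param exams Classified exam table.
#' @param point Operating point or numeric threshold.
#' @return Proportion in `[0, 1]`.
#' @export
relative_sensitivity <- function(exams, point) {
  exams <- as.data.frame(exams)
  .check_metric_cols(exams, c("class", "assessment", "device_score"))
  t <- .get_threshold(point)
  pos <- exams[exams$class == "positive", , drop = FALSE]
  rtp <- radiologist_true_positive(pos)
  if (!any(rtp)) stop("no radiologist true positives; relative sensitivity undefined")
  sum(rtp & pos$device_score >= t) / sum(rtp)
}

#' Absolute device sensitivity
#'
#' Fraction of cancer-positive examinations with score >= threshold.
#'
#' @inheritParams relative_sensitivity
#' @return Proportion in `[0, 1]`.
#' @export
absolute_sensitivity <- function(exams, point) {
  exams <- as.data.frame(exams)
  .check_metric_cols(exams, c("class", "device_score"))
  t <- .get_threshold(point)
  pos <- exams$class == "positive"
  if (!any(pos)) stop("no positive examinations; sensitivity undefined")
  mean(exams$device_score[pos] >= t)
}

#' Radiologist (standard-workflow) sensitivity
#'
#' Fraction of cancer-positive examinations the radiologists recalled
#' (assessment BI-RADS 0, 4, 5, 6).
#'
#' @inheritParams relative_sensitivity
#' @return Proportion in `[0, 1]`.
#' @export
radiologist_sensitivity <- function(exams) {
  exams <- as.data.frame(exams)
  .check_metric_cols(exams, c("class", "assessment"))
  pos <- exams[exams$class == "positive", , drop = FALSE]
  if (!nrow(pos)) stop("no positive examinations; sensitivity undefined")
  mean(radiologist_true_positive(pos))
}

#' Simulated human-plus-device workflow sensitivity
#'
#' Fraction of cancer-positive examinations detected under the rule-out
#' workflow: radiologist-recalled and retained by the device. Equals
#' [radiologist_sensitivity()] times [relative_sensitivity()] exactly.
#'
#' @inheritParams relative_sensitivity
#' @return Proportion in `[0, 1]`.
#' @export
workflow_sensitivity <- function(exams, point) {
  exams <- as.data.frame(exams)
  .check_metric_cols(exams, c("class", "assessment", "device_score"))
  t <- .get_threshold(point)
  pos <- exams[exams$class == "positive", , drop = FALSE]
  if (!nrow(pos)) stop("no positive examinations; sensitivity undefined")
  mean(radiologist_true_positive(pos) & pos$device_score >= t)
}

#' Rule-out rate
#'
#' The (optionally prevalence-weighted) fraction of screening
#' examinations with a device score below the rule-out threshold,
#' computed over non-excluded examinations.
#'
#' @inheritParams relative_sensitivity
#' @param weights Optional named per-subclass weights from
#'   [prevalence_weights()].
#' @return Proportion in `[0, 1]`.
#' @export
ruleout_rate <- function(exams, point, weights = NULL) {
  exams <- as.data.frame(exams)
  .check_metric_cols(exams, c("class", "exam_label", "device_score"))
  t <- .get_threshold(point)
  keep <- exams$class != "excluded"
  exams <- exams[keep, , drop = FALSE]
  w <- .exam_weights(exams, weights)
  sum(w * (exams$device_score < t)) / sum(w)
}

#' Cancer detection rate per 1000 examinations
#'
#' Screen-detected cancers (radiologist true positives; with the device,
#' those additionally retained at the threshold) per 1000 (weighted)
#' examinations.
#'
#' @inheritParams ruleout_rate
#' @param point Operating point or threshold; `NULL` gives the
#'   standard-workflow (no device) CDR.
#' @return Detections per 1000 examinations.
#' @export
cdr <- function(exams, point = NULL, weights = NULL) {
  exams <- as.data.frame(exams)
  .check_metric_cols(exams, c("class", "exam_label", "assessment",
                              "device_score"))
  t <- .get_threshold(point)
  exams <- exams[exams$class != "excluded", , drop = FALSE]
  if (!nrow(exams)) stop("no examinations")
  w <- .exam_weights(exams, weights)
  detected <- exams$class == "positive" &
    as.integer(exams$assessment) %in% c(0L, 4L, 5L, 6L)
  if (!is.null(t)) detected <- detected & exams$device_score >= t
  1000 * sum(w * detected) / sum(w)
}

#' False-positive callback reduction rate
#'
#' Fraction of false-positive callbacks (cancer-negative examinations
#' recalled for diagnostic workup) that the device rules out, i.e. whose
#' diagnostic workup is avoided.
#'
#' @inheritParams ruleout_rate
#' @return Proportion in `[0, 1]`.
#' @export
fp_callback_reduction <- function(exams, point, weights = NULL) {
  exams <- as.data.frame(exams)
  .check_metric_cols(exams, c("class", "exam_label", "assessment",
                              "device_score"))
  t <- .get_threshold(point)
  fp <- exams$class == "negative" & .is_callback(exams$assessment)
  if (!any(fp)) stop("no false-positive callbacks; reduction undefined")
  exams <- exams[fp, , drop = FALSE]
  w <- .exam_weights(exams, weights)
  sum(w * (exams$device_score < t)) / sum(w)
}

#' Benign biopsy reduction rate
#'
#' Fraction of examinations with benign-biopsy outcomes (labels P or H)
#' that the device rules out, avoiding the biopsy.
#'
#' @inheritParams ruleout_rate
#' @return Proportion in `[0, 1]`.
#' @export
benign_biopsy_reduction <- function(exams, point, weights = NULL) {
  exams <- as.data.frame(exams)
  .check_metric_cols(exams, c("exam_label", "device_score"))
  t <- .get_threshold(point)
  bb <- as.character(exams$exam_label) %in% c("P", "H")
  if (!any(bb)) stop("no benign-biopsy examinations; reduction undefined")
  exams <- exams[bb, , drop = FALSE]
  w <- .exam_weights(exams, weights)
  sum(w * (exams$device_score < t)) / sum(w)
}

#' Specificity with and without the rule-out device
#'
#' Without the device, specificity is the fraction of cancer-negative
#' examinations assessed BI-RADS 1 or 2. With the device, a negative
#' examination also counts as correctly dismissed when it is ruled out.
#'
#' @inheritParams ruleout_rate
#' @param point Operating point or threshold; `NULL` gives the
#'   standard-workflow specificity.
#' @return Proportion in `[0, 1]`.
#' @export
specificity <- function(exams, point = NULL, weights = NULL) {
  exams <- as.data.frame(exams)
  .check_metric_cols(exams, c("class", "exam_label", "assessment",
                              "device_score"))
  t <- .get_threshold(point)
  neg <- exams$class == "negative"
  if (!any(neg)) stop("no negative examinations; specificity undefined")
  exams <- exams[neg, , drop = FALSE]
  w <- .exam_weights(exams, weights)
  ok <- !.is_callback(exams$assessment)
  if (!is.null(t)) ok <- ok | exams$device_score < t
  sum(w * ok) / sum(w)
}

#' Prevalence weights for enrichment rebalancing
#'
#' Case-enriched evaluation sets over-represent cancer subclasses. To
#' make prevalence-dependent metrics reflect a natural screening
#' population, each examination is weighted by
#' `target(c) / observed_proportion(c)` for its subclass `c`, so weighted
#' subclass proportions equal the target prevalence vector exactly.
#'
#' @param observed Named nonnegative integer counts per subclass
#'   (over N, S, D, P, H, M, I).
#' @param target Named nonnegative prevalence vector summing to 1.
#' @return A named numeric vector of class `prevalence_weights`.
#' @export
#' @examples
#' prevalence_weights(c(N = 90, M = 10), c(N = 0.99, M = 0.01))
prevalence_weights <- function(observed, target) {
  if (is.null(names(observed)) || is.null(names(target))) {
    stop("observed and target must be named by subclass")
  }
  if (abs(sum(target) - 1) > 1e-9) stop("target prevalences must sum to 1")
  if (any(target < 0) || any(observed < 0)) {
    stop("counts and prevalences must be nonnegative")
  }
  obs <- observed[names(target)]
  obs[is.na(obs)] <- 0
  zero_obs <- names(target)[target > 0 & obs == 0]
  if (length(zero_obs)) {
    stop("target prevalence > 0 but no observed examinations for ",
         "subclass(es): ", paste(zero_obs, collapse = ", "))
  }
  total <- sum(observed)
  w <- target / (obs / total)
  w[target == 0] <- 0
  structure(as.numeric(w), names = names(target),
            class = "prevalence_weights")
}

#' @export
print.prevalence_weights <- function(x, ...) {
  cat("Prevalence weights (target / observed proportion):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Metric set for one group of examinations
#'
#' Computes the standard panel — radiologist and workflow sensitivity,
#' specificity with/without device, CDR with/without device, rule-out
#' rate and the two reduction rates — returning one row per metric.
#' Metrics undefined on the group (e.g. no callbacks) are returned as NA.
#'
#' @inheritParams ruleout_rate
#' @param group Label recorded in the output.
#' @return `data.frame` with columns `metric`, `group`, `value`,
#'   `weighted`.
#' @export
metric_panel <- function(exams, point, weights = NULL, group = "all") {
  safe <- function(f) tryCatch(f, error = function(e) NA_real_)
  vals <- c(
    sensitivity_radiologist = safe(radiologist_sensitivity(exams)),
    sensitivity_workflow = safe(workflow_sensitivity(exams, point)),
    sensitivity_abs = safe(absolute_sensitivity(exams, point)),
    sensitivity_rel = safe(relative_sensitivity(exams, point)),
    specificity = safe(specificity(exams, NULL, weights)),
    specificity_workflow = safe(specificity(exams, point, weights)),
    cdr = safe(cdr(exams, NULL, weights)),
    cdr_workflow = safe(cdr(exams, point, weights)),
    ruleout_rate = safe(ruleout_rate(exams, point, weights)),
    fp_callback_reduction = safe(fp_callback_reduction(exams, point, weights)),
    benign_biopsy_reduction = safe(benign_biopsy_reduction(exams, point, weights))
  )
  data.frame(metric = names(vals), group = group, value = unname(vals),
             weighted = !is.null(weights), stringsAsFactors = FALSE)
}

#' Stratified metric summaries by reader or scanner
#'
#' Computes the metric panel per stratum. Following the per-reader
#' inclusion rule, a stratum is reported only if it contains at least
#' `min_pos` cancer-positive and `min_neg` cancer-negative examinations;
#' omitted strata still contribute to the collective row, in which every
#' examination has equal weight.
#'
#' @inheritParams ruleout_rate
#' @param by `"reader"` (uses column `reader_id`) or `"scanner"`.
#' @param min_pos,min_neg Inclusion minima (default 10 and 10).
#' @return `data.frame` of metric rows; the collective summary has group
#'   `"collective"`.
#' @export
stratify_and_summarize <- function(exams, point, by = c("reader", "scanner"),
                                   weights = NULL, min_pos = 10, min_neg = 10) {
  by <- match.arg(by)
  exams <- as.data.frame(exams)
  key <- if (by == "reader") "reader_id" else "scanner"
  .check_metric_cols(exams, c(key, "class"))
  out <- metric_panel(exams, point, weights, group = "collective")
  for (g in sort(unique(as.character(exams[[key]])))) {
    sub <- exams[exams[[key]] == g, , drop = FALSE]
    if (sum(sub$class == "positive") < min_pos ||
        sum(sub$class == "negative") < min_neg) next
    out <- rbind(out, metric_panel(sub, point, weights, group = g))
  }
  rownames(out) <- NULL
  out
}

#' Screening workflow flow table, normalized per 10 000 examinations
#'
#' Accounts for where examinations go in the standard workflow and in the
#' rule-out workflow: ruled out vs read by radiologists, callbacks vs
#' negatives among the read, benign biopsies and detected cancers among
#' the callbacks. Counts are (optionally weighted) and normalized to
#' `per` screening examinations; the nodes conserve the total at every
#' split.
#'
#' @inheritParams ruleout_rate
#' @param per Normalisation (default 10 000).
#' @return `data.frame` with columns `node`, `standard`, `ruleout`.
#' @export
flow_table <- function(exams, point, weights = NULL, per = 10000) {
  exams <- as.data.frame(exams)
  .check_metric_cols(exams, c("class", "exam_label", "assessment",
                              "device_score"))
  t <- .get_threshold(point)
  exams <- exams[exams$class != "excluded", , drop = FALSE]
  w <- .exam_weights(exams, weights)
  w <- w / sum(w) * per
  ruled <- exams$device_score < t
  cb <- .is_callback(exams$assessment)
  bb <- as.character(exams$exam_label) %in% c("P", "H")
  det <- exams$class == "positive" &
    as.integer(exams$assessment) %in% c(0L, 4L, 5L, 6L)
  node <- function(std_mask, ro_mask) c(sum(w[std_mask]), sum(w[ro_mask]))
  rows <- rbind(
    total = node(TRUE & rep(TRUE, length(w)), rep(TRUE, length(w))),
    ruled_out = node(rep(FALSE, length(w)), ruled),
    radiologist_read = node(rep(TRUE, length(w)), !ruled),
    callbacks = node(cb, cb & !ruled),
    screen_negatives = node(!cb, !cb & !ruled),
    benign_biopsies = node(bb & cb, bb & cb & !ruled),
    cancers_detected = node(det, det & !ruled)
  )
  data.frame(node = rownames(rows), standard = rows[, 1], ruleout = rows[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}
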
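#' Select the rule-out operating threshold at a target sensitivity
#'
#' Examinations with device scores below the threshold are ruled out
#' (assigned a negative prediction); scores greater than or equal to the
#' threshold are retained for human reading. The threshold is chosen on a
#' validation set as the largest candidate value such that the fraction
#' of cancer-positive examinations with score >= threshold is at least
#' `target_sensitivity` — i.e. the rule-out volume is maximised subject to
#' the sensitivity constraint. Candidate thresholds are the observed score
#' values plus 0.
#'
#' @param scores Numeric device scores in `[0, 1]`.
#' @param positive Logical, cancer-positive flag per score.
#' @param target_sensitivity Target cancer sensitivity in `(0, 1]`
#'   (typically 0.99 or 0.97).
#' @return An `operating_point` object: list with `threshold`,
#'   `target_sensitivity`, `achieved_validation_sensitivity`,
#'   `n_positive`, `n`.
#' @export
#' @examples
#' select_operating_threshold(c(0.2, 0.5, 0.9), c(TRUE, TRUE, TRUE), 2 / 3)
select_operating_threshold <- function(scores, positive, target_sensitivity) {
  scores <- as.numeric(scores)
  positive <- as.logical(positive)
  if (length(scores) != length(positive)) {
    stop("scores and positive must have the same length")
  }
  if (anyNA(scores) || any(!is.finite(scores)) ||
      any(scores < 0 | scores > 1)) {
    stop("scores must be finite values in [0, 1]")
  }
  if (!any(positive)) stop("at least one positive examination is required")
  if (length(target_sensitivity) != 1L || is.na(target_sensitivity) ||
      target_sensitivity <= 0 || target_sensitivity > 1) {
    stop("target_sensitivity must be in (0, 1]")
  }
  pos <- scores[positive]
  np <- length(pos)
  candidates <- sort(unique(c(0, scores)))
  # sensitivity at candidate t: fraction of positives with score >= t
  sp <- sort(pos)
  n_lt <- findInterval(candidates, sp, left.open = TRUE)  # positives < t
  sens <- (np - n_lt) / np
  feasible <- sens >= target_sensitivity
  threshold <- max(candidates[feasible])
  achieved <- sens[which(candidates == threshold)]
  if (target_sensitivity < 1 && (np - 1) / np < target_sensitivity) {
    warning("no threshold above the minimum positive score meets the ",
            "sensitivity target; all positives are retained")
  }
  structure(
    list(threshold = threshold,
         target_sensitivity = target_sensitivity,
         achieved_validation_sensitivity = achieved,
         n_positive = np,
         n = length(scores)),
    class = "operating_point"
  )
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "Rule-out operating point\n  threshold: %.6g\n  target sensitivity: %.4g\n  achieved validation sensitivity: %.4g (%d positives, %d exams)\n",
    x$threshold, x$target_sensitivity, x$achieved_validation_sensitivity,
    x$n_positive, x$n))
  invisible(x)
}

#' Simulate the rule-out workflow on a set of examinations
#'
#' Examinations with a device score strictly below the operating threshold
#' are ruled out and assigned a negative prediction (BI-RADS 1); ties at
#' the threshold are retained for human reading. All other examinations
#' keep the original clinical assessment, modelling radiologists whose
#' interpretations are unaffected by the device.
#'
#' @param exams `data.frame` with `exam_id`, `device_score` and
#'   `assessment` columns.
#' @param point An [operating_point][select_operating_threshold] or a
#'   single numeric threshold.
#' @return `data.frame` with `exam_id`, `ruled_out`,
#'   `effective_assessment`, in the input row order.
#' @export
apply_ruleout <- function(exams, point) {
  exams <- as.data.frame(exams)
  req <- c("exam_id", "device_score", "assessment")
  if (!all(req %in% names(exams))) {
    stop("exams must have columns: ", paste(req, collapse = ", "))
  }
  threshold <- if (inherits(point, "operating_point")) point$threshold
               else as.numeric(point)
  stopifnot(length(threshold) == 1L, !is.na(threshold))
  if (anyNA(exams$device_score)) {
    stop("missing device score for exam(s): ",
         paste(utils::head(exams$exam_id[is.na(exams$device_score)], 10L),
               collapse = ", "))
  }
  ruled_out <- exams$device_score < threshold
  data.frame(
    exam_id = exams$exam_id,
    ruled_out = ruled_out,
    effective_assessment = ifelse(ruled_out, 1L,
                                  as.integer(exams$assessment)),
    stringsAsFactors = FALSE
  )
}

#' Combined sensitivity of the human-plus-device workflow
#'
#' The sensitivity of the rule-out workflow is the product of the standard
#' workflow's sensitivity (the radiologist sensitivity) and the device's
#' relative sensitivity (the fraction of radiologist-detected cancers the
#' device retains). Because the device can only remove detections, never
#' add them, this product equals the directly simulated workflow
#' sensitivity exactly.
#'
#' @param radiologist_sensitivity,relative_device_sensitivity Proportions
#'   in `[0, 1]`.
#' @return Their product.
#' @export
#' @examples
#' combined_workflow_sensitivity(552 / 595, 550 / 552)  # 550/595
combined_workflow_sensitivity <- function(radiologist_sensitivity,
                                          relative_device_sensitivity) {
  for (x in list(radiologist_sensitivity, relative_device_sensitivity)) {
    if (anyNA(x) || any(x < 0 | x > 1)) {
      stop("sensitivities must lie in [0, 1]")
    }
  }
  radiologist_sensitivity * relative_device_sensitivity
}
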
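# Independent oracles and fixture builders shared across tests.

# Exhaustive threshold search: largest candidate (observed scores plus 0)
# whose positive-score sensitivity meets the target.
brute_force_threshold <- function(scores, positive, target) {
  pos <- scores[positive]
  candidates <- sort(unique(c(0, scores)))
  sens <- vapply(candidates, function(t) mean(pos >= t), numeric(1))
  keep <- sens >= target
  list(threshold = max(candidates[keep]),
       achieved = sens[max(which(keep))])
}

# Delta-method standard error of a weighted ratio sum(w*x)/sum(w*z),
# exams independent (x, z 0/1 indicators, x <= z).
weighted_ratio_se <- function(w, x, z = rep(1, length(x))) {
  r <- sum(w * x) / sum(w * z)
  sqrt(sum((w * (x - r * z))^2)) / sum(w * z)
}

# A classified exam table built directly from counts: n_pos positives of
# which n_detected are radiologist-detected (assessment 0, rest 1), and
# among the detected ones n_retained have scores above the threshold 0.5.
# Negatives are split between clean negatives and FP callbacks.
fixture_from_counts <- function(n_pos, n_detected, n_retained,
                                n_neg = 0, n_fp_callback = 0,
                                n_fp_ruled = 0) {
  stopifnot(n_detected <= n_pos, n_retained <= n_detected,
            n_fp_callback <= n_neg, n_fp_ruled <= n_fp_callback)
  pos <- data.frame(
    exam_id = sprintf("pos%04d", seq_len(n_pos)),
    class = "positive",
    exam_label = "M",
    assessment = rep(c(0L, 1L), c(n_detected, n_pos - n_detected)),
    device_score = c(rep(c(0.9, 0.1), c(n_retained, n_detected - n_retained)),
                     rep(0.9, n_pos - n_detected))
  )
  if (n_neg == 0) return(pos)
  neg <- data.frame(
    exam_id = sprintf("neg%04d", seq_len(n_neg)),
    class = "negative",
    exam_label = rep(c("D", "N"), c(n_fp_callback, n_neg - n_fp_callback)),
    assessment = rep(c(0L, 1L), c(n_fp_callback, n_neg - n_fp_callback)),
    device_score = c(rep(c(0.1, 0.9), c(n_fp_ruled, n_fp_callback - n_fp_ruled)),
                     rep(0.9, n_neg - n_fp_callback))
  )
  rbind(pos, neg)
}

# Minimal event table builder: rows are lists
# (patient, side, date, type, value).
make_events <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = r[[1]], side = r[[2]], date = as.Date(r[[3]]),
               event_type = r[[4]], value = r[[5]], stringsAsFactors = FALSE)
  }))
}

# Small generator config with fast defaults for property tests.
quick_config <- function(n = 2000, seed = 1, ...) {
  generator_config(n_exams = n, seed = seed, ...)
}
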
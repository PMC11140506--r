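# Paired noninferiority testing and bootstrap inference.

#' Paired noninferiority z test for proportions
#'
#' Tests whether the rule-out workflow's success proportion is not
#' inferior to the standard workflow's by more than `margin`, on `n`
#' paired units (examinations read under both workflows). With `b` pairs
#' succeeding only under the standard workflow and `c` only under the
#' rule-out workflow, the paired difference is `d = (b - c)/n` and the
#' hypotheses are `H0: d >= margin` vs `H1: d < margin`.
#'
#' The statistic is a score-type z with the variance constrained to the
#' noninferiority boundary, `var0 = ((2c)/n + margin - margin^2)/n`, and
#' a 0.5/n continuity correction:
#' `z = (margin - d - 0.5/n) / sqrt(var0)`, with the one-sided p value
#' from the upper normal tail. In the structural rule-out case (`c = 0`,
#' the device can only remove detections) this closely reproduces the
#' exact paired-binomial enumeration `P(B <= b)` with
#' `B ~ Binomial(n, margin)`; when `b = c = 0` the exact enumeration
#' `(1 - margin)^n` is used directly.
#'
#' @param b Pairs succeeding under the standard workflow only (losses).
#' @param c Pairs succeeding under the rule-out workflow only (0
#'   structurally when the device can only remove detections).
#' @param n Number of paired units.
#' @param margin Noninferiority margin as a proportion (0.05 for
#'   sensitivity; 0.00025 for CDR, i.e. 0.25 per 1000 examinations).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `c("noninferiority_test", "htest")` with
#'   `statistic`, `p.value`, `estimate` (the paired difference), `margin`
#'   and `conclusion` (`"noninferior"` or `"inconclusive"`).
#' @export
#' @examples
#' noninferiority_paired_z(b = 2, c = 0, n = 595, margin = 0.05)
noninferiority_paired_z <- function(b, c = 0, n, margin, alpha = 0.05) {
  stopifnot(length(b) == 1L, length(c) == 1L, length(n) == 1L)
  b <- as.integer(b); c <- as.integer(c); n <- as.integer(n)
  if (n <= 0) stop("n must be positive")
  if (b < 0 || c < 0 || b + c > n) stop("invalid paired counts")
  if (margin <= 0) stop("margin must be positive")
  d_hat <- (b - c) / n
  if (b == 0 && c == 0) {
    # No discordant pairs: exact enumeration at the boundary null.
    p <- (1 - margin)^n
    z <- NA_real_
    method <- "Exact paired-binomial noninferiority test (no discordant pairs)"
  } else {
    var0 <- ((2 * c) / n + margin - margin^2) / n
    z <- (margin - d_hat - 0.5 / n) / sqrt(var0)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "Noninferiority z test for paired proportions"
  }
  structure(
    list(statistic = c(z = z),
         p.value = p,
         estimate = c(`paired difference` = d_hat),
         margin = margin,
         alpha = alpha,
         conclusion = if (p < alpha) "noninferior" else "inconclusive",
         method = method,
         data.name = sprintf("b = %d, c = %d, n = %d", b, c, n)),
    class = c("noninferiority_test", "htest")
  )
}

#' @export
print.noninferiority_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n")
  cat("data: ", x$data.name, "\n")
  if (!is.na(x$statistic)) cat(sprintf("z = %.4f, ", x$statistic))
  cat(sprintf("p-value = %.4g\n", x$p.value))
  cat(sprintf("margin = %g, paired difference = %.6g\n",
              x$margin, x$estimate))
  cat("conclusion:", x$conclusion, "\n\n")
  invisible(x)
}

#' Bootstrap percentile confidence interval for a screening metric
#'
#' Resamples examinations (or whole patients) with replacement and
#' returns the percentile interval of the statistic over the replicates.
#' Resampling can be stratified by outcome subclass so each replicate
#' preserves the subclass counts — prevalence-adjusted metrics are
#' undefined when a subclass vanishes from a resample. Replicates on
#' which the statistic is undefined (error or `NA`) are redrawn up to
#' `max_redraw` times; if more than half the replicates remain undefined
#' the interval is not reported.
#'
#' @param statistic_fn Function of a resampled exam table returning one
#'   number.
#' @param exams Exam table (`data.frame`).
#' @param n_reps Number of bootstrap replicates (default 2000).
#' @param seed Optional integer seed; given the seed, input order and
#'   `n_reps`, results are reproducible.
#' @param unit `"exam"` (rows independent) or `"patient"` (resample
#'   patients, keeping each patient's exams together).
#' @param stratify_by Optional column name (e.g. `"exam_label"`) for
#'   stratified resampling.
#' @param level Confidence level (default 0.95).
#' @param max_redraw Redraw attempts per degenerate replicate.
#' @return Object of class `bootstrap_ci`: list with `ci_low`, `ci_high`,
#'   `replicates`, `n_reps`, `level`, `n_undefined`.
#' @export
bootstrap_ci <- function(statistic_fn, exams, n_reps = 2000, seed = NULL,
                         unit = c("exam", "patient"), stratify_by = NULL,
                         level = 0.95, max_redraw = 10) {
  unit <- match.arg(unit)
  exams <- as.data.frame(exams)
  stopifnot(n_reps >= 1, level > 0, level < 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  n <- nrow(exams)
  if (!is.null(stratify_by)) {
    if (!stratify_by %in% names(exams)) {
      stop("stratification column not found: ", stratify_by)
    }
    strata <- split(seq_len(n), exams[[stratify_by]])
  }
  pat_split <- if (unit == "patient") {
    split(seq_len(n), exams$patient_id)
  } else NULL

  draw_idx <- function() {
    if (unit == "patient") {
      pats <- sample(length(pat_split), length(pat_split), replace = TRUE)
      unlist(pat_split[pats], use.names = FALSE)
    } else if (!is.null(stratify_by)) {
      unlist(lapply(strata, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
    } else {
      sample.int(n, n, replace = TRUE)
    }
  }

  reps <- rep(NA_real_, n_reps)
  n_undef <- 0L
  for (r in seq_len(n_reps)) {
    for (attempt in seq_len(max_redraw + 1L)) {
      val <- tryCatch(
        statistic_fn(exams[draw_idx(), , drop = FALSE]),
        error = function(e) NA_real_)
      if (length(val) == 1L && is.finite(val)) break
      val <- NA_real_
    }
    if (is.na(val)) n_undef <- n_undef + 1L
    reps[r] <- val
  }
  if (n_undef > n_reps / 2) {
    stop("statistic undefined on ", n_undef, " of ", n_reps,
         " bootstrap replicates (after up to ", max_redraw,
         " redraws each); check for vanishing denominators")
  }
  qs <- stats::quantile(reps, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(
    list(ci_low = qs[1], ci_high = qs[2], replicates = reps,
         n_reps = n_reps, level = level, n_undefined = n_undef,
         unit = unit, stratified = !is.null(stratify_by)),
    class = "bootstrap_ci"
  )
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf(
    "Bootstrap percentile CI (%.0f%%, %d reps%s, unit = %s): [%.6g, %.6g]\n",
    100 * x$level, x$n_reps,
    if (x$stratified) ", stratified" else "", x$unit, x$ci_low, x$ci_high))
  if (x$n_undefined > 0) {
    cat("  (", x$n_undefined, "replicate(s) undefined )\n")
  }
  invisible(x)
}

#' One-sided superiority p value from bootstrap replicates
#'
#' Inverts the bootstrap distribution of a statistic (e.g. a reduction
#' rate) to test `H0: statistic <= null_value` against superiority:
#' `p = (1 + #{replicates <= null_value}) / (n_reps + 1)`.
#'
#' @param replicates Numeric bootstrap replicates of the statistic.
#' @param null_value Null value (default 0).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `c("superiority_test", "htest")`.
#' @export
superiority_p_from_bootstrap <- function(replicates, null_value = 0,
                                         alpha = 0.05) {
  if (inherits(replicates, "bootstrap_ci")) replicates <- replicates$replicates
  replicates <- replicates[!is.na(replicates)]
  if (!length(replicates)) stop("no bootstrap replicates supplied")
  p <- (1 + sum(replicates <= null_value)) / (length(replicates) + 1)
  structure(
    list(statistic = c(`median replicate` = stats::median(replicates)),
         p.value = p,
         null.value = c(statistic = null_value),
         alpha = alpha,
         conclusion = if (p < alpha) "superior" else "not_superior",
         method = "One-sided superiority test by bootstrap CI inversion",
         data.name = paste(length(replicates), "bootstrap replicates")),
    class = c("superiority_test", "htest")
  )
}

#' @export
print.superiority_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n")
  cat("data: ", x$data.name, "\n")
  cat(sprintf("p-value = %.4g (null value %g)\n", x$p.value, x$null.value))
  cat("conclusion:", x$conclusion, "\n\n")
  invisible(x)
}
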
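# Schema-validated CSV I/O and pipeline orchestration.

.parse_iso_date <- function(x, what, file) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & nzchar(as.character(x)))
  if (length(bad)) {
    stop("unparseable ISO-8601 date in ", file, ", column '", what,
         "', row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  d
}

#' Read and validate a screening cohort from CSV tables
#'
#' `exams_path` must have columns `exam_id`, `patient_id`, `exam_date`
#' (ISO-8601), `assessment` (BI-RADS code, or a UK reader opinion string
#' when `uk_opinion_mapping = TRUE`), `device_score`; `reader_id` /
#' `reader_ids` and `scanner` are carried through when present.
#' `events_path` must have `patient_id`, `side`, `date`, `event_type`,
#' `value`. Rows failing validation (bad dates, scores outside `[0, 1]`,
#' duplicate exam ids, unknown event types) are rejected with the row
#' numbers named.
#'
#' @param exams_path,events_path CSV file paths.
#' @param uk_opinion_mapping Map UK opinion strings to BI-RADS codes via
#'   [map_uk_opinion()] (screening context for exam assessments,
#'   nonscreening for diagnostic event values).
#' @return List with validated `exams` and `events` data frames.
#' @export
read_cohort <- function(exams_path, events_path, uk_opinion_mapping = FALSE) {
  for (f in c(exams_path, events_path)) {
    if (!file.exists(f)) stop("file not found: ", f)
  }
  exams <- utils::read.csv(exams_path, stringsAsFactors = FALSE)
  events <- utils::read.csv(events_path, stringsAsFactors = FALSE)

  req_x <- c("exam_id", "patient_id", "exam_date", "assessment",
             "device_score")
  miss <- setdiff(req_x, names(exams))
  if (length(miss)) {
    stop("missing column(s) in ", exams_path, ": ",
         paste(miss, collapse = ", "))
  }
  req_e <- c("patient_id", "side", "date", "event_type", "value")
  miss <- setdiff(req_e, names(events))
  if (length(miss)) {
    stop("missing column(s) in ", events_path, ": ",
         paste(miss, collapse = ", "))
  }

  dup <- unique(exams$exam_id[duplicated(exams$exam_id)])
  if (length(dup)) {
    stop("duplicate exam_id(s) in ", exams_path, ": ",
         paste(utils::head(dup, 10L), collapse = ", "))
  }
  exams$exam_date <- .parse_iso_date(exams$exam_date, "exam_date", exams_path)
  events$date <- .parse_iso_date(events$date, "date", events_path)

  if (uk_opinion_mapping) {
    exams$assessment <- map_uk_opinion(exams$assessment, "screening")
    scr <- events$event_type == "screen_assess"
    dia <- events$event_type == "diag_assess"
    is_op <- events$value %in% c("normal", "benign", "suspicious",
                                 "uncertain", "malignant")
    events$value[scr & is_op] <-
      as.character(map_uk_opinion(events$value[scr & is_op], "screening"))
    events$value[dia & is_op] <-
      as.character(map_uk_opinion(events$value[dia & is_op], "nonscreening"))
  }
  a <- suppressWarnings(as.integer(exams$assessment))
  bad <- which(is.na(a) | !(a %in% 0:6))
  if (length(bad)) {
    stop("invalid assessment in ", exams_path, ", row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  exams$assessment <- a
  sc <- suppressWarnings(as.numeric(exams$device_score))
  bad <- which(is.na(sc) | sc < 0 | sc > 1)
  if (length(bad)) {
    stop("device_score outside [0, 1] in ", exams_path, ", row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  exams$device_score <- sc
  ok_types <- c("screen_assess", "diag_assess", "biopsy")
  bad <- which(!(events$event_type %in% ok_types))
  if (length(bad)) {
    stop("unknown event_type in ", events_path, ", row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  ok_side <- events$side %in% c("left", "right")
  if (!all(ok_side)) {
    stop("side must be 'left' or 'right' in ", events_path, ", row(s): ",
         paste(utils::head(which(!ok_side), 5L), collapse = ", "))
  }
  bx <- events$event_type == "biopsy"
  bad <- which(bx & !(events$value %in% c("benign", "high_risk", "malignant")))
  if (length(bad)) {
    stop("invalid biopsy value in ", events_path, ", row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  message(nrow(exams), " examinations and ", nrow(events),
          " events read")
  list(exams = exams, events = events)
}

#' Write a synthetic cohort to CSV (and its truth table)
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("exams.csv", "events.csv", "truth.csv"))
  utils::write.csv(cohort$exams, paths[1], row.names = FALSE)
  utils::write.csv(cohort$events, paths[2], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Run the full rule-out evaluation pipeline
#'
#' Orchestrates labeling, threshold selection, workflow simulation,
#' metric computation with bootstrap confidence intervals and the paired
#' noninferiority test, writing all outputs under `config$out_dir`:
#' `labeled_exams.csv`, `operating_point.json`, `metrics.csv`,
#' `flow_table.csv`, per-scanner and per-reader breakdowns, and a copy of
#' the resolved configuration (`run_config.yaml`).
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `exams`, `events` (paths); optional `validation_exams`,
#'   `validation_events` (threshold selection set; defaults to the test
#'   tables); `windows` (default 12), `interval_months` (default 12),
#'   `followup_min_months` (24), `target_sensitivity` (0.99),
#'   `prevalence_target` (named vector; omit for unweighted metrics),
#'   `per_scanner` (FALSE), `uk_opinion_mapping` (FALSE), `bootstrap`
#'   (list: `n_reps` 2000, `unit` "exam", `stratified` TRUE),
#'   `noninferiority` (list: `sensitivity_margin` 0.05,
#'   `cdr_margin_per_1000` 0.25), `alpha` (0.05), `seed`, `out_dir`.
#' @return Invisibly, a list with the labeled exams, operating point(s),
#'   metric table, flow table and test results per window.
#' @export
run_evaluation <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(windows = 12, interval_months = 12,
                   followup_min_months = 24, target_sensitivity = 0.99,
                   per_scanner = FALSE, uk_opinion_mapping = FALSE,
                   alpha = 0.05, seed = 1L, out_dir = "ruleout_results")
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  boot <- utils::modifyList(list(n_reps = 2000, unit = "exam",
                                 stratified = TRUE),
                            config$bootstrap %||% list())
  noninf <- utils::modifyList(list(sensitivity_margin = 0.05,
                                   cdr_margin_per_1000 = 0.25),
                              config$noninferiority %||% list())
  if (is.null(config$exams) || is.null(config$events)) {
    stop("config must name 'exams' and 'events' input files")
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  message("[read] ", config$exams, " + ", config$events)
  dat <- read_cohort(config$exams, config$events, config$uk_opinion_mapping)

  message("[label] interval ", config$interval_months, " months")
  labeled <- label_cohort(dat$exams, dat$events,
                          interval_months = config$interval_months,
                          followup_min_months = config$followup_min_months)
  utils::write.csv(labeled, file.path(config$out_dir, "labeled_exams.csv"),
                   row.names = FALSE)

  # threshold selection set: validation tables when given, else the
  # evaluation tables themselves (single-shot use)
  if (!is.null(config$validation_exams)) {
    val <- read_cohort(config$validation_exams, config$validation_events,
                       config$uk_opinion_mapping)
    val_lab <- label_cohort(val$exams, val$events,
                            interval_months = config$interval_months,
                            followup_min_months = config$followup_min_months)
  } else {
    val_lab <- labeled
  }
  val_cls <- classify_exams(val_lab, config$windows[1])
  keep <- val_cls$class != "excluded"
  message("[threshold] target sensitivity ", config$target_sensitivity)
  select_one <- function(d) {
    select_operating_threshold(d$device_score, d$class == "positive",
                               config$target_sensitivity)
  }
  points <- if (isTRUE(config$per_scanner)) {
    lapply(split(val_cls[keep, ], val_cls$scanner[keep]), select_one)
  } else {
    list(global = select_one(val_cls[keep, ]))
  }
  jsonlite::write_json(
    lapply(points, function(p) p[c("threshold", "target_sensitivity",
                                   "achieved_validation_sensitivity")]),
    file.path(config$out_dir, "operating_point.json"),
    auto_unbox = TRUE, digits = NA)

  results <- list()
  metrics_all <- NULL
  for (w in config$windows) {
    message("[evaluate] window ", w, " months")
    cls <- classify_exams(labeled, w)
    weights <- NULL
    if (!is.null(config$prevalence_target)) {
      weights <- prevalence_weights(subclass_counts(cls[cls$class != "excluded", ]),
                                    unlist(config$prevalence_target))
    }
    point <- points[[1]]
    if (isTRUE(config$per_scanner)) {
      # evaluate each scanner stratum at its own threshold
      per <- lapply(names(points), function(s) {
        metric_panel(cls[cls$scanner == s, ], points[[s]], weights,
                     group = paste0("scanner:", s))
      })
      panel <- do.call(rbind, per)
    } else {
      panel <- metric_panel(cls, point, weights)
      if ("scanner" %in% names(cls)) {
        sc <- stratify_and_summarize(cls, point, "scanner", weights)
        sc <- sc[sc$group != "collective", , drop = FALSE]
        if (nrow(sc)) {
          sc$group <- paste0("scanner:", sc$group)
          panel <- rbind(panel, sc)
        }
      }
    }
    if ("reader_id" %in% names(cls)) {
      rd <- stratify_and_summarize(cls, point, "reader", weights)
      rd <- rd[rd$group != "collective", , drop = FALSE]
      if (nrow(rd)) {
        rd$group <- paste0("reader:", rd$group)
        panel <- rbind(panel, rd)
      }
    }
    panel$window <- w

    # bootstrap CIs and superiority p for the headline device metrics
    eval_set <- cls[cls$class != "excluded", ]
    ci_rows <- list()
    for (m in c("ruleout_rate", "fp_callback_reduction",
                "benign_biopsy_reduction")) {
      fn <- get(m, mode = "function")
      bci <- bootstrap_ci(
        function(d) fn(d, point, weights), eval_set,
        n_reps = boot$n_reps, seed = config$seed,
        unit = boot$unit,
        stratify_by = if (isTRUE(boot$stratified)) "exam_label" else NULL)
      sup <- superiority_p_from_bootstrap(bci, 0, config$alpha)
      ci_rows[[m]] <- data.frame(metric = m, ci_low = bci$ci_low,
                                 ci_high = bci$ci_high,
                                 p_superiority = sup$p.value,
                                 n_boot = boot$n_reps)
    }
    ci_tab <- do.call(rbind, ci_rows)
    panel <- merge(panel, ci_tab, by = "metric", all.x = TRUE, sort = FALSE)

    # paired noninferiority: sensitivity and CDR, standard vs rule-out
    pos <- cls[cls$class == "positive", ]
    rtp <- radiologist_true_positive(pos)
    lost <- sum(rtp & pos$device_score < point$threshold)
    ni_sens <- noninferiority_paired_z(
      b = lost, c = 0, n = nrow(pos),
      margin = noninf$sensitivity_margin, alpha = config$alpha)
    ni_cdr <- noninferiority_paired_z(
      b = lost, c = 0, n = nrow(eval_set),
      margin = noninf$cdr_margin_per_1000 / 1000, alpha = config$alpha)
    flow <- flow_table(cls, point, weights)

    results[[paste0("window_", w)]] <- list(
      classified = cls, metrics = panel, flow = flow,
      noninferiority_sensitivity = ni_sens, noninferiority_cdr = ni_cdr,
      weights = weights)
    metrics_all <- rbind(metrics_all, panel)
    utils::write.csv(flow,
                     file.path(config$out_dir,
                               paste0("flow_table_window", w, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(metrics_all, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  resolved <- config
  resolved$bootstrap <- boot
  resolved$noninferiority <- noninf
  yaml::write_yaml(lapply(resolved, function(x)
    if (inherits(x, "Date")) format(x) else x),
    file.path(config$out_dir, "run_config.yaml"))
  message(sprintf("[done] %.1f s; outputs in %s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  config$out_dir))
  invisible(list(labeled = labeled, operating_points = points,
                 metrics = metrics_all, windows = results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
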
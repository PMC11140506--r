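#' Construct a breast history
#'
#' A breast history is the date-ordered evidence for one breast of one
#' patient: screening assessments, diagnostic assessments, and biopsy
#' pathology results. Labeling additionally needs patient-level context
#' (events from both breasts) because the negative-type labels require no
#' biopsy event anywhere in the patient's history and a later follow-up
#' examination.
#'
#' @param patient_id Opaque identifier.
#' @param side `"left"` or `"right"`.
#' @param events `data.frame` with columns `date` (Date), `event_type`
#'   (one of `screen_assess`, `diag_assess`, `biopsy`) and `value`
#'   (BI-RADS code for assessments; `benign`, `high_risk` or `malignant`
#'   for biopsies). Rows need not be pre-sorted.
#' @param patient_events Events for the whole patient (both sides, with a
#'   `side` column); defaults to `events`, which is correct only when the
#'   patient has no events on the other breast.
#' @return A `breast_history` object.
#' @export
breast_history <- function(patient_id, side, events, patient_events = NULL) {
  side <- match.arg(side, c("left", "right"))
  events <- as.data.frame(events)
  req <- c("date", "event_type", "value")
  if (!all(req %in% names(events))) {
    stop("events must have columns: ", paste(req, collapse = ", "))
  }
  events$date <- as.Date(events$date)
  if (anyNA(events$date)) stop("events contain unparseable dates")
  ok_types <- c("screen_assess", "diag_assess", "biopsy")
  if (!all(events$event_type %in% ok_types)) {
    stop("unknown event_type(s): ",
         paste(setdiff(unique(events$event_type), ok_types), collapse = ", "))
  }
  bx <- events$event_type == "biopsy"
  ok_path <- c("benign", "high_risk", "malignant")
  if (!all(events$value[bx] %in% ok_path)) {
    stop("biopsy values must be one of: ", paste(ok_path, collapse = ", "))
  }
  code <- suppressWarnings(as.integer(events$value[!bx]))
  if (anyNA(code) || !all(code %in% 0:6)) {
    stop("assessment values must be BI-RADS codes 0-6")
  }
  events <- events[order(events$date), , drop = FALSE]
  scr <- events$date[events$event_type == "screen_assess"]
  if (anyDuplicated(scr)) {
    stop("at most one screening assessment per date per side (patient ",
         patient_id, ", ", side, ")")
  }
  if (is.null(patient_events)) {
    patient_events <- cbind(events, side = side)
  } else {
    patient_events <- as.data.frame(patient_events)
    patient_events$date <- as.Date(patient_events$date)
  }
  structure(
    list(patient_id = patient_id, side = side, events = events,
         patient_events = patient_events),
    class = "breast_history"
  )
}

#' @export
print.breast_history <- function(x, ...) {
  cat("Breast history: patient", x$patient_id, "-", x$side, "breast,",
      nrow(x$events), "event(s)\n")
  print(x$events, row.names = FALSE)
  invisible(x)
}

# Core labeling rule on pre-extracted vectors (dates as numeric days).
# Returns list(label, cancer_date). `code` is this side's screening
# assessment at the index exam; `horizon` = exam + interval months;
# `followup_date` = exam + follow-up minimum months.
.label_breast <- function(code, ev_date, ev_type, ev_value,
                          exam_date, horizon, followup_date,
                          pat_screen_dates, pat_has_biopsy) {
  callback <- !(code %in% c(1L, 2L))
  is_bx <- ev_type == "biopsy"
  bx_date <- ev_date[is_bx]
  bx_kind <- ev_value[is_bx]
  if (anyDuplicated(bx_date)) {
    for (d in unique(bx_date[duplicated(bx_date)])) {
      if (length(unique(bx_kind[bx_date == d])) > 1L) {
        stop("conflicting same-day pathology entries on ",
             as.Date(d, origin = "1970-01-01"))
      }
    }
  }
  # Callback-path pathology includes same-day results; the interval-cancer
  # window is half-open at the exam date.
  in_win <- if (callback) {
    bx_date >= exam_date & bx_date <= horizon
  } else {
    bx_date > exam_date & bx_date <= horizon
  }
  kinds <- bx_kind[in_win]
  dates <- bx_date[in_win]
  nxt <- pat_screen_dates[pat_screen_dates > exam_date]
  next_screen <- if (length(nxt)) min(nxt) else Inf

  if ("malignant" %in% kinds) {
    mdate <- min(dates[kinds == "malignant"])
    if (callback) return(list(label = "M", cancer_date = mdate))
    if (mdate < next_screen) return(list(label = "I", cancer_date = mdate))
    return(list(label = "U", cancer_date = NA_real_))
  }
  if ("high_risk" %in% kinds) return(list(label = "H", cancer_date = NA_real_))
  if ("benign" %in% kinds) return(list(label = "P", cancer_date = NA_real_))

  if (callback) {
    is_dx <- ev_type == "diag_assess" &
      ev_date >= exam_date & ev_date <= horizon
    dx_code <- suppressWarnings(as.integer(ev_value[is_dx]))
    resolved <- any(dx_code %in% c(1L, 2L, 3L), na.rm = TRUE)
    if (!resolved) return(list(label = "U", cancer_date = NA_real_))
    candidate <- "D"
  } else {
    candidate <- if (code == 2L) "S" else "N"
  }
  # Negative-type labels need a follow-up examination and a biopsy-free
  # patient history; otherwise the outcome is unknown.
  if (pat_has_biopsy) return(list(label = "U", cancer_date = NA_real_))
  if (!any(pat_screen_dates >= followup_date)) {
    return(list(label = "U", cancer_date = NA_real_))
  }
  list(label = candidate, cancer_date = NA_real_)
}

#' Assign the outcome label for one breast at one screening examination
#'
#' Applies the outcome labeling scheme: malignant pathology on the
#' callback pathway gives M; malignant pathology within the screening
#' interval after a negative/benign screen (and before the next screening
#' examination) gives I (interval cancer); nonupstaged high-risk pathology
#' gives H; benign pathology gives P; a recall (BI-RADS 0, or any
#' non-negative screening code) resolved by a negative diagnostic
#' assessment gives D; screening BI-RADS 2 gives S and BI-RADS 1 gives N.
#' The N, S and D labels additionally require a later screening
#' examination at least `followup_min_months` after the index examination
#' and no biopsy event anywhere in the patient's history; otherwise the
#' outcome is unknown (U). When several pathology results fall in the
#' window the most severe wins (malignant > high risk > benign).
#'
#' @param history A [breast_history()].
#' @param exam_date Date of the index screening examination; must carry a
#'   screening assessment in `history`.
#' @param interval_months Screening interval defining the interval-cancer
#'   and callback-resolution window (12 for annual US-style programmes,
#'   36 for the UK triennial programme).
#' @param followup_min_months Minimum follow-up for negative-type labels
#'   (default 24).
#' @return Single-character outcome label with attribute `cancer_date`
#'   (the malignant pathology date, `NA` unless the label is M or I).
#' @export
assign_breast_label <- function(history, exam_date, interval_months = 12,
                                followup_min_months = 24) {
  stopifnot(inherits(history, "breast_history"))
  exam_date <- as.Date(exam_date)
  ev <- history$events
  scr <- ev$event_type == "screen_assess" & ev$date == exam_date
  if (!any(scr)) {
    stop("no screening assessment on ", format(exam_date), " for patient ",
         history$patient_id, " (", history$side, " breast)")
  }
  code <- as.integer(ev$value[scr][1L])
  pe <- history$patient_events
  res <- .label_breast(
    code = code,
    ev_date = as.numeric(ev$date),
    ev_type = ev$event_type,
    ev_value = as.character(ev$value),
    exam_date = as.numeric(exam_date),
    horizon = as.numeric(add_months(exam_date, interval_months)),
    followup_date = as.numeric(add_months(exam_date, followup_min_months)),
    pat_screen_dates = as.numeric(pe$date[pe$event_type == "screen_assess"]),
    pat_has_biopsy = any(pe$event_type == "biopsy")
  )
  structure(res$label,
            cancer_date = as.Date(res$cancer_date, origin = "1970-01-01"))
}

#' Label every examination in a cohort
#'
#' Derives left and right breast labels from the event table, propagates
#' them to the examination level (most severe wins) and attaches the
#' cancer date for M/I examinations. Per-side screening assessments are
#' read from `screen_assess` events dated at the examination; if a side
#' has none, the examination-level `assessment` column is applied to both
#' sides (with a warning).
#'
#' @param exams `data.frame` with at least `exam_id`, `patient_id`,
#'   `exam_date`; an `assessment` column is used as per-side fallback.
#' @param events `data.frame` with `patient_id`, `side`, `date`,
#'   `event_type`, `value`.
#' @param interval_months,followup_min_months See [assign_breast_label()].
#' @return `exams` with added columns `left_label`, `right_label`,
#'   `exam_label`, `cancer_date`.
#' @export
label_cohort <- function(exams, events, interval_months = 12,
                         followup_min_months = 24) {
  exams <- as.data.frame(exams)
  events <- as.data.frame(events)
  req_x <- c("exam_id", "patient_id", "exam_date")
  req_e <- c("patient_id", "side", "date", "event_type", "value")
  if (!all(req_x %in% names(exams))) {
    stop("exams must have columns: ", paste(req_x, collapse = ", "))
  }
  if (!all(req_e %in% names(events))) {
    stop("events must have columns: ", paste(req_e, collapse = ", "))
  }
  exams$exam_date <- as.Date(exams$exam_date)
  events$date <- as.Date(events$date)
  n <- nrow(exams)

  # Per-patient event vectors, extracted once.
  ev_split <- split(seq_len(nrow(events)), events$patient_id)
  e_date <- as.numeric(events$date)
  e_side <- as.character(events$side)
  e_type <- as.character(events$event_type)
  e_val <- as.character(events$value)

  exam_num <- as.numeric(exams$exam_date)
  horizon <- as.numeric(add_months(exams$exam_date, interval_months))
  fup <- as.numeric(add_months(exams$exam_date, followup_min_months))
  fallback <- if ("assessment" %in% names(exams)) exams$assessment else NULL
  warned <- FALSE

  left_label <- character(n)
  right_label <- character(n)
  cancer_date <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    idx <- ev_split[[as.character(exams$patient_id[i])]]
    if (is.null(idx)) idx <- integer(0)
    d <- e_date[idx]; s <- e_side[idx]; ty <- e_type[idx]; v <- e_val[idx]
    pat_screen <- d[ty == "screen_assess"]
    has_bx <- any(ty == "biopsy")
    cd <- NA_real_
    for (side in c("left", "right")) {
      on_side <- s == side
      sd <- d[on_side]; sty <- ty[on_side]; sv <- v[on_side]
      at_exam <- sty == "screen_assess" & sd == exam_num[i]
      if (any(at_exam)) {
        code <- as.integer(sv[at_exam][1L])
      } else if (!is.null(fallback) && !is.na(fallback[i])) {
        if (!warned) {
          warning("per-side screening assessments missing for some exams; ",
                  "applying the examination-level assessment to both sides")
          warned <- TRUE
        }
        code <- as.integer(fallback[i])
      } else {
        stop("no screening assessment for exam ", exams$exam_id[i],
             " (", side, " breast) and no exam-level fallback")
      }
      res <- .label_breast(code, sd, sty, sv, exam_num[i], horizon[i],
                           fup[i], pat_screen, has_bx)
      if (side == "left") left_label[i] <- res$label else
        right_label[i] <- res$label
      if (!is.na(res$cancer_date)) {
        cd <- if (is.na(cd)) res$cancer_date else min(cd, res$cancer_date)
      }
    }
    cancer_date[i] <- cd
  }

  exams$left_label <- left_label
  exams$right_label <- right_label
  exams$exam_label <- propagate_exam_label(left_label, right_label)
  exams$cancer_date <- as.Date(cancer_date, origin = "1970-01-01")
  exams
}

#' Classify labeled examinations against an outcome window
#'
#' The cancer-positive class contains M and I examinations whose cancer
#' date falls within the window (half-open: strictly after the exam date,
#' up to and including `window_months` calendar months later). The
#' negative class contains N, S, D, P, H. Unknown outcomes (U) are
#' excluded, as are M/I examinations whose cancer falls outside the
#' window (a known cancer is never treated as a negative).
#'
#' @param labeled Output of [label_cohort()] (needs `exam_label`,
#'   `exam_date`, `cancer_date`).
#' @param window_months Outcome window in months (6, 12, 24 or 36).
#' @return `labeled` with an added `class` column
#'   (`positive`/`negative`/`excluded`); the window is recorded in
#'   attribute `window_months`.
#' @export
classify_exams <- function(labeled, window_months) {
  labeled <- as.data.frame(labeled)
  req <- c("exam_label", "exam_date", "cancer_date")
  if (!all(req %in% names(labeled))) {
    stop("labeled exams must have columns: ", paste(req, collapse = ", "))
  }
  stopifnot(length(window_months) == 1L, window_months > 0)
  lab <- as.character(labeled$exam_label)
  pos_lab <- lab %in% c("M", "I")
  if (any(pos_lab & is.na(labeled$cancer_date))) {
    stop("M/I examination(s) with missing cancer_date: ",
         paste(utils::head(labeled$exam_id[pos_lab & is.na(labeled$cancer_date)], 5L),
               collapse = ", "))
  }
  exam_date <- as.Date(labeled$exam_date)
  win_end <- add_months(exam_date, window_months)
  in_win <- !is.na(labeled$cancer_date) &
    labeled$cancer_date > exam_date & labeled$cancer_date <= win_end
  cls <- rep("excluded", nrow(labeled))
  cls[pos_lab & in_win] <- "positive"
  cls[lab %in% c("N", "S", "D", "P", "H")] <- "negative"
  labeled$class <- cls
  attr(labeled, "window_months") <- window_months
  labeled
}
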
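#' Outcome label levels, from least to most severe
#'
#' Breast-level screening outcomes form a total order used when propagating
#' labels from breasts to examinations:
#' N (negative) < S (screening benign) < D (diagnostic benign) <
#' U (unknown) < P (pathology benign) < H (high risk, nonupstaged) <
#' I (interval cancer) < M (malignant, screen detected).
#'
#' @return Character vector of the eight labels in rank order (rank 0-7).
#' @export
#' @examples
#' outcome_levels()
outcome_levels <- function() {
  c("N", "S", "D", "U", "P", "H", "I", "M")
}

#' Coerce to an ordered outcome-label factor
#'
#' @param x Character vector of labels among [outcome_levels()].
#' @return Ordered factor with levels `N < S < D < U < P < H < I < M`.
#' @export
outcome_label <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% outcome_levels())
  if (any(bad)) {
    stop("unknown outcome label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = outcome_levels(), ordered = TRUE)
}

#' Integer severity rank of an outcome label
#'
#' @param label Character or factor vector of outcome labels.
#' @return Integer vector, `N` = 0 up to `M` = 7.
#' @export
outcome_rank <- function(label) {
  r <- match(as.character(label), outcome_levels()) - 1L
  if (anyNA(r) && !anyNA(label)) {
    stop("unknown outcome label(s): ",
         paste(setdiff(unique(as.character(label)), outcome_levels()),
               collapse = ", "))
  }
  r
}

#' Propagate breast-level labels to an examination label
#'
#' The examination label is the more severe (higher-ranked) of the two
#' breast labels. Vectorised over pairs.
#'
#' @param left,right Outcome labels (character or factor).
#' @return Character vector of examination labels.
#' @export
#' @examples
#' propagate_exam_label("N", "M")  # "M"
#' propagate_exam_label("D", "U")  # "U"
propagate_exam_label <- function(left, right) {
  rl <- outcome_rank(left)
  rr <- outcome_rank(right)
  outcome_levels()[pmax(rl, rr) + 1L]
}

#' Map a UK reader opinion to a BI-RADS assessment code
#'
#' UK screening programmes do not use the BI-RADS lexicon; reader opinions
#' are mapped so that the same labeling rules apply to both regions.
#' Screening opinions of normal or benign map to BI-RADS 1 and 2; any other
#' screening opinion is a recall (BI-RADS 0). Nonscreening (diagnostic)
#' opinions map benign to 3, suspicious or uncertain to 4, and malignant
#' to 5; a nonscreening normal opinion maps to 1 (negative diagnostic
#' assessment).
#'
#' @param opinion Character vector among `normal`, `benign`, `suspicious`,
#'   `uncertain`, `malignant`.
#' @param context `"screening"` or `"nonscreening"` (recycled).
#' @return Integer BI-RADS codes.
#' @export
#' @examples
#' map_uk_opinion("normal", "screening")        # 1
#' map_uk_opinion("uncertain", "nonscreening")  # 4
map_uk_opinion <- function(opinion, context = "screening") {
  opinion <- as.character(opinion)
  context <- rep_len(as.character(context), length(opinion))
  ok_op <- c("normal", "benign", "suspicious", "uncertain", "malignant")
  bad <- !(opinion %in% ok_op)
  if (any(bad)) {
    stop("unknown reader opinion(s): ", paste(unique(opinion[bad]), collapse = ", "))
  }
  if (!all(context %in% c("screening", "nonscreening"))) {
    stop("context must be 'screening' or 'nonscreening'")
  }
  out <- integer(length(opinion))
  scr <- context == "screening"
  out[scr] <- c(normal = 1L, benign = 2L, suspicious = 0L,
                uncertain = 0L, malignant = 0L)[opinion[scr]]
  out[!scr] <- c(normal = 1L, benign = 3L, suspicious = 4L,
                 uncertain = 4L, malignant = 5L)[opinion[!scr]]
  out
}

#' Add calendar months to a date
#'
#' Calendar-month offset keeping the day of month, clamped to the last day
#' of the target month (so 2015-01-31 plus one month is 2015-02-28). Used
#' for all screening-interval and follow-up window arithmetic so that the
#' date logic is independent of leap years and month lengths.
#'
#' @param date `Date` vector.
#' @param n Integer number of months (scalar or same length as `date`).
#' @return `Date` vector.
#' @export
#' @examples
#' add_months(as.Date("2015-01-31"), 1)  # 2015-02-28
add_months <- function(date, n) {
  date <- as.Date(date)
  lt <- as.POSIXlt(date)
  day <- lt$mday
  m0 <- lt$year * 12L + lt$mon + as.integer(n)
  y <- m0 %/% 12L
  m <- m0 %% 12L
  last <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[m + 1L]
  yr <- y + 1900L
  leap <- yr %% 4L == 0L & (yr %% 100L != 0L | yr %% 400L == 0L)
  last[m == 1L & leap] <- 29L
  lt$year <- y
  lt$mon <- m
  lt$mday <- pmin(day, last)
  as.Date(lt)
}
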
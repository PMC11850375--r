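# Time-related mentions and onset arithmetic.  Four time classes are
# distinguished: DATE (DT: "yesterday", "November 3rd, 2023", "2 years
# ago"), DURATION (DU: "3 months", "2 weeks"), TIME (T: "7 pm"), SET
# (S: "daily", "weekly").  Past-pointing date/duration expressions are
# normalized to an absolute day offset from the post's publication date
# under deliberately coarse calendar conventions: year = 365 d, month =
# 30 d, week = 7 d, day = 1 d; named months resolve in true calendar days.

pl_time_classes <- c("DT", "DU", "T", "S")

pl_month_names <- c(
  january = 1L, february = 2L, march = 3L, april = 4L, may = 5L,
  june = 6L, july = 7L, august = 8L, september = 9L, october = 10L,
  november = 11L, december = 12L
)

number_core <- paste0(
  "\\d+|", paste(names(word_numbers), collapse = "|"), "|couple of")
unit_core <- "years?|months?|weeks?|days?|hours?|minutes?"
number_alt <- sprintf("(?:%s)", number_core)
unit_alt <- sprintf("(?:%s)", unit_core)
month_alt <- paste(names(pl_month_names), collapse = "|")

# ordered pattern table; overlap resolved leftmost-longest, earlier rows
# win ties at equal span
time_pattern_table <- function() {
  tibble::tibble(
    time_class = c(
      "DT", "DT", "DT", "DT", "DT", "DT", "DT", "DT",
      "DU", "DU", "DU",
      "T", "T", "T",
      "S", "S"
    ),
    pattern = c(
      sprintf("\\b%s +%s +(?:ago|back|earlier)\\b", number_alt, unit_alt),
      "\\blast +(?:year|month|week|night)\\b",
      "\\b(?:earlier +this|this) +(?:year|month|week)\\b",
      "\\b(?:right +now|now|currently|yesterday|today|tomorrow)\\b",
      sprintf(
        "\\b(?:%s)(?: +\\d{1,2}(?:st|nd|rd|th)?)?(?:,? +\\d{4})?\\b",
        month_alt),
      "\\bnext +(?:year|month|week)\\b",
      "\\ba while (?:ago|back)\\b",
      "\\b(?:19|20)\\d{2}\\b",
      sprintf("\\b%s +%s\\b", number_alt, unit_alt),
      "\\b(?:several|many|a few|few) +(?:years|months|weeks|days)\\b",
      "\\b(?:years|months|weeks|days|decades)\\b",
      "\\b\\d{1,2}:\\d{2}\\b",
      "\\b\\d{1,2} ?(?:am|pm)\\b",
      "\\b\\d{1,2} ?o'? ?clock\\b",
      "\\b(?:daily|weekly|monthly|yearly|hourly|annually)\\b",
      "\\bevery +(?:day|week|month|year|morning|evening|night)\\b"
    )
  )
}

#' Reference time-mention extractor
#'
#' Regex/pattern-based span tagger for the four time classes, so the test
#' suite needs no model.  A fine-tuned sequence tagger with the same
#' contract (`text -> tibble(time_class, start, end)`) can be plugged into
#' [extract_time_mentions()].
#'
#' @return An extractor function.
#' @export
reference_time_extractor <- function() {
  tab <- time_pattern_table()
  function(text) {
    cands <- list()
    for (r in seq_len(nrow(tab))) {
      loc <- stringr::str_locate_all(
        text, stringr::regex(tab$pattern[[r]], ignore_case = TRUE))[[1]]
      if (nrow(loc)) {
        cands[[length(cands) + 1L]] <- tibble::tibble(
          time_class = tab$time_class[[r]],
          start = loc[, 1] - 1L, end = loc[, 2], rank = r)
      }
    }
    out <- dplyr::bind_rows(cands)
    if (is.null(out) || nrow(out) == 0) {
      return(tibble::tibble(time_class = character(), start = integer(),
                            end = integer()))
    }
    out <- out[order(out$start, -(out$end - out$start), out$rank), ]
    keep <- rep(TRUE, nrow(out))
    last_end <- -1L
    for (i in seq_len(nrow(out))) {
      if (out$start[[i]] < last_end) keep[[i]] <- FALSE
      else last_end <- out$end[[i]]
    }
    out[keep, c("time_class", "start", "end"), drop = FALSE]
  }
}

#' Extract time-related mentions from one sentence
#'
#' Applies the extractor and then the package's deictic-present convention:
#' *now* / *currently* / *right now* are always tagged DATE whatever the
#' backend says, because the present moment pins a disease onset to the
#' posting date.
#'
#' @param sentence One-row sentences tibble (or list with `text`).
#' @param extractor Span tagger; defaults to [reference_time_extractor()].
#' @return A `TimeMention` tibble: `time_class` (`DT`, `DU`, `T`, `S`),
#'   `surface`, `start`, `end` (0-based half-open into the sentence).
#' @export
#' @examples
#' extract_time_mentions(list(text = "Two weeks ago I got the result"))
extract_time_mentions <- function(sentence,
                                  extractor = reference_time_extractor()) {
  text <- sentence$text[[1]]
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(time_class = character(), surface = character(),
                          start = integer(), end = integer()))
  }
  spans <- extractor(text)
  if (nrow(spans) == 0) {
    return(tibble::tibble(time_class = character(), surface = character(),
                          start = integer(), end = integer()))
  }
  spans$surface <- substr0(text, spans$start, spans$end)
  deictic <- normalize_term(spans$surface) %in%
    c("now", "right now", "currently")
  spans$time_class[deictic] <- "DT"
  tibble::tibble(time_class = spans$time_class, surface = spans$surface,
                 start = as.integer(spans$start),
                 end = as.integer(spans$end))
}

unit_days <- c(year = 365, month = 30, week = 7, day = 1, hour = 0,
               minute = 0)

unit_to_days <- function(unit) {
  unit <- stringr::str_remove(stringr::str_to_lower(unit), "s$")
  unname(unit_days[unit])
}

#' Normalize a time mention to a day offset from a reference date
#'
#' Maps past-pointing DATE and DURATION expressions to the integer number
#' of days before `reference_date` (the post's publication date).
#' Conventions: counted units use the coarse calendar (year = 365,
#' month = 30, week = 7, day = 1); `last <unit>` is exactly one unit;
#' deictic present (*now*, *currently*, *today*) and `[earlier] this
#' <unit>` with no finer anchor are 0; a named month resolves to day 1 of
#' that month in the reference year (previous year when that date falls
#' after the reference) and is counted in true calendar days, as is a bare
#' or explicit year.  A bare duration ("3 months") is read as
#' illness-duration, i.e. onset that many days back.  Expressions too
#' vague to resolve ("a while back", "several years") and future-pointing
#' ones (onsets precede posts) come back unresolvable; offsets are never
#' negative.
#'
#' @param mention One-row `TimeMention` tibble (or list with `time_class`
#'   and `surface`); `time_class` must be `DT` or `DU`.
#' @param reference_date A `Date` (or string coercible to one).
#' @return A list with `days` (non-negative integer, `NA` when
#'   unresolvable) and `resolvable` (logical).
#' @export
#' @examples
#' normalize_to_day_offset(
#'   list(time_class = "DT", surface = "2 years ago"), as.Date("2023-06-01"))
normalize_to_day_offset <- function(mention, reference_date) {
  time_class <- mention$time_class[[1]]
  surface <- mention$surface[[1]]
  if (!time_class %in% c("DT", "DU")) {
    abort_pl(sprintf(
      "normalize_to_day_offset expects a DATE or DURATION mention, got %s",
      time_class), class = "patientlens_contract_error")
  }
  reference_date <- as.Date(reference_date)
  s <- normalize_term(surface)
  unresolved <- list(days = NA_integer_, resolvable = FALSE)
  resolved <- function(d) {
    d <- as.integer(round(d))
    if (is.na(d) || d < 0) unresolved else list(days = d, resolvable = TRUE)
  }

  if (s %in% c("now", "right now", "currently", "today")) return(resolved(0))
  if (s %in% c("yesterday", "last night")) return(resolved(1))
  if (s %in% c("tomorrow") || stringr::str_detect(s, "^next ")) {
    return(unresolved)
  }
  if (stringr::str_detect(s, "^a while (ago|back)$")) return(unresolved)
  if (stringr::str_detect(s, "^(earlier this|this) (year|month|week)$")) {
    return(resolved(0))
  }
  m <- stringr::str_match(s, "^last (year|month|week)$")
  if (!is.na(m[1, 1])) return(resolved(unit_to_days(m[1, 2])))
  m <- stringr::str_match(
    s, sprintf("^(%s) (%s) (?:ago|back|earlier)$", number_core, unit_core))
  if (!is.na(m[1, 1])) {
    n <- parse_count(m[1, 2])
    if (is.na(n)) return(unresolved)
    return(resolved(n * unit_to_days(m[1, 3])))
  }

  if (time_class == "DU") {
    m <- stringr::str_match(s, sprintf("^(%s) (%s)$", number_core, unit_core))
    if (!is.na(m[1, 1])) {
      n <- parse_count(m[1, 2])
      if (is.na(n)) return(unresolved)
      return(resolved(n * unit_to_days(m[1, 3])))
    }
    return(unresolved)  # bare/vague durations carry no count
  }

  # named month, optional day-of-month and year
  m <- stringr::str_match(
    s, sprintf("^(%s)(?: (\\d{1,2})(?:st|nd|rd|th)?)?(?:,? (\\d{4}))?$",
               month_alt))
  if (!is.na(m[1, 1])) {
    month <- pl_month_names[[m[1, 2]]]
    day <- if (!is.na(m[1, 3])) as.integer(m[1, 3]) else 1L
    year <- if (!is.na(m[1, 4])) as.integer(m[1, 4]) else NA_integer_
    if (is.na(year)) {
      year <- as.integer(format(reference_date, "%Y"))
      anchor <- as.Date(sprintf("%04d-%02d-%02d", year, month, day))
      if (is.na(anchor)) return(unresolved)
      if (anchor > reference_date) {
        anchor <- as.Date(sprintf("%04d-%02d-%02d", year - 1L, month, day))
      }
    } else {
      anchor <- as.Date(sprintf("%04d-%02d-%02d", year, month, day))
    }
    if (is.na(anchor) || anchor > reference_date) return(unresolved)
    return(resolved(as.numeric(reference_date - anchor)))
  }

  # bare year
  m <- stringr::str_match(s, "^((?:19|20)\\d{2})$")
  if (!is.na(m[1, 1])) {
    anchor <- as.Date(sprintf("%s-01-01", m[1, 1]))
    if (anchor > reference_date) return(unresolved)
    return(resolved(as.numeric(reference_date - anchor)))
  }
  unresolved
}

#' Normalize all date/duration mentions of a mention table
#'
#' Vectorized convenience over [normalize_to_day_offset()]; TIME and SET
#' mentions pass through with `resolvable = FALSE`.
#'
#' @param mentions A `TimeMention` tibble.
#' @param reference_date Reference `Date`.
#' @return `mentions` with `days` and `resolvable` columns added.
#' @export
normalize_time_mentions <- function(mentions, reference_date) {
  if (nrow(mentions) == 0) {
    mentions$days <- integer()
    mentions$resolvable <- logical()
    return(mentions)
  }
  res <- lapply(seq_len(nrow(mentions)), function(i) {
    if (!mentions$time_class[[i]] %in% c("DT", "DU")) {
      return(list(days = NA_integer_, resolvable = FALSE))
    }
    normalize_to_day_offset(mentions[i, , drop = FALSE], reference_date)
  })
  mentions$days <- vapply(res, function(x) x$days, integer(1))
  mentions$resolvable <- vapply(res, function(x) x$resolvable, logical(1))
  mentions
}

#' Day offset of the onset expression in one sentence
#'
#' Runs [extract_time_mentions()] then [normalize_to_day_offset()] and
#' returns the day offset of the first resolvable date/duration expression
#' -- the arithmetic behind onset analyses: "Two weeks ago I received a
#' diagnosis of IPF." posted on day D puts the onset at D - 14.
#'
#' @param text Sentence text.
#' @param reference_date Publication date of the enclosing post.
#' @param extractor Optional span tagger override.
#' @return Integer day offset, or `NA` when no resolvable expression is
#'   present.
#' @export
sentence_onset_days <- function(text, reference_date,
                                extractor = reference_time_extractor()) {
  mentions <- extract_time_mentions(list(text = text), extractor)
  mentions <- normalize_time_mentions(mentions, reference_date)
  hit <- which(mentions$resolvable)
  if (length(hit) == 0) return(NA_integer_)
  mentions$days[[hit[[1]]]]
}
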
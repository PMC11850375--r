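test_that("time classes follow the date/duration/time/set scheme", {
  classes <- function(text) {
    m <- extract_time_mentions(list(text = text))
    setNames(m$time_class, m$surface)
  }
  expect_equal(unname(classes("it lasted 3 months")), "DU")
  expect_equal(unname(classes("we met 2 weeks after")), "DU")
  expect_equal(unname(classes("I take it daily")), "S")
  expect_equal(unname(classes("call me at 7 pm")), "T")
  expect_equal(unname(classes("she left yesterday")), "DT")
  expect_equal(unname(classes("diagnosed on November 3rd, 2023")), "DT")
  # the deictic-present convention: now/currently are always DATE
  expect_equal(unname(classes("I am currently on oxygen")), "DT")
  expect_equal(unname(classes("now it is different")), "DT")
  expect_equal(nrow(extract_time_mentions(list(text = ""))), 0)
})

test_that("day-offset normalization reproduces the coarse-calendar conventions", {
  ref <- as.Date("2023-11-15")
  days_of <- function(surface, class = "DT") {
    normalize_to_day_offset(list(time_class = class, surface = surface),
                            ref)
  }
  expect_equal(days_of("2 years ago")$days, 730L)
  expect_equal(days_of("last year")$days, 365L)
  expect_equal(days_of("Two weeks ago")$days, 14L)
  expect_equal(days_of("currently")$days, 0L)
  expect_equal(days_of("earlier this year")$days, 0L)
  expect_equal(days_of("yesterday")$days, 1L)
  expect_equal(days_of("3 months ago")$days, 90L)
  expect_equal(days_of("3 months", "DU")$days, 90L)
  # month names resolve to day 1 in true calendar days
  expect_equal(days_of("January")$days,
               as.integer(ref - as.Date("2023-01-01")))
  # a month after the reference date falls into the previous year
  expect_equal(days_of("December")$days,
               as.integer(ref - as.Date("2022-12-01")))
  expect_equal(days_of("March 10th, 2022")$days,
               as.integer(ref - as.Date("2022-03-10")))
  expect_equal(days_of("2021")$days,
               as.integer(ref - as.Date("2021-01-01")))
})

test_that("vague or future expressions are unresolvable, offsets never negative", {
  ref <- as.Date("2023-11-15")
  unresolvable <- function(surface, class = "DT") {
    out <- normalize_to_day_offset(
      list(time_class = class, surface = surface), ref)
    expect_false(out$resolvable)
    expect_true(is.na(out$days))
  }
  unresolvable("a while back")
  unresolvable("tomorrow")
  unresolvable("next year")
  unresolvable("December 2024")
  unresolvable("several years", "DU")
  unresolvable("days", "DU")

  expect_error(normalize_to_day_offset(
    list(time_class = "S", surface = "daily"), ref),
    class = "patientlens_contract_error")

  # purity + non-negativity over the full supported inventory
  inventory <- c("2 years ago", "two weeks ago", "last year", "last month",
                 "last week", "3 months ago", "yesterday", "currently",
                 "now", "today", "earlier this year", "January", "June",
                 "2022", "six weeks ago")
  for (s in inventory) {
    a <- normalize_to_day_offset(list(time_class = "DT", surface = s), ref)
    b <- normalize_to_day_offset(list(time_class = "DT", surface = s), ref)
    expect_identical(a, b)
    if (a$resolvable) expect_gte(a$days, 0)
  }
})

test_that("the reference extractor agrees with a direct pattern oracle on planted expressions", {
  inventory <- tibble::tibble(
    surface = c("2 years ago", "two weeks ago", "last year",
                "3 months ago", "yesterday", "currently", "daily",
                "7 pm", "3 months"),
    class = c("DT", "DT", "DT", "DT", "DT", "DT", "S", "T", "DU"))
  carriers <- c("It began %s for me.", "She said %s it all changed.",
                "Symptoms worsened %s and stayed.")
  withr::with_seed(3, {
    for (i in seq_len(nrow(inventory))) {
      text <- sprintf(sample(carriers, 1), inventory$surface[[i]])
      m <- extract_time_mentions(list(text = text))
      expect_equal(nrow(m), 1, info = text)
      expect_equal(m$surface, inventory$surface[[i]])
      expect_equal(m$time_class, inventory$class[[i]])
      # offsets index into the sentence
      expect_identical(substring(text, m$start + 1, m$end), m$surface)
    }
  })
})

test_that("sentence_onset_days composes extraction and normalization", {
  ref <- as.Date("2023-11-15")
  expect_equal(sentence_onset_days(
    "Two weeks ago I received my result.", ref), 14L)
  expect_equal(sentence_onset_days("Nothing temporal here.", ref),
               NA_integer_)
  expect_equal(sentence_onset_days(
    "It started a while back, I think.", ref), NA_integer_)
})
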
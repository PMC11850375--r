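test_that("read_posts parses well-formed JSONL in file order", {
  path <- write_posts_file(c(post_line("a", "first post"),
                             post_line("b", "second post")))
  posts <- read_posts(path)
  expect_equal(nrow(posts), 2)
  expect_equal(posts$post_id, c("a", "b"))
  expect_s3_class(posts$published_at, "Date")
  expect_equal(nrow(read_posts(write_posts_file(character(0)))), 0)
})

test_that("malformed lines are skipped with a logged error or abort", {
  path <- write_posts_file(c(
    post_line("a", "ok"),
    jsonlite::toJSON(list(post_id = "b", text = "no date"),
                     auto_unbox = TRUE),
    post_line("c", "ok too")))
  expect_warning(posts <- read_posts(path, on_error = "skip"),
                 class = "patientlens_read_warning")
  expect_equal(posts$post_id, c("a", "c"))
  errs <- attr(posts, "errors")
  expect_equal(nrow(errs), 1)
  expect_equal(errs$line, 2)
  expect_error(read_posts(path, on_error = "abort"),
               class = "patientlens_parse_error")
})

test_that("write_posts/read_posts round-trips records", {
  path <- write_posts_file(c(
    post_line("a", "My mother was unwell. She recovered."),
    post_line("b", "", published_at = "2022-05-01")))
  posts <- read_posts(path)
  out <- withr::local_tempfile(fileext = ".jsonl")
  write_posts(posts, out)
  again <- read_posts(out)
  cols <- c("post_id", "source", "url", "published_at", "text", "lang")
  expect_equal(as.data.frame(posts[, cols]), as.data.frame(again[, cols]))
})

test_that("deduplication keeps one post per normalized text", {
  posts <- tibble::tibble(
    post_id = c("p2", "p1"),
    source = "forum", url = c("u1", "u2"),
    published_at = as.Date(c("2023-01-02", "2023-01-02")),
    text = c("Same content here", "Same content here"), lang = "en")
  out <- deduplicate_posts(posts)
  expect_equal(nrow(out), 1)
  expect_equal(out$post_id, "p1")  # date tie broken by post_id

  distinct <- tibble::tibble(
    post_id = c("a", "b"), source = "s", url = "u",
    published_at = as.Date("2023-01-01"),
    text = c("one thing", "another thing"), lang = "en")
  expect_equal(deduplicate_posts(distinct), distinct)
})

test_that("dedup of case/whitespace variants keeps the earliest, matching a pairwise oracle", {
  texts <- c("My IPF story", "my ipf  story", "MY IPF STORY",
             "my\tipf story", " My IPF story ")
  posts <- tibble::tibble(
    post_id = paste0("p", 1:5), source = "s", url = "u",
    published_at = as.Date("2023-03-01") + c(4, 2, 0, 3, 1),
    text = texts, lang = "en")
  out <- deduplicate_posts(posts)
  expect_equal(nrow(out), 1)
  expect_equal(out$published_at, min(posts$published_at))

  # brute-force pairwise duplicate oracle
  norm <- tolower(gsub("\\s+", " ", trimws(posts$text)))
  dup_pairs <- outer(norm, norm, "==")
  expect_true(all(dup_pairs))  # fixture is one equivalence class

  # idempotence on random corpora
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- sample(3:10, 1)
      rnd <- tibble::tibble(
        post_id = paste0("q", seq_len(n)), source = "s", url = "u",
        published_at = as.Date("2023-01-01") + sample(0:30, n, TRUE),
        text = sample(c("alpha beta", "Alpha  Beta", "gamma", "delta"),
                      n, TRUE),
        lang = "en")
      once <- deduplicate_posts(rnd)
      expect_identical(deduplicate_posts(once), once)
    }
  })
})

test_that("pseudonymization replaces emails with the fixed placeholder", {
  out <- pseudonymize("write to a@b.com", seed = 1)
  expect_equal(out$text, "write to [EMAIL]")
  expect_equal(out$report$replacements$kind, "email")
  expect_equal(out$report$replacements$original, "a@b.com")
})

test_that("pseudonymization is a seeded identity-preserving transform", {
  plain <- "no identifiers in this sentence"
  out <- pseudonymize(plain, seed = 3)
  expect_equal(out$text, plain)
  expect_equal(nrow(out$report$replacements), 0)

  text <- "Dr. John Smith told Mary to write to j.smith@clinic.org soon"
  a <- pseudonymize(text, seed = 42)
  b <- pseudonymize(text, seed = 42)
  expect_identical(a$text, b$text)
  expect_identical(a$report$replacements, b$report$replacements)
  expect_false(grepl("John Smith", a$text, fixed = TRUE))
  expect_true(grepl("[EMAIL]", a$text, fixed = TRUE))

  # splicing check: characters outside the reported spans are untouched
  rep_tbl <- a$report$replacements
  rep_tbl <- rep_tbl[order(rep_tbl$start), ]
  keep_orig <- character(0)
  prev <- 0L
  for (i in seq_len(nrow(rep_tbl))) {
    keep_orig <- c(keep_orig, substring(text, prev + 1, rep_tbl$start[[i]]))
    prev <- rep_tbl$end[[i]]
  }
  keep_orig <- c(keep_orig, substring(text, prev + 1, nchar(text)))
  reconstructed <- keep_orig[[1]]
  for (i in seq_len(nrow(rep_tbl))) {
    reconstructed <- paste0(reconstructed, rep_tbl$replacement[[i]],
                            keep_orig[[i + 1]])
  }
  expect_identical(reconstructed, a$text)
})

test_that("segmentation yields offset-exact, ordered, gap-is-whitespace sentences", {
  expect_equal(nrow(segment_post(list(post_id = "e", text = ""))), 0)

  two <- segment_post(list(post_id = "p", text = "A. B."))
  expect_equal(two$text, c("A.", "B."))
  expect_equal(two$start, c(0L, 3L))
  expect_equal(two$end, c(2L, 5L))

  post <- list(post_id = "m", text = paste(
    "My mother was diagnosed last spring.",
    "I have been on oxygen since then!",
    "Dr. Lee says e.g. walking helps.",
    "Is that enough?"))
  sents <- segment_post(post)
  expect_equal(nrow(sents), 4)
  expect_equal(sents$index, 0:3)
  for (i in seq_len(nrow(sents))) {
    expect_identical(substring(post$text, sents$start[[i]] + 1,
                               sents$end[[i]]), sents$text[[i]])
  }
  expect_true(all(diff(sents$start) > 0))
  # inter-span gaps are whitespace only
  for (i in seq_len(nrow(sents) - 1)) {
    gap <- substring(post$text, sents$end[[i]] + 1, sents$start[[i + 1]])
    expect_match(gap, "^\\s*$")
  }
  # abbreviation guard kept "Dr." and "e.g." inside one sentence
  expect_match(sents$text[[3]], "^Dr\\. Lee says e\\.g\\. walking")
})

test_that("a post mixing perspectives splits into one sentence per statement", {
  post <- list(post_id = "mix", text = paste(
    "My husband was diagnosed with IPF last year.",
    "I also developed a cough myself."))
  sents <- segment_post(post)
  expect_equal(nrow(sents), 2)
  expect_equal(sents$index, c(0L, 1L))
})
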
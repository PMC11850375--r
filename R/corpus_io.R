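#' Read social-media posts from a JSONL file
#'
#' One post per line, as a JSON object with fields `post_id`, `source`,
#' `url`, `published_at` (ISO-8601 `YYYY-MM-DD`), `text` and `lang`.
#' `post_id`, `text` and a parseable `published_at` are required;
#' `source`, `url` and `lang` default to `""`, `""` and `"en"`.
#'
#' @param path Path to a JSONL file.
#' @param on_error `"skip"` logs malformed lines (attached as the
#'   `"errors"` attribute, a tibble with `line` and `message`) and keeps
#'   going; `"abort"` raises on the first malformed line.
#' @return A tibble of posts in file order, one row per well-formed line,
#'   with columns `post_id`, `source`, `url`, `published_at` (`Date`),
#'   `text`, `lang` and the originating `line` number.
#' @seealso [write_posts()], [deduplicate_posts()], [segment_posts()]
#' @export
read_posts <- function(path, on_error = c("skip", "abort")) {
  on_error <- match.arg(on_error)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- vector("list", length(lines))
  errors <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[[i]]))) next
    parsed <- tryCatch(parse_post_line(lines[[i]], i), error = identity)
    if (inherits(parsed, "error")) {
      if (on_error == "abort") {
        abort_pl(sprintf("line %d: %s", i, conditionMessage(parsed)),
                 class = "patientlens_parse_error")
      }
      errors[[length(errors) + 1L]] <-
        tibble::tibble(line = i, message = conditionMessage(parsed))
      next
    }
    rows[[i]] <- parsed
  }
  posts <- dplyr::bind_rows(rows)
  if (nrow(posts) == 0) posts <- empty_posts()
  errors <- if (length(errors)) dplyr::bind_rows(errors) else
    tibble::tibble(line = integer(), message = character())
  if (nrow(errors) > 0) {
    warn(sprintf("skipped %d malformed line(s) in %s", nrow(errors), path),
         class = "patientlens_read_warning")
  }
  if (anyDuplicated(posts$post_id)) {
    abort_pl("duplicate post_id in corpus", class = "patientlens_parse_error")
  }
  attr(posts, "errors") <- errors
  posts
}

parse_post_line <- function(line, lineno) {
  obj <- jsonlite::fromJSON(line, simplifyVector = TRUE)
  for (field in c("post_id", "text", "published_at")) {
    if (is.null(obj[[field]])) stop("missing required field '", field, "'")
  }
  date <- suppressWarnings(as.Date(as.character(obj$published_at)))
  if (is.na(date)) stop("published_at not an ISO-8601 date")
  tibble::tibble(
    post_id = as.character(obj$post_id),
    source = as.character(obj$source %||% ""),
    url = as.character(obj$url %||% ""),
    published_at = date,
    text = as.character(obj$text),
    lang = as.character(obj$lang %||% "en"),
    line = lineno
  )
}

empty_posts <- function() {
  tibble::tibble(
    post_id = character(), source = character(), url = character(),
    published_at = as.Date(character()), text = character(),
    lang = character(), line = integer()
  )
}

#' Write posts to a JSONL file
#'
#' Inverse of [read_posts()]: record-equivalent round trip for well-formed
#' input.
#'
#' @param posts A posts tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(posts))) {
    obj <- list(
      post_id = posts$post_id[[i]], source = posts$source[[i]],
      url = posts$url[[i]],
      published_at = format(posts$published_at[[i]], "%Y-%m-%d"),
      text = posts$text[[i]], lang = posts$lang[[i]]
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Drop duplicated posts
#'
#' Users repost identical content under different URLs; duplicated text
#' would bias every downstream count.  Posts are keyed by their normalized
#' full text (casefolded, whitespace collapsed); within a key the earliest
#' `published_at` survives, ties broken by lexicographic `post_id`.
#' Survivors keep their relative input order.  The operation is idempotent.
#'
#' @param posts A posts tibble.
#' @return The deduplicated posts tibble.
#' @export
deduplicate_posts <- function(posts) {
  if (nrow(posts) <= 1) return(posts)
  key <- normalize_term(posts$text)
  ord <- order(key, as.numeric(posts$published_at), posts$post_id,
               method = "radix")
  winners <- ord[!duplicated(key[ord])]
  posts[sort(winners), , drop = FALSE]
}

#' Replace direct identifiers in free text
#'
#' Pseudonymizes a post body: detected person names are replaced by
#' randomly generated equivalents (random substitution, deterministic under
#' `seed`), and email-shaped tokens by the literal placeholder `[EMAIL]`
#' (tagging).  All characters outside the replaced spans are preserved.
#'
#' @param text A single string.
#' @param seed Integer seed; the same `(text, seed)` pair always yields
#'   byte-identical output.
#' @param name_detector A function `text -> tibble(start, end)` of 0-based
#'   half-open person-name spans. Defaults to [reference_name_detector()];
#'   a model-backed detector with the same contract can be plugged in.
#' @return A list with `text` (the pseudonymized string) and `report`, a
#'   list carrying the `seed` and a `replacements` tibble
#'   (`kind`, `start`, `end`, `original`, `replacement`; spans refer to the
#'   original text and never overlap).
#' @export
#' @examples
#' pseudonymize("write to a@b.com", seed = 1)$text
pseudonymize <- function(text, seed, name_detector = reference_name_detector()) {
  stopifnot(is.character(text), length(text) == 1)
  seed <- as.integer(seed)
  emails <- locate_emails(text)
  names_ <- name_detector(text)
  spans <- dplyr::bind_rows(
    if (nrow(emails)) tibble::tibble(kind = "email", start = emails$start,
                                     end = emails$end),
    if (nrow(names_)) tibble::tibble(kind = "person_name",
                                     start = names_$start, end = names_$end)
  )
  if (is.null(spans) || nrow(spans) == 0) {
    return(list(text = text, report = list(
      seed = seed,
      replacements = tibble::tibble(
        kind = character(), start = integer(), end = integer(),
        original = character(), replacement = character()))))
  }
  # emails win over overlapping name detections; then drop any overlaps
  spans <- spans[order(match(spans$kind, c("email", "person_name")),
                       spans$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(spans))
  for (i in seq_len(nrow(spans))) {
    if (!keep[[i]]) next
    for (j in seq_len(nrow(spans))) {
      if (i == j || !keep[[j]]) next
      if (spans$start[[j]] < spans$end[[i]] &&
          spans$start[[i]] < spans$end[[j]]) {
        keep[[j]] <- FALSE
      }
    }
  }
  spans <- spans[keep, , drop = FALSE]
  spans <- spans[order(spans$start), , drop = FALSE]
  spans$original <- substr0(text, spans$start, spans$end)
  spans$replacement <- ifelse(
    spans$kind == "email", "[EMAIL]",
    vapply(spans$original, generate_pseudonym, character(1), seed = seed)
  )
  out <- text
  for (i in rev(seq_len(nrow(spans)))) {
    stringr::str_sub(out, spans$start[[i]] + 1L, spans$end[[i]]) <-
      spans$replacement[[i]]
  }
  list(text = out,
       report = list(seed = seed,
                     replacements = tibble::tibble(spans[, c(
                       "kind", "start", "end", "original", "replacement")])))
}

locate_emails <- function(text) {
  loc <- stringr::str_locate_all(
    text, "[A-Za-z0-9._%+-]+@[A-Za-z0-9.-]+\\.[A-Za-z]{2,}")[[1]]
  tibble::tibble(start = loc[, 1] - 1L, end = loc[, 2])
}

# packaged replacement-name inventory for random substitution
pl_first_names <- c(
  "Alex", "Bella", "Carmen", "Daniel", "Elena", "Felix", "Grace", "Hugo",
  "Irene", "Jonas", "Karin", "Leo", "Mara", "Nils", "Olivia", "Pavel",
  "Quentin", "Rosa", "Stefan", "Tara", "Ulrich", "Vera", "Wim", "Xenia",
  "Yusuf", "Zoe"
)
pl_last_names <- c(
  "Adler", "Berger", "Conti", "Dvorak", "Egger", "Fischer", "Gruber",
  "Haas", "Illes", "Jensen", "Koch", "Lang", "Moser", "Novak", "Olsen",
  "Petrov", "Quast", "Reiter", "Steiner", "Toth", "Unger", "Vogel",
  "Weber", "Ziegler"
)

# deterministic pseudonym: same original + seed -> same replacement
generate_pseudonym <- function(original, seed) {
  h <- string_hash(normalize_term(original), seed = seed)
  first <- pl_first_names[[(h %% length(pl_first_names)) + 1L]]
  last <- pl_last_names[[(floor(h / 257) %% length(pl_last_names)) + 1L]]
  paste(first, last)
}

#' Reference person-name detector
#'
#' A dependency-free token-annotation stand-in for a statistical
#' named-entity recognizer: detects honorific-introduced names
#' (`Dr. Jane Smith`) and capitalized tokens drawn from a packaged
#' given-name list, optionally followed by a capitalized surname.
#'
#' @return A function `text -> tibble(start, end)` (0-based half-open).
#' @export
reference_name_detector <- function() {
  given <- paste(pl_detector_given_names, collapse = "|")
  pat_honorific <-
    "\\b(?:Mr|Mrs|Ms|Dr|Prof)\\.?\\s+([A-Z][a-z]+(?:\\s+[A-Z][a-z]+)?)"
  pat_given <- sprintf("\\b(%s)(?:\\s+[A-Z][a-z]+)?\\b", given)
  function(text) {
    m1 <- stringr::str_match_all(text, pat_honorific)[[1]]
    l1 <- stringr::str_locate_all(text, pat_honorific)[[1]]
    spans <- list()
    if (nrow(l1)) {
      # span of the captured name, not the honorific
      for (i in seq_len(nrow(l1))) {
        whole <- substr(text, l1[i, 1], l1[i, 2])
        off <- stringr::str_locate(whole, stringr::fixed(m1[i, 2]))
        spans[[length(spans) + 1L]] <- tibble::tibble(
          start = l1[i, 1] - 1L + off[1, 1] - 1L,
          end = l1[i, 1] - 1L + off[1, 2])
      }
    }
    l2 <- stringr::str_locate_all(text, pat_given)[[1]]
    if (nrow(l2)) {
      spans[[length(spans) + 1L]] <-
        tibble::tibble(start = l2[, 1] - 1L, end = l2[, 2])
    }
    out <- dplyr::bind_rows(spans)
    if (is.null(out) || nrow(out) == 0) {
      return(tibble::tibble(start = integer(), end = integer()))
    }
    out <- out[order(out$start, -out$end), , drop = FALSE]
    # keep longest span on overlap
    keep <- rep(TRUE, nrow(out))
    last_end <- -1L
    for (i in seq_len(nrow(out))) {
      if (out$start[[i]] < last_end) keep[[i]] <- FALSE
      else last_end <- out$end[[i]]
    }
    out[keep, , drop = FALSE]
  }
}

# names the reference detector recognizes in running text
pl_detector_given_names <- c(
  "James", "Mary", "John", "Patricia", "Robert", "Jennifer", "Michael",
  "Linda", "William", "Elizabeth", "David", "Barbara", "Richard", "Susan",
  "Joseph", "Jessica", "Thomas", "Sarah", "Charles", "Karen", "Anna",
  "Peter", "Laura", "Paul", "Emma", "George"
)

#' Reference rule-based sentence segmenter
#'
#' Splits on runs of terminal punctuation (`.`, `!`, `?`) that are followed
#' by whitespace and an upper-case letter, digit or opening quote (or end
#' of text), guarded by an abbreviation list and a decimal-number check.
#' Model-backed segmenters with the same contract can be plugged into
#' [segment_post()].
#'
#' @param abbreviations Lower-case tokens (final period stripped) that never
#'   end a sentence.
#' @return A function `text -> tibble(start, end)` of sentence spans
#'   (0-based, half-open, whitespace-trimmed).
#' @export
reference_segmenter <- function(abbreviations = pl_abbreviations) {
  function(text) {
    n <- nchar(text)
    if (is.na(text) || n == 0) {
      return(tibble::tibble(start = integer(), end = integer()))
    }
    runs <- stringr::str_locate_all(text, "[.!?]+")[[1]]
    bounds <- integer(0)
    for (r in seq_len(nrow(runs))) {
      s <- runs[r, 1]; e <- runs[r, 2]
      after <- if (e < n) substr(text, e + 1, n) else ""
      at_eos <- !stringr::str_detect(after, "\\S")
      next_ok <- stringr::str_detect(
        after, "^[\"'\\)\\]]*\\s+[\"'\\(\\[]*[A-Z0-9]")
      if (!at_eos && !next_ok) next
      if (substr(text, s, e) == ".") {
        prev_word <- stringr::str_extract(substr(text, 1, s - 1),
                                          "[\\p{L}\\p{N}.]+$")
        if (!is.na(prev_word) &&
            stringr::str_to_lower(prev_word) %in% abbreviations) next
        if (s > 1 && e < n &&
            stringr::str_detect(substr(text, s - 1, s - 1), "\\d") &&
            stringr::str_detect(substr(text, e + 1, e + 1), "\\d")) next
      }
      bounds <- c(bounds, e)
    }
    if (length(bounds) == 0 || max(bounds) < n) bounds <- c(bounds, n)
    spans <- list()
    prev <- 0L
    for (b in bounds) {
      seg <- substr0(text, prev, b)
      first_ns <- stringr::str_locate(seg, "\\S")
      if (!is.na(first_ns[1, 1])) {
        last_ns <- nchar(stringr::str_remove(seg, "\\s+$"))
        spans[[length(spans) + 1L]] <- tibble::tibble(
          start = prev + first_ns[1, 1] - 1L,
          end = prev + last_ns)
      }
      prev <- as.integer(b)
    }
    out <- dplyr::bind_rows(spans)
    if (is.null(out) || nrow(out) == 0) {
      return(tibble::tibble(start = integer(), end = integer()))
    }
    out
  }
}

pl_abbreviations <- c(
  "mr", "mrs", "ms", "dr", "prof", "st", "etc", "e.g", "i.e", "vs", "cf",
  "fig", "no", "al", "approx", "dept", "inc", "jr", "sr"
)

#' Split one post into sentences
#'
#' All downstream analyses in the package run at the sentence level, so a
#' perspective shift inside one post (say, caregiver to patient) can be
#' located precisely.  Sentence offsets always index into the original post
#' text: `substr0(post$text, start, end) == text`, sentences are ordered,
#' non-overlapping, and separated only by whitespace.
#'
#' @param post One-row posts tibble (or a list with `post_id` and `text`).
#' @param segmenter A sentence-boundary function `text -> tibble(start,
#'   end)`; defaults to [reference_segmenter()].
#' @return A tibble with `post_id`, `index` (0-based, contiguous), `text`,
#'   `start`, `end`.
#' @export
segment_post <- function(post, segmenter = reference_segmenter()) {
  spans <- segmenter(post$text[[1]])
  if (nrow(spans) == 0) {
    return(tibble::tibble(post_id = character(), index = integer(),
                          text = character(), start = integer(),
                          end = integer()))
  }
  tibble::tibble(
    post_id = post$post_id[[1]],
    index = seq_len(nrow(spans)) - 1L,
    text = substr0(post$text[[1]], spans$start, spans$end),
    start = as.integer(spans$start),
    end = as.integer(spans$end)
  )
}

#' Segment every post of a corpus
#'
#' @param posts A posts tibble.
#' @inheritParams segment_post
#' @return Row-bound [segment_post()] output for all posts.
#' @export
segment_posts <- function(posts, segmenter = reference_segmenter()) {
  out <- lapply(seq_len(nrow(posts)), function(i) {
    segment_post(posts[i, , drop = FALSE], segmenter)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(post_id = character(), index = integer(),
                          text = character(), start = integer(),
                          end = integer())
  }
  res
}

#' Write sentences to JSONL
#' @param sentences A sentences tibble from [segment_posts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sentences <- function(sentences, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(sentences))) {
    writeLines(jsonlite::toJSON(
      as.list(sentences[i, c("post_id", "index", "start", "end", "text")]),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read sentences from JSONL
#' @param path Path written by [write_sentences()].
#' @return A sentences tibble.
#' @export
read_sentences <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- lapply(lines[nzchar(trimws(lines))], function(l) {
    obj <- jsonlite::fromJSON(l)
    tibble::tibble(post_id = as.character(obj$post_id),
                   index = as.integer(obj$index),
                   text = as.character(obj$text),
                   start = as.integer(obj$start),
                   end = as.integer(obj$end))
  })
  dplyr::bind_rows(rows)
}
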
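# Shared low-level helpers.  All character offsets in the package are
# 0-based, half-open [start, end), counted in characters.

# substring by 0-based half-open offsets (vectorized over spans)
substr0 <- function(x, start, end) substring(x, start + 1L, end)

# term/key normalization: casefold + collapse internal whitespace + trim
normalize_term <- function(x) {
  stringr::str_squish(stringr::str_to_lower(x))
}

clamp01 <- function(x) pmin(1, pmax(0, x))

abort_pl <- function(message, class = "patientlens_error", ...) {
  abort(message, class = c(class, "patientlens_error"), ...)
}

# word-token spans (letters/digits, with internal apostrophes/hyphens),
# returned as a tibble with 0-based half-open offsets
token_spans <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          token = character()))
  }
  loc <- stringr::str_locate_all(
    text, "[\\p{L}\\p{N}_]+(?:['’-][\\p{L}\\p{N}_]+)*")[[1]]
  if (nrow(loc) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          token = character()))
  }
  tibble::tibble(
    start = loc[, 1] - 1L,
    end = loc[, 2],
    token = substr0(text, loc[, 1] - 1L, loc[, 2])
  )
}

# deterministic non-cryptographic string hash (31-polynomial, mod 2^31-1)
string_hash <- function(x, seed = 0L) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(enc2utf8(x))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  h
}

# small-number words understood by the time normalizer and pseudonym fixture
word_numbers <- c(
  a = 1, an = 1, one = 1, two = 2, three = 3, four = 4, five = 5,
  six = 6, seven = 7, eight = 8, nine = 9, ten = 10, eleven = 11,
  twelve = 12, couple = 2
)

parse_count <- function(word) {
  word <- stringr::str_to_lower(word)
  if (stringr::str_detect(word, "^\\d+$")) {
    return(as.integer(word))
  }
  word <- stringr::str_remove(word, " of$")
  if (word %in% names(word_numbers)) {
    return(as.integer(word_numbers[[word]]))
  }
  NA_integer_
}

# minimal English stopword inventory for the reference entailment scorer
pl_stopwords <- c(
  "the", "a", "an", "and", "or", "but", "if", "of", "to", "in", "on", "at",
  "for", "with", "by", "from", "as", "is", "are", "was", "were", "be",
  "been", "being", "am", "it", "its", "this", "that", "these", "those",
  "i", "you", "he", "she", "we", "they", "my", "your", "his", "her", "our",
  "their", "me", "him", "them", "us", "do", "does", "did", "have", "has",
  "had", "not", "no", "so", "too", "very", "can", "could", "will", "would",
  "should", "may", "might", "must", "there", "here", "what", "which",
  "who", "whom", "when", "where", "why", "how"
)

# indefinite placeholders treated as free slots in screening hypotheses
pl_indefinites <- c("someone", "something", "somebody", "anyone",
                    "anything", "anybody")

new_mention_tbl <- function() {
  tibble::tibble(
    concept_type = character(), surface = character(),
    start = integer(), end = integer(),
    canonical_id = character(), source = character()
  )
}
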
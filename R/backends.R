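# Model contracts.  Every learned step in the pipeline is hidden behind one
# of three small interfaces -- entailment scoring, extractive question
# answering, sentence embedding -- so transformer-backed adapters can be
# swapped in without touching pipeline code.  The packaged reference
# implementations are deterministic, dependency-free, and documented well
# enough that expected scores can be computed by hand.

#' Construct an entailment-scoring backend
#'
#' The contract is a single entailment probability in `[0, 1]` for a
#' (premise, hypothesis) pair -- higher means the premise supports the
#' hypothesis.  A binary view of natural language inference is used
#' throughout (entailment vs. everything else).
#'
#' @param score_fn `function(premise, hypothesis) -> numeric(1)`.
#' @param name Backend label recorded in provenance.
#' @return An object of class `pl_entailment_backend`.
#' @export
entailment_backend <- function(score_fn, name = "custom") {
  structure(list(score = score_fn, name = name),
            class = "pl_entailment_backend")
}

#' Construct a question-answering backend
#'
#' Extractive contract: an answer, when present, is a contiguous substring
#' of the context, returned with 0-based half-open offsets and a confidence
#' in `[0, 1]`; `NULL` means no answer.
#'
#' @param answer_fn `function(question, context) -> NULL` or
#'   `list(text, start, end, confidence)`.
#' @param name Backend label.
#' @return An object of class `pl_qa_backend`.
#' @export
qa_backend <- function(answer_fn, name = "custom") {
  structure(list(answer = answer_fn, name = name), class = "pl_qa_backend")
}

#' Construct a sentence-embedding backend
#'
#' @param embed_fn `function(character vector) -> numeric matrix` with one
#'   row per input text.
#' @param dim Fixed embedding dimension for this provider.
#' @param name Backend label.
#' @return An object of class `pl_embedding_backend`.
#' @export
embedding_backend <- function(embed_fn, dim, name = "custom") {
  structure(list(embed = embed_fn, dim = as.integer(dim), name = name),
            class = "pl_embedding_backend")
}

backend_error <- function(message, parent = NULL) {
  abort(message, class = c("patientlens_backend_error", "patientlens_error"),
        parent = parent)
}

#' Score a hypothesis against a premise
#'
#' @param premise,hypothesis Non-empty strings; the sentence under analysis
#'   is the premise, the instantiated template the hypothesis.
#' @param scorer An entailment backend.
#' @return A single numeric score in `[0, 1]` (clamped, never `NA`).
#'   Backend failures raise a typed `patientlens_backend_error`, so a
#'   crashed model is never mistaken for a low score.
#' @export
score_entailment <- function(premise, hypothesis, scorer) {
  if (!nzchar(premise) || !nzchar(hypothesis)) {
    abort_pl("premise and hypothesis must be non-empty",
             class = "patientlens_contract_error")
  }
  val <- tryCatch(scorer$score(premise, hypothesis), error = function(e) {
    backend_error(sprintf("entailment backend '%s' failed", scorer$name),
                  parent = e)
  })
  if (!is.numeric(val) || length(val) != 1 || is.na(val)) {
    backend_error(sprintf("entailment backend '%s' returned a non-score",
                          scorer$name))
  }
  clamp01(as.numeric(val))
}

#' Extract an answer span from a context
#'
#' @param question Question string.
#' @param context Context string (here: one sentence).
#' @param answerer A question-answering backend.
#' @return `NULL` when the backend abstains; otherwise a list with `text`,
#'   `start`, `end` (0-based half-open into `context`) and `confidence`.
#'   The extractive guarantee `substr0(context, start, end) == text` is
#'   enforced.
#' @export
extract_answer <- function(question, context, answerer) {
  ans <- tryCatch(answerer$answer(question, context), error = function(e) {
    backend_error(sprintf("qa backend '%s' failed", answerer$name),
                  parent = e)
  })
  if (is.null(ans)) return(NULL)
  ans$confidence <- clamp01(ans$confidence %||% 1)
  if (!identical(substr0(context, ans$start, ans$end), ans$text)) {
    backend_error(sprintf(
      "qa backend '%s' violated the extractive contract", answerer$name))
  }
  ans
}

#' Embed a collection of sentences
#'
#' @param texts Character vector.
#' @param embedder An embedding backend.
#' @return A numeric matrix, one row per text (0-row matrix for empty
#'   input), with exactly `embedder$dim` columns.
#' @export
embed_sentences <- function(texts, embedder) {
  if (length(texts) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = embedder$dim))
  }
  mat <- tryCatch(embedder$embed(texts), error = function(e) {
    backend_error(sprintf("embedding backend '%s' failed", embedder$name),
                  parent = e)
  })
  if (!is.matrix(mat) || nrow(mat) != length(texts) ||
      ncol(mat) != embedder$dim) {
    backend_error(sprintf("embedding backend '%s' returned wrong shape",
                          embedder$name))
  }
  mat
}

# ---- reference implementations -------------------------------------------

# content tokens for the reference scorer: casefold, drop stopwords and
# indefinite placeholders, strip one regular suffix (ing/ed/es/s)
scorer_tokens <- function(text) {
  toks <- token_spans(stringr::str_to_lower(text))$token
  toks <- toks[!(toks %in% pl_stopwords) & !(toks %in% pl_indefinites)]
  vapply(toks, strip_suffix, character(1), USE.NAMES = FALSE)
}

strip_suffix <- function(tok) {
  for (suf in c("ing", "ed", "es", "s")) {
    if (stringr::str_ends(tok, suf) && nchar(tok) - nchar(suf) >= 3) {
      return(stringr::str_sub(tok, 1, nchar(tok) - nchar(suf)))
    }
  }
  tok
}

# stem equivalence: exact, or one stem a prefix of the other with the
# shorter >= 4 characters (absorbs diagnos/diagnosi-style residue)
stems_match <- function(a, b) {
  if (a == b) return(TRUE)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  nchar(a) >= 4 && stringr::str_starts(b, stringr::fixed(a))
}

#' Reference entailment scorer
#'
#' A deterministic lexical-overlap formula standing in for a natural
#' language inference model so the whole pipeline runs offline.  Let `k` be
#' the number of content tokens of the hypothesis (stopwords and the
#' indefinite placeholders *someone/something/...* excluded, tokens
#' suffix-stripped) and `m` the number of them with a stem-equivalent token
#' in the premise.  A full match (`m == k`) scores
#' `min(1, 1 + 0.1 * order)` = 1; a partial match scores `m / (2k)`, so a
#' multi-word slot filler alone can never push a hypothesis past a 0.5
#' threshold -- the predicate tokens have to match too.  `order` is 1 when
#' the matched premise positions are strictly increasing; `k = 0` scores
#' 0.  Pure-functional: identical input gives identical output.
#'
#' @return An entailment backend named `"reference"`.
#' @export
#' @examples
#' s <- reference_entailment_backend()
#' score_entailment("water is wet", "water is wet", s)
reference_entailment_backend <- function() {
  entailment_backend(function(premise, hypothesis) {
    h <- scorer_tokens(hypothesis)
    if (length(h) == 0) return(0)
    p <- scorer_tokens(premise)
    pos <- vapply(h, function(tok) {
      hit <- which(vapply(p, stems_match, logical(1), a = tok))
      if (length(hit)) hit[[1]] else NA_integer_
    }, integer(1))
    m <- sum(!is.na(pos))
    if (m < length(h)) return(m / (2 * length(h)))
    ordered <- length(h) >= 2 && !is.unsorted(pos, strictly = TRUE)
    min(1, 1 + if (ordered) 0.1 else 0)
  }, name = "reference")
}

#' Reference pattern-table answerer
#'
#' Maps each known question to an ordered list of capture patterns (up to
#' three word tokens per answer).  Adequate for fixtures and offline tests;
#' explicitly not of production quality.
#'
#' @param patterns Named list: question -> character vector of regular
#'   expressions with exactly one capture group.
#' @return A question-answering backend named `"reference"`.
#' @export
reference_qa_backend <- function(patterns = reference_qa_patterns()) {
  qa_backend(function(question, context) {
    pats <- patterns[[question]]
    if (is.null(pats)) return(NULL)
    for (pat in pats) {
      m <- regexpr(pat, context, perl = TRUE, ignore.case = TRUE)
      if (m[[1]] == -1L) next
      cs <- attr(m, "capture.start")[1, 1]
      cl <- attr(m, "capture.length")[1, 1]
      start <- as.integer(cs - 1L)
      end <- as.integer(cs - 1L + cl)
      return(list(text = substr0(context, start, end),
                  start = start, end = end, confidence = 0.8))
    }
    NULL
  }, name = "reference")
}

# up-to-three-word noun-phrase-ish capture
np3 <- "((?:[\\w'-]+ ){0,2}[\\w'-]+)"

#' Default question patterns for the reference answerer
#' @return Named list of capture patterns.
#' @export
reference_qa_patterns <- function() {
  list(
    "What is needed?" = c(
      paste0("in need of ", np3),
      paste0("\\bneeds? ", np3),
      paste0("\\brequires? ", np3)
    ),
    "What support is provided?" = c(
      paste0("support (?:from|by) ", np3),
      paste0("\\breceives? ", np3),
      paste0("\\boffers? ", np3),
      paste0("\\bprovides? ", np3)
    ),
    "Who provides support?" = c(
      paste0(np3, " (?:provides?|offers?|offered) support"),
      paste0("support (?:from|by) ", np3)
    )
  )
}

#' Reference feature-hashing sentence embedder
#'
#' Seeded bag-of-words feature hashing into a fixed 256-dimensional vector:
#' every casefolded token is hashed to a coordinate and a sign, and counts
#' are accumulated.  Fully deterministic; identical texts map to identical
#' vectors.
#'
#' @param dim Embedding dimension.
#' @param seed Hash salt.
#' @return An embedding backend named `"reference"`.
#' @export
reference_embedding_backend <- function(dim = 256L, seed = 1L) {
  dim <- as.integer(dim)
  embedding_backend(function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      toks <- token_spans(stringr::str_to_lower(texts[[i]]))$token
      for (tok in toks) {
        h <- string_hash(tok, seed = seed)
        idx <- (h %% dim) + 1L
        sgn <- if (floor(h / dim) %% 2 == 0) 1 else -1
        out[i, idx] <- out[i, idx] + sgn
      }
    }
    out
  }, dim = dim, name = "reference")
}

#' Constant-score entailment backend
#'
#' Returns the same score for every (premise, hypothesis) pair; used to
#' probe threshold semantics.
#'
#' @param value The constant score.
#' @return An entailment backend named `"constant"`.
#' @export
constant_entailment_backend <- function(value) {
  entailment_backend(function(premise, hypothesis) value, name = "constant")
}

# ---- backend registry ----------------------------------------------------

the_registry <- new.env(parent = emptyenv())

#' Register a named backend
#'
#' Plugins register themselves under `(kind, name)` and become resolvable
#' from configuration keys such as `backends.entailment = "myplugin"`.
#'
#' @param kind One of `"entailment"`, `"qa"`, `"embedding"`.
#' @param name Registry key.
#' @param backend The backend object.
#' @return `backend`, invisibly.
#' @export
register_backend <- function(kind, name, backend) {
  kind <- match.arg(kind, c("entailment", "qa", "embedding"))
  assign(paste(kind, name, sep = "."), backend, envir = the_registry)
  invisible(backend)
}

#' Resolve a backend from a configuration value
#'
#' `"reference"` resolves to the packaged reference implementation; a
#' backend object passes through unchanged; any other string is looked up
#' in the plugin registry.  (`"oracle"` backends are bound to a particular
#' synthetic corpus, so they are obtained from [oracle_backends()] and
#' passed as objects.)
#'
#' @inheritParams register_backend
#' @param value Configuration value: a backend object or a name.
#' @return A backend object.
#' @export
resolve_backend <- function(kind, value) {
  kind <- match.arg(kind, c("entailment", "qa", "embedding"))
  expected <- paste0("pl_", kind, "_backend")
  if (inherits(value, expected)) return(value)
  if (identical(value, "reference")) {
    return(switch(kind,
      entailment = reference_entailment_backend(),
      qa = reference_qa_backend(),
      embedding = reference_embedding_backend()
    ))
  }
  key <- paste(kind, value, sep = ".")
  if (exists(key, envir = the_registry)) {
    return(get(key, envir = the_registry))
  }
  abort_pl(sprintf("unknown %s backend '%s'", kind, value),
           class = "patientlens_config_error")
}
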
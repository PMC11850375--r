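# Dictionary/ontology-based recognition of the four primary biomedical
# entity classes: disease (DI), drug (DR), symptom (SY), treatment (TR).
# Medical ontologies consist mostly of unambiguous terms, so exact
# case-insensitive matching at token boundaries buys high precision; the
# residual false-positive sources are handled by explicit filters
# (organization spans, non-nominal phrase heads, per-ontology blacklists)
# and by the disease/symptom overlap rule.

pl_primary_types <- c("DI", "DR", "SY", "TR")
# precedence when several concept types match the identical span
pl_type_precedence <- c("DR", "TR", "DI", "SY")

#' Build a concept lexicon
#'
#' @param entries Tibble/data.frame with columns `term`, `concept_type`
#'   (one of `DI`, `DR`, `SY`, `TR`), `canonical_id`, `source`.
#' @param blacklist Named list: source name -> character vector of excluded
#'   terms (matched after normalization).  Blacklisted terms are never
#'   matchable.
#' @return A `concept_lexicon` object.  Lookup is case-insensitive;
#'   `(term, concept_type)` pairs are unique after normalization.
#' @export
concept_lexicon <- function(entries, blacklist = list()) {
  entries <- tibble::as_tibble(entries)
  needed <- c("term", "concept_type", "canonical_id", "source")
  if (!all(needed %in% names(entries))) {
    abort_pl("lexicon entries need columns term, concept_type, canonical_id, source",
             class = "patientlens_config_error")
  }
  if (any(!nzchar(entries$term))) {
    abort_pl("empty lexicon term", class = "patientlens_config_error")
  }
  bad <- setdiff(unique(entries$concept_type), pl_primary_types)
  if (length(bad)) {
    abort_pl(sprintf("unknown concept type(s): %s",
                     paste(bad, collapse = ", ")),
             class = "patientlens_config_error")
  }
  entries$term_norm <- normalize_term(entries$term)
  entries <- entries[!duplicated(entries[, c("term_norm", "concept_type")]), ]
  entries$n_tokens <- vapply(
    entries$term_norm,
    function(t) length(stringr::str_split_1(t, " ")), integer(1),
    USE.NAMES = FALSE)
  blacklist <- lapply(blacklist, normalize_term)
  drop <- mapply(function(norm, src) {
    !is.null(blacklist[[src]]) && norm %in% blacklist[[src]]
  }, entries$term_norm, entries$source)
  structure(
    list(entries = entries[!drop, , drop = FALSE], blacklist = blacklist),
    class = "concept_lexicon")
}

#' @export
print.concept_lexicon <- function(x, ...) {
  cat(sprintf("<concept_lexicon> %d terms (%s); %d blacklist(s)\n",
              nrow(x$entries),
              paste(sprintf("%s: %d", names(table(x$entries$concept_type)),
                            table(x$entries$concept_type)), collapse = ", "),
              length(x$blacklist)))
  invisible(x)
}

#' Read a concept lexicon from TSV files
#'
#' The lexicon file has tab-separated columns `term`, `type`,
#' `canonical_id`, `source` (with a header).  Blacklists live next to it as
#' `<source>.blacklist.txt`, one term per line.
#'
#' @param path Path to the lexicon TSV.
#' @param blacklist_dir Directory scanned for `*.blacklist.txt`; defaults
#'   to the lexicon's directory.
#' @return A `concept_lexicon`.
#' @export
read_lexicon <- function(path, blacklist_dir = dirname(path)) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           fileEncoding = "UTF-8")
  entries <- tibble::tibble(
    term = raw$term, concept_type = raw$type,
    canonical_id = raw$canonical_id, source = raw$source)
  files <- list.files(blacklist_dir, pattern = "\\.blacklist\\.txt$",
                      full.names = TRUE)
  blacklist <- lapply(files, function(f) {
    lines <- readLines(f, encoding = "UTF-8", warn = FALSE)
    lines[nzchar(trimws(lines))]
  })
  names(blacklist) <- stringr::str_remove(basename(files),
                                          "\\.blacklist\\.txt$")
  concept_lexicon(entries, blacklist)
}

#' Build a class hierarchy from an edge list
#'
#' @param edges Tibble/data.frame of `child`, `parent` id pairs.
#' @param labels Named character vector: node id -> human-readable term.
#' @return A `class_hierarchy` (checked acyclic; every referenced node must
#'   be labeled).
#' @export
class_hierarchy <- function(edges, labels) {
  edges <- tibble::as_tibble(edges)
  nodes <- unique(c(edges$child, edges$parent))
  missing <- setdiff(nodes, names(labels))
  if (length(missing)) {
    abort_pl(sprintf("unlabeled hierarchy node(s): %s",
                     paste(missing, collapse = ", ")),
             class = "patientlens_config_error")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$child, to = edges$parent),
    directed = TRUE, vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) {
    abort_pl("class hierarchy contains a cycle",
             class = "patientlens_config_error")
  }
  structure(list(graph = g, labels = labels), class = "class_hierarchy")
}

#' Read a class hierarchy from TSV files
#'
#' @param edges_path TSV with header columns `child`, `parent`.
#' @param labels_path TSV with header columns `id`, `label`.
#' @return A `class_hierarchy`.
#' @export
read_class_hierarchy <- function(edges_path, labels_path) {
  edges <- utils::read.delim(edges_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "",
                             fileEncoding = "UTF-8")
  lab <- utils::read.delim(labels_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           fileEncoding = "UTF-8")
  class_hierarchy(edges, setNames(lab$label, lab$id))
}

#' Compile a treatment lexicon from a class hierarchy
#'
#' Medical ontologies rarely offer a dedicated treatment vocabulary, so one
#' is compiled from a generic class hierarchy (e.g. a Wikidata extract):
#' all terms classified under the include superclasses (typically *therapy*
#' and *medical procedure*) are retrieved, and everything under the exclude
#' superclasses (diagnostic categories such as *health assessment*,
#' *invasive test*, *medical diagnosis*, *medical test*) is removed.
#' "Under" is inclusive of the root itself, and exclusion wins when a node
#' sits under both.
#'
#' @param hierarchy A [class_hierarchy()].
#' @param include_roots,exclude_roots Node ids.
#' @param source Source tag stamped on the produced entries.
#' @return A tibble of `LexiconEntry` rows with `concept_type = "TR"`.
#' @export
compile_treatment_lexicon <- function(hierarchy, include_roots,
                                      exclude_roots = character(),
                                      source = "hierarchy") {
  known <- igraph::V(hierarchy$graph)$name
  bad <- setdiff(c(include_roots, exclude_roots), known)
  if (length(bad)) {
    abort_pl(sprintf("unknown hierarchy root(s): %s",
                     paste(bad, collapse = ", ")),
             class = "patientlens_config_error")
  }
  descendants <- function(roots) {
    if (length(roots) == 0) return(character(0))
    unique(unlist(lapply(roots, function(r) {
      igraph::subcomponent(hierarchy$graph, r, mode = "in")$name
    })))
  }
  keep <- setdiff(descendants(include_roots), descendants(exclude_roots))
  keep <- sort(keep)
  tibble::tibble(
    term = unname(hierarchy$labels[keep]),
    concept_type = "TR",
    canonical_id = keep,
    source = source
  )
}

#' Reference token annotator
#'
#' Regex word tokenization only: no part-of-speech tags, phrase heads or
#' organization spans.  The matcher's head-noun and ORGANIZATION filters
#' degrade gracefully (skipped with a logged warning) when these
#' capabilities are absent, so the full pipeline runs model-free.
#'
#' @return An annotator: `function(text) -> list(tokens, pos, org_spans)`
#'   where `pos` and `org_spans` are `NULL`.
#' @export
reference_annotator <- function() {
  function(text) list(tokens = token_spans(text), pos = NULL,
                      org_spans = NULL)
}

#' Assemble an annotator with explicit capabilities (mainly for tests)
#'
#' @param pos_lexicon Named character vector token (casefolded) ->
#'   coarse part-of-speech tag (`"NOUN"`, `"PROPN"`, `"VERB"`, ...);
#'   unlisted tokens get `"X"`.
#' @param org_patterns Regular expressions whose matches are tagged as
#'   ORGANIZATION spans.
#' @return An annotator function.
#' @export
make_annotator <- function(pos_lexicon = NULL, org_patterns = NULL) {
  function(text) {
    toks <- token_spans(text)
    pos <- NULL
    if (!is.null(pos_lexicon)) {
      pos <- unname(pos_lexicon[stringr::str_to_lower(toks$token)])
      pos[is.na(pos)] <- "X"
    }
    org <- NULL
    if (!is.null(org_patterns)) {
      locs <- lapply(org_patterns, function(p) {
        stringr::str_locate_all(text, p)[[1]]
      })
      locs <- do.call(rbind, locs)
      org <- if (is.null(locs) || nrow(locs) == 0) {
        tibble::tibble(start = integer(), end = integer())
      } else {
        tibble::tibble(start = locs[, 1] - 1L, end = locs[, 2])
      }
    }
    list(tokens = toks, pos = pos, org_spans = org)
  }
}

#' Match lexicon concepts in one sentence
#'
#' Case-insensitive, token-boundary-aligned dictionary matching with
#' leftmost-longest resolution: scanning left to right, the longest
#' matching term starting at the current token wins and matching resumes
#' after it, so returned mentions never overlap.  When several concept
#' types match the identical span the precedence `DR > TR > DI > SY`
#' applies (the disease/symptom overlap is instead handled by
#' [resolve_disease_symptom_overlap()]).  Two precision filters run when
#' the annotator supports them: matches inside ORGANIZATION spans are
#' dropped (disease names embedded in foundation names), and matches whose
#' phrase head -- approximated by the final token -- is not a noun or
#' proper noun are dropped.  Missing capabilities skip the filter with a
#' logged warning.
#'
#' @param sentence One-row sentences tibble (or list with `text`).
#' @param lexicon A [concept_lexicon()].
#' @param annotator Token-annotation function; defaults to
#'   [reference_annotator()].
#' @return An `EntityMention` tibble: `concept_type`, `surface`, `start`,
#'   `end` (sentence-relative, 0-based half-open), `canonical_id`,
#'   `source`.
#' @export
#' @examples
#' lex <- concept_lexicon(tibble::tibble(
#'   term = c("pirfenidone", "nintedanib"), concept_type = "DR",
#'   canonical_id = c("D1", "D2"), source = "demo"))
#' match_concepts(list(text = "She takes pirfenidone daily"), lex)
match_concepts <- function(sentence, lexicon,
                           annotator = reference_annotator()) {
  text <- sentence$text[[1]]
  entries <- lexicon$entries
  if (nrow(entries) == 0 || is.na(text) || !nzchar(text)) {
    return(new_mention_tbl())
  }
  ann <- annotator(text)
  toks <- ann$tokens
  if (nrow(toks) == 0) return(new_mention_tbl())
  max_len <- max(entries$n_tokens)
  found <- list()
  i <- 1L
  n <- nrow(toks)
  while (i <= n) {
    hit <- NULL
    for (j in seq(min(n, i + max_len - 1L), i)) {
      span_norm <- normalize_term(substr0(text, toks$start[[i]],
                                          toks$end[[j]]))
      cand <- entries[entries$term_norm == span_norm, , drop = FALSE]
      if (nrow(cand) > 0) {
        cand <- cand[order(match(cand$concept_type, pl_type_precedence)), ]
        hit <- list(entry = cand[1, ], start = toks$start[[i]],
                    end = toks$end[[j]], last_tok = j)
        break
      }
    }
    if (is.null(hit)) { i <- i + 1L; next }
    found[[length(found) + 1L]] <- tibble::tibble(
      concept_type = hit$entry$concept_type,
      surface = substr0(text, hit$start, hit$end),
      start = as.integer(hit$start), end = as.integer(hit$end),
      canonical_id = hit$entry$canonical_id,
      source = hit$entry$source,
      last_tok = hit$last_tok
    )
    i <- hit$last_tok + 1L
  }
  if (length(found) == 0) return(new_mention_tbl())
  mentions <- dplyr::bind_rows(found)

  # ORGANIZATION filter
  if (is.null(ann$org_spans)) {
    warn("annotator provides no ORGANIZATION spans; filter skipped",
         class = "patientlens_capability_warning")
  } else if (nrow(ann$org_spans) > 0) {
    inside <- vapply(seq_len(nrow(mentions)), function(k) {
      any(mentions$start[[k]] < ann$org_spans$end &
            ann$org_spans$start < mentions$end[[k]])
    }, logical(1))
    mentions <- mentions[!inside, , drop = FALSE]
  }

  # phrase-head filter (head approximated by the match's final token)
  if (is.null(ann$pos)) {
    warn("annotator provides no part-of-speech tags; head filter skipped",
         class = "patientlens_capability_warning")
  } else if (nrow(mentions) > 0) {
    head_pos <- ann$pos[mentions$last_tok]
    mentions <- mentions[head_pos %in% c("NOUN", "PROPN"), , drop = FALSE]
  }
  mentions$last_tok <- NULL
  mentions
}

#' Terms present in both the disease and the symptom lexicon
#' @param lexicon A [concept_lexicon()].
#' @return Normalized terms carried by both `DI` and `SY` entries.
#' @export
disease_symptom_overlap_terms <- function(lexicon) {
  e <- lexicon$entries
  intersect(e$term_norm[e$concept_type == "DI"],
            e$term_norm[e$concept_type == "SY"])
}

#' Relabel disease/symptom overlap mentions as symptoms
#'
#' Disease and symptom ontologies overlap, and lay authors use the two
#' interchangeably, so a reliable distinction cannot be drawn from the
#' text; every overlapping term is therefore treated as a symptom.
#'
#' @param mentions An `EntityMention` tibble.
#' @param overlap_terms Normalized terms present in both lexicons, e.g.
#'   from [disease_symptom_overlap_terms()].
#' @return `mentions` with affected `DI` rows relabeled `SY`; everything
#'   else untouched.
#' @export
resolve_disease_symptom_overlap <- function(mentions, overlap_terms) {
  if (nrow(mentions) == 0 || length(overlap_terms) == 0) return(mentions)
  flip <- mentions$concept_type == "DI" &
    normalize_term(mentions$surface) %in% overlap_terms
  mentions$concept_type[flip] <- "SY"
  mentions
}
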
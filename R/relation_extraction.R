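# Zero-shot relation extraction.  For every unordered pair of mentions in
# a sentence, slotted hypothesis templates are instantiated in both
# argument orders (direction is decided by which order scores higher),
# ontologically inadmissible relations are pruned up front (a disease
# cannot cause a point in time), the highest-scoring hypothesis wins if it
# clears the threshold -- only one relation can hold between two concepts
# -- and finally micro-relations without an in-sentence lexical trigger
# are demoted to their macro-relation, because a causal or
# ameliorative/exacerbative reading requires an explicit cue word.

#' The relation inventory
#'
#' Seven relations plus `NOREL`: *ameliorates* (AM), *creates* (CR),
#' *diagnoses* (DG), *exacerbates* (EX), *is associated with* (IAW, the
#' only symmetric relation -- swapping the arguments does not change the
#' meaning), *is used for* (IUF) and *is time of* (ITO).  AM is a
#' subclass (micro-relation) of the macro-relation IUF; CR and EX are
#' micro-relations of IAW.
#'
#' @return A tibble with `code`, `symmetric`, `macro_of`.
#' @export
relation_types <- function() {
  tibble::tibble(
    code = c("AM", "CR", "DG", "EX", "IAW", "IUF", "ITO", "NOREL"),
    symmetric = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    macro_of = c("IUF", "IAW", NA, "IAW", NA, NA, NA, NA)
  )
}

pl_micro_relations <- c("AM", "CR", "EX")
# fixed tie-break precedence (an artifact decision; deterministic)
pl_relation_precedence <- c("DG", "ITO", "AM", "EX", "CR", "IUF", "IAW")
pl_bio_types <- c("DI", "SY", "TR", "DR")
pl_point_time_types <- c("DT", "DU")

#' Default relation schema
#'
#' Bundles hypothesis templates (two slots, `{concept 1}` and
#' `{concept 2}`), the type-admissibility rules, the micro-relation cue
#' lists and the decision threshold (default 0.2, the operating point of
#' the thresholded argmax).  Admissibility: DG, IUF and AM take a
#' treatment or drug as first argument and a disease or symptom as second;
#' CR and EX take any ordered biomedical pair; IAW any biomedical pair;
#' ITO takes a date/duration mention as first argument and a biomedical
#' mention as second.  Cue lists: the AM and EX inventories with regular
#' inflections, and an explicit-causation list for CR ("causes", "due
#' to", "leads to", ...); matching is case-insensitive at word
#' boundaries, so "IPF cough" never licenses a causal reading.
#'
#' @param threshold Decision threshold override.
#' @return A `relation_schema` list with `templates`, `admissible`,
#'   `cues`, `threshold`.
#' @export
default_relation_schema <- function(threshold = 0.2) {
  schema <- list(
    templates = list(
      AM = "{concept 1} ameliorates {concept 2}",
      CR = "{concept 1} leads to {concept 2}",
      DG = "{concept 1} is used to diagnose {concept 2}",
      EX = "{concept 1} worsens {concept 2}",
      IAW = "{concept 1} is associated with {concept 2}",
      IUF = "{concept 1} is used for {concept 2}",
      ITO = "{concept 1} is the time of {concept 2}"
    ),
    admissible = list(
      AM = list(arg1 = c("TR", "DR"), arg2 = c("DI", "SY")),
      CR = list(arg1 = pl_bio_types, arg2 = pl_bio_types),
      DG = list(arg1 = c("TR", "DR"), arg2 = c("DI", "SY")),
      EX = list(arg1 = pl_bio_types, arg2 = pl_bio_types),
      IAW = list(arg1 = pl_bio_types, arg2 = pl_bio_types),
      IUF = list(arg1 = c("TR", "DR"), arg2 = c("DI", "SY")),
      ITO = list(arg1 = pl_point_time_types, arg2 = pl_bio_types)
    ),
    cues = list(
      AM = c("improve", "improves", "improved", "ameliorate", "ameliorates",
             "amelioration", "decrease", "decreases", "decreased",
             "reduce", "reduces", "reduced"),
      CR = c("causes", "caused", "leads to", "led to", "due to",
             "results in", "resulting in", "because of"),
      EX = c("exacerbate", "exacerbates", "exacerbated", "worsen",
             "worsens", "worsened", "worse")
    ),
    threshold = threshold
  )
  structure(schema, class = "relation_schema")
}

#' Read a relation schema from a YAML file
#'
#' Keys `templates` (relation -> pattern or list of patterns),
#' `admissible` (relation -> `arg1`/`arg2` type lists), `cues`
#' (micro-relation -> trigger words) and `threshold`.  Missing keys fall
#' back to the defaults.
#'
#' @param path YAML path.
#' @return A `relation_schema`.
#' @export
read_relation_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_relation_schema()
  for (key in c("templates", "admissible", "cues")) {
    if (!is.null(raw[[key]])) base[[key]] <- raw[[key]]
  }
  if (!is.null(raw$threshold)) base$threshold <- as.numeric(raw$threshold)
  validate_relation_schema(base)
}

validate_relation_schema <- function(schema) {
  rels <- setdiff(relation_types()$code, "NOREL")
  missing <- setdiff(rels, names(schema$templates))
  if (length(missing)) {
    abort_pl(sprintf("relation(s) without template: %s",
                     paste(missing, collapse = ", ")),
             class = "patientlens_config_error")
  }
  # ITO must involve exactly one time-typed argument
  ito <- schema$admissible$ITO
  if (!all(ito$arg1 %in% pl_point_time_types) ||
      any(ito$arg2 %in% pl_point_time_types)) {
    abort_pl("ITO admissibility must have a time-typed first argument only",
             class = "patientlens_config_error")
  }
  structure(schema, class = "relation_schema")
}

instantiate_template <- function(pattern, s1, s2) {
  out <- stringr::str_replace(pattern, stringr::fixed("{concept 1}"), s1)
  stringr::str_replace(out, stringr::fixed("{concept 2}"), s2)
}

#' Generate candidate relation hypotheses for a mention pair
#'
#' For every relation admissible between the two mention types and every
#' template of that relation, instantiates the hypothesis string: both
#' argument orders for directed relations (the swapped hypothesis is what
#' determines direction), a single offset-canonical instantiation for the
#' symmetric IAW.  Inadmissible relations produce nothing -- ontological
#' pruning before any model call.
#'
#' @param sentence One-row sentences tibble (unused by the default
#'   implementation, kept for contract symmetry).
#' @param pair Two-row mention tibble (columns `concept_type` or
#'   `time_class` unified as `type`, plus `surface`, `start`, `end`).
#' @param schema A `relation_schema`.
#' @return Tibble `relation`, `direction` (`"forward"` = first pair row is
#'   arg1, `"reverse"`, or `"symmetric"`), `hypothesis`.
#' @export
generate_hypotheses <- function(sentence, pair, schema) {
  empty <- tibble::tibble(relation = character(), direction = character(),
                          hypothesis = character())
  if (is.null(pair) || nrow(pair) != 2) return(empty)
  t1 <- pair$type[[1]]; t2 <- pair$type[[2]]
  out <- list()
  for (rel in names(schema$templates)) {
    adm <- schema$admissible[[rel]]
    if (is.null(adm)) next
    sym <- relation_types()$symmetric[relation_types()$code == rel]
    fwd <- t1 %in% adm$arg1 && t2 %in% adm$arg2
    rev <- t2 %in% adm$arg1 && t1 %in% adm$arg2
    if (!fwd && !rev) next
    for (pattern in schema$templates[[rel]]) {
      if (sym) {
        # canonical order: smaller start offset first
        first <- if (pair$start[[1]] <= pair$start[[2]]) 1L else 2L
        out[[length(out) + 1L]] <- tibble::tibble(
          relation = rel, direction = "symmetric",
          hypothesis = instantiate_template(
            pattern, pair$surface[[first]], pair$surface[[3L - first]]))
        next
      }
      if (fwd) {
        out[[length(out) + 1L]] <- tibble::tibble(
          relation = rel, direction = "forward",
          hypothesis = instantiate_template(pattern, pair$surface[[1]],
                                            pair$surface[[2]]))
      }
      if (rev) {
        out[[length(out) + 1L]] <- tibble::tibble(
          relation = rel, direction = "reverse",
          hypothesis = instantiate_template(pattern, pair$surface[[2]],
                                            pair$surface[[1]]))
      }
    }
  }
  if (length(out) == 0) return(empty)
  unique(dplyr::bind_rows(out))
}

#' Select the winning relation from scored hypotheses
#'
#' Argmax over all (relation, direction) candidates; multiple templates of
#' one relation aggregate by maximum.  If the best score does not strictly
#' exceed the threshold the pair holds no relation (`NOREL`).  Ties break
#' by the fixed precedence `DG > ITO > AM > EX > CR > IUF > IAW`, then by
#' forward direction.
#'
#' @param scored Tibble with `relation`, `direction`, `score`.
#' @param schema A `relation_schema` (supplies the threshold).
#' @return List `relation`, `direction` (`NA` for `NOREL`), `score`.
#' @export
select_relation <- function(scored, schema) {
  if (is.null(scored) || nrow(scored) == 0) {
    return(list(relation = "NOREL", direction = NA_character_, score = 0))
  }
  ord <- order(-scored$score,
               match(scored$relation, pl_relation_precedence),
               match(scored$direction, c("forward", "symmetric", "reverse")))
  best <- scored[ord[[1]], ]
  if (best$score <= schema$threshold) {
    return(list(relation = "NOREL", direction = NA_character_,
                score = best$score))
  }
  list(relation = best$relation, direction = best$direction,
       score = best$score)
}

cue_present <- function(text, cues) {
  any(vapply(cues, function(cue) {
    pat <- paste0("\\b", stringr::str_replace_all(cue, " ", " +"), "\\b")
    stringr::str_detect(text, stringr::regex(pat, ignore_case = TRUE))
  }, logical(1)))
}

#' Demote a micro-relation without a lexical trigger
#'
#' If the selected relation is a micro-relation (AM, CR, EX) and none of
#' its trigger words occurs in the sentence (case-insensitive,
#' word-boundary match), it is demoted to its macro-relation (AM -> IUF,
#' CR/EX -> IAW).  A demotion to the symmetric IAW canonicalizes the
#' direction to `"symmetric"`.
#'
#' @param selection Output of [select_relation()].
#' @param sentence_text The sentence.
#' @param schema A `relation_schema` (supplies the cue lists).
#' @return The (possibly demoted) selection.
#' @export
apply_cue_demotion <- function(selection, sentence_text, schema) {
  rel <- selection$relation
  if (!rel %in% pl_micro_relations) return(selection)
  if (cue_present(sentence_text, schema$cues[[rel]])) return(selection)
  types <- relation_types()
  macro <- types$macro_of[types$code == rel]
  selection$relation <- macro
  if (types$symmetric[types$code == macro]) {
    selection$direction <- "symmetric"
  }
  selection
}

#' Extract relations between the mentions of one sentence
#'
#' Composition of [generate_hypotheses()], entailment scoring,
#' [select_relation()] and [apply_cue_demotion()] over all unordered
#' mention pairs.  Relations are extracted as stated in the text, not as
#' they hold in reality: the only evidence consulted is the sentence
#' itself.  For directed results `arg1` is the head of the relation; for
#' the symmetric IAW the argument with the smaller start offset is `arg1`,
#' so extraction is invariant under argument swap.
#'
#' @param sentence One-row sentences tibble (or list with `text`).
#' @param mentions Mention tibble with a unified `type` column (`DI`,
#'   `DR`, `SY`, `TR`, `DT`, `DU`, `T`, `S`), `surface`, `start`, `end`.
#' @param schema A `relation_schema`.
#' @param scorer Entailment backend.
#' @param keep_norel Emit `NOREL` rows too (off by default; needed for
#'   SemEval-style evaluation against datasets that include no-relation
#'   pairs).
#' @return A `RelationInstance` tibble: `arg1_*`/`arg2_*` (type, surface,
#'   start, end), `relation`, `direction`, `score`.  Every non-`NOREL`
#'   row has `score > schema$threshold`.
#' @export
extract_relations <- function(sentence, mentions, schema, scorer,
                              keep_norel = FALSE) {
  empty <- tibble::tibble(
    arg1_type = character(), arg1_surface = character(),
    arg1_start = integer(), arg1_end = integer(),
    arg2_type = character(), arg2_surface = character(),
    arg2_start = integer(), arg2_end = integer(),
    relation = character(), direction = character(), score = numeric())
  if (is.null(mentions) || nrow(mentions) < 2) return(empty)
  mentions <- mentions[order(mentions$start, mentions$end), , drop = FALSE]
  text <- sentence$text[[1]]
  pairs <- combn(nrow(mentions), 2)
  out <- list()
  for (k in seq_len(ncol(pairs))) {
    pair <- mentions[pairs[, k], , drop = FALSE]
    hyps <- generate_hypotheses(sentence, pair, schema)
    if (nrow(hyps) > 0) {
      hyps$score <- vapply(hyps$hypothesis, function(h) {
        score_entailment(text, h, scorer)
      }, numeric(1), USE.NAMES = FALSE)
    } else {
      hyps$score <- numeric(0)
    }
    sel <- select_relation(hyps, schema)
    sel <- apply_cue_demotion(sel, text, schema)
    if (sel$relation == "NOREL" && !keep_norel) next
    ord <- if (identical(sel$direction, "reverse")) c(2L, 1L) else c(1L, 2L)
    a <- pair[ord[[1]], ]; b <- pair[ord[[2]], ]
    direction <- if (is.na(sel$direction)) NA_character_
      else if (identical(sel$direction, "symmetric")) "symmetric"
      else "forward"
    out[[length(out) + 1L]] <- tibble::tibble(
      arg1_type = a$type, arg1_surface = a$surface,
      arg1_start = a$start, arg1_end = a$end,
      arg2_type = b$type, arg2_surface = b$surface,
      arg2_start = b$start, arg2_end = b$end,
      relation = sel$relation, direction = direction, score = sel$score)
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}
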
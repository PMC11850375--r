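# Abstract entities -- need, support, diagnosis, misdiagnosis -- cannot be
# enumerated in a lexicon: needs may be social or psychological, support
# takes arbitrary shapes.  They are detected by hypothesis screening
# (zero-shot entailment) and, for the ungrounded targets, an extractive
# question-answering step on the sentences that pass.  Diagnosis and
# misdiagnosis are grounded in previously extracted disease/symptom
# mentions: the hypothesis "<entity> was diagnosed." can only be
# instantiated once the entity is known, which injects ontology knowledge
# into an otherwise general-domain inference model.

pl_abstract_targets <- c("NEED", "SUPPORT", "DIAGNOSIS", "MISDIAGNOSIS")
pl_grounded_targets <- c("DIAGNOSIS", "MISDIAGNOSIS")

#' Construct a hypothesis template
#'
#' Grounded targets (`DIAGNOSIS`, `MISDIAGNOSIS`) carry exactly one
#' `{entity}` slot and no questions; ungrounded targets (`NEED`,
#' `SUPPORT`) carry no slot and at least one question, asked in priority
#' order.
#'
#' @param target One of `NEED`, `SUPPORT`, `DIAGNOSIS`, `MISDIAGNOSIS`.
#' @param pattern Hypothesis pattern, e.g. `"Someone needs something."` or
#'   `"{entity} was diagnosed."`.
#' @param questions Character vector of questions (ungrounded targets).
#' @param threshold Screening threshold in `[0, 1]`; a sentence passes only
#'   with score strictly above it.
#' @return A one-row `HypothesisTemplate` tibble.
#' @export
hypothesis_template <- function(target, pattern, questions = character(),
                                threshold = 0.5) {
  target <- match.arg(target, pl_abstract_targets)
  n_slots <- stringr::str_count(pattern, stringr::fixed("{entity}"))
  grounded <- target %in% pl_grounded_targets
  if (grounded && n_slots != 1) {
    abort_pl(sprintf("%s template needs exactly one {entity} slot", target),
             class = "patientlens_config_error")
  }
  if (!grounded && (n_slots != 0 || length(questions) < 1)) {
    abort_pl(sprintf(
      "%s template must have no slot and at least one question", target),
      class = "patientlens_config_error")
  }
  if (threshold < 0 || threshold > 1) {
    abort_pl("threshold must be in [0, 1]",
             class = "patientlens_config_error")
  }
  tibble::tibble(target = target, pattern = pattern,
                 questions = list(questions), threshold = threshold)
}

#' Default template bank for abstract entities
#'
#' The need hypothesis/question pair and the two diagnosis hypothesis
#' variants are the canonical formulations; the remaining rows are package
#' defaults, fully replaceable via [read_template_bank()].  All four
#' targets default to threshold 0.5.
#'
#' @return A `HypothesisTemplate` tibble (one row per pattern; grounded
#'   targets have several pattern variants whose scores are combined by
#'   maximum).
#' @export
default_template_bank <- function() {
  dplyr::bind_rows(
    hypothesis_template("NEED", "Someone needs something.",
                        questions = "What is needed?"),
    hypothesis_template("SUPPORT", "Someone receives support.",
                        questions = c("What support is provided?",
                                      "Who provides support?")),
    hypothesis_template("DIAGNOSIS", "{entity} was diagnosed."),
    hypothesis_template("DIAGNOSIS", "{entity} was detected."),
    hypothesis_template("MISDIAGNOSIS", "{entity} was misdiagnosed."),
    hypothesis_template("MISDIAGNOSIS", "{entity} was missed.")
  )
}

#' Read a template bank from TSV
#'
#' Columns `target`, `pattern`, `questions` (`|`-separated, may be empty)
#' and `threshold`.
#'
#' @param path TSV path.
#' @return A `HypothesisTemplate` tibble.
#' @export
read_template_bank <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           fileEncoding = "UTF-8")
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    qs <- raw$questions[[i]]
    qs <- if (is.na(qs) || !nzchar(qs)) character() else
      stringr::str_split_1(qs, stringr::fixed("|"))
    hypothesis_template(raw$target[[i]], raw$pattern[[i]], qs,
                        raw$threshold[[i]])
  })
  dplyr::bind_rows(rows)
}

#' Screen a sentence against an ungrounded hypothesis
#'
#' The sentence is the premise, the template pattern the hypothesis; the
#' sentence passes when the entailment score strictly exceeds the template
#' threshold.  Screening before question answering is what keeps the
#' false-positive rate of the extractive step down.
#'
#' @param sentence One-row sentences tibble (or list with `text`).
#' @param template One-row ungrounded `HypothesisTemplate`.
#' @param scorer Entailment backend.
#' @return List with `score` and `pass`.
#' @export
screen_sentence <- function(sentence, template, scorer) {
  if (template$target[[1]] %in% pl_grounded_targets) {
    abort_pl("screen_sentence expects an ungrounded template",
             class = "patientlens_contract_error")
  }
  score <- score_entailment(sentence$text[[1]], template$pattern[[1]],
                            scorer)
  list(score = score, pass = score > template$threshold[[1]])
}

#' Extract the answer span for a screened sentence
#'
#' Questions are asked in template order; the first one yielding a span
#' wins.  The span is guaranteed to be a substring of the sentence.
#'
#' @inheritParams screen_sentence
#' @param answerer Question-answering backend.
#' @return An `AnswerSpan` list (`text`, `start`, `end`, `confidence`) or
#'   `NULL`.
#' @export
extract_target_span <- function(sentence, template, answerer) {
  for (q in template$questions[[1]]) {
    ans <- extract_answer(q, sentence$text[[1]], answerer)
    if (!is.null(ans)) return(ans)
  }
  NULL
}

#' Classify the diagnosis status of a disease/symptom mention
#'
#' Instantiates the grounded diagnosis and misdiagnosis hypothesis variants
#' with the entity surface ("pulmonary fibrosis was diagnosed.", "... was
#' detected.", ...), scores each against the sentence, and keeps the
#' maximum per target -- the variants are alternative phrasings of the same
#' claim.  A target fires when its score strictly exceeds its threshold;
#' when both fire, the more specific `MISDIAGNOSIS` wins.
#'
#' @param sentence One-row sentences tibble (or list with `text`).
#' @param entity One-row `EntityMention`; `concept_type` must be `DI` or
#'   `SY` (diagnosis is defined over diseases and symptoms).
#' @param templates Template bank; grounded rows are used.
#' @param scorer Entailment backend.
#' @return A one-row `AbstractMention` tibble (`target`, `trigger_surface`,
#'   `trigger_start`, `trigger_end`, `answer_text`/`answer_start`/
#'   `answer_end` all `NA`, `score`) or `NULL` when neither target fires.
#' @export
classify_diagnosis_status <- function(sentence, entity, templates, scorer) {
  if (!entity$concept_type[[1]] %in% c("DI", "SY")) {
    abort_pl(sprintf(
      "diagnosis status is defined over DI/SY mentions, got %s",
      entity$concept_type[[1]]), class = "patientlens_contract_error")
  }
  grounded <- templates[templates$target %in% pl_grounded_targets, ,
                        drop = FALSE]
  best <- list()
  for (target in unique(grounded$target)) {
    rows <- grounded[grounded$target == target, , drop = FALSE]
    scores <- vapply(seq_len(nrow(rows)), function(i) {
      hyp <- stringr::str_replace(rows$pattern[[i]],
                                  stringr::fixed("{entity}"),
                                  entity$surface[[1]])
      score_entailment(sentence$text[[1]], hyp, scorer)
    }, numeric(1))
    if (max(scores) > rows$threshold[[1]]) {
      best[[target]] <- max(scores)
    }
  }
  if (length(best) == 0) return(NULL)
  target <- if ("MISDIAGNOSIS" %in% names(best)) "MISDIAGNOSIS" else
    names(best)[[1]]
  tibble::tibble(
    target = target,
    trigger_surface = entity$surface[[1]],
    trigger_start = entity$start[[1]], trigger_end = entity$end[[1]],
    answer_text = NA_character_, answer_start = NA_integer_,
    answer_end = NA_integer_,
    score = best[[target]]
  )
}

#' Extract all abstract mentions of one sentence
#'
#' Runs the full cascade: every ungrounded target is screened and, on a
#' pass, sent to question answering (by default a mention without an
#' answer span is suppressed); every disease/symptom mention is probed for
#' diagnosis/misdiagnosis status.  A sentence that fails screening is
#' never shown to the answerer.
#'
#' @param sentence One-row sentences tibble (or list with `text`).
#' @param entity_mentions `EntityMention` tibble for the sentence.
#' @param templates Template bank.
#' @param scorer Entailment backend.
#' @param answerer Question-answering backend.
#' @param require_answer Suppress ungrounded mentions without an answer
#'   span (default `TRUE`).
#' @return An `AbstractMention` tibble; every row carries
#'   `score > threshold` of its template.
#' @export
extract_abstract_mentions <- function(sentence, entity_mentions, templates,
                                      scorer, answerer,
                                      require_answer = TRUE) {
  out <- list()
  ungrounded <- templates[!templates$target %in% pl_grounded_targets, ,
                          drop = FALSE]
  for (target in unique(ungrounded$target)) {
    rows <- ungrounded[ungrounded$target == target, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      tpl <- rows[i, , drop = FALSE]
      sc <- screen_sentence(sentence, tpl, scorer)
      if (!sc$pass) next
      ans <- extract_target_span(sentence, tpl, answerer)
      if (is.null(ans) && require_answer) next
      out[[length(out) + 1L]] <- tibble::tibble(
        target = target,
        trigger_surface = NA_character_, trigger_start = NA_integer_,
        trigger_end = NA_integer_,
        answer_text = if (is.null(ans)) NA_character_ else ans$text,
        answer_start = if (is.null(ans)) NA_integer_ else ans$start,
        answer_end = if (is.null(ans)) NA_integer_ else ans$end,
        score = sc$score
      )
      break  # one mention per ungrounded target
    }
  }
  di_sy <- entity_mentions[entity_mentions$concept_type %in% c("DI", "SY"), ,
                           drop = FALSE]
  for (i in seq_len(nrow(di_sy))) {
    hit <- classify_diagnosis_status(sentence, di_sy[i, , drop = FALSE],
                                     templates, scorer)
    if (!is.null(hit)) out[[length(out) + 1L]] <- hit
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(
      target = character(), trigger_surface = character(),
      trigger_start = integer(), trigger_end = integer(),
      answer_text = character(), answer_start = integer(),
      answer_end = integer(), score = numeric())
  }
  res
}
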
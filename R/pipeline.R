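# End-to-end orchestration: ingest -> segment -> interest-group
# classification -> lexicon NER -> time NER -> abstract IE -> relation
# extraction, plus the downstream summaries (co-occurrence tables, onset
# day records).  Analytics consume the serialized result and never
# re-invoke backends, so a run can be archived and re-analyzed
# reproducibly.

#' Assemble a pipeline configuration
#'
#' @param lexicon A [concept_lexicon()]; defaults to the packaged fixture
#'   lexicon.
#' @param templates Abstract-entity template bank.
#' @param schema Relation schema.
#' @param backends List with `entailment`, `qa`, `embedding`: backend
#'   objects or names resolvable by [resolve_backend()] (e.g.
#'   `"reference"`).
#' @param classifier Optional trained [train_interest_classifier()] model;
#'   without one, sentence group labels are `NA`.
#' @param annotator Token annotator for the matcher.
#' @param time_extractor Time span tagger.
#' @param disease_synonyms Normalized surfaces treated as the focus
#'   disease in analytics (defaults to the idiopathic-pulmonary-fibrosis
#'   keyword set).
#' @param seed Integer seed recorded in provenance.
#' @param dedupe,pseudonymize,lang_filter Ingestion switches: drop
#'   duplicated posts, replace direct identifiers, keep only posts whose
#'   `lang` equals the filter (`NULL` disables).
#' @param keep_norel Keep no-relation pairs in the relation table.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(lexicon = NULL,
                            templates = default_template_bank(),
                            schema = default_relation_schema(),
                            backends = list(entailment = "reference",
                                            qa = "reference",
                                            embedding = "reference"),
                            classifier = NULL,
                            annotator = reference_annotator(),
                            time_extractor = reference_time_extractor(),
                            disease_synonyms = c(
                              "idiopathic pulmonary fibrosis", "ipf",
                              "pulmonary fibrosis",
                              "idiopathic lung fibrosis"),
                            seed = 1L,
                            dedupe = TRUE, pseudonymize = FALSE,
                            lang_filter = "en", keep_norel = FALSE) {
  if (is.null(lexicon)) {
    lexicon <- read_lexicon(patientlens_example("lexicon/terms.tsv"))
  }
  backends$entailment <- resolve_backend("entailment", backends$entailment)
  backends$qa <- resolve_backend("qa", backends$qa)
  backends$embedding <- resolve_backend("embedding", backends$embedding)
  structure(list(
    lexicon = lexicon, templates = templates,
    schema = validate_relation_schema(schema), backends = backends,
    classifier = classifier, annotator = annotator,
    time_extractor = time_extractor,
    disease_synonyms = normalize_term(disease_synonyms),
    seed = as.integer(seed), dedupe = dedupe,
    pseudonymize = pseudonymize, lang_filter = lang_filter,
    keep_norel = keep_norel), class = "pipeline_config")
}

#' Run the full pipeline over a corpus
#'
#' Stages run in a fixed order; the failure of one sentence is logged and
#' never aborts the corpus.  The result is deterministic given the
#' configuration, seed and backends.
#'
#' @param posts A posts tibble (see [read_posts()]).
#' @param config A [pipeline_config()].
#' @return A `patientlens_result` list: `posts`, `sentences`, `groups`,
#'   `entities`, `times`, `abstract`, `relations` (all tibbles keyed by
#'   `post_id` + `index`), `log` (character) and `provenance` (config
#'   hash, seed, backend names).
#' @export
run_pipeline <- function(posts, config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(msg) log[[length(log) + 1L]] <<- msg

  if (!is.null(config$lang_filter) && "lang" %in% names(posts)) {
    posts <- posts[posts$lang == config$lang_filter, , drop = FALSE]
  }
  if (config$dedupe) posts <- deduplicate_posts(posts)
  if (config$pseudonymize) {
    for (i in seq_len(nrow(posts))) {
      posts$text[[i]] <- pseudonymize(posts$text[[i]],
                                      seed = config$seed)$text
    }
  }
  sentences <- segment_posts(posts)

  groups <- tibble::tibble(post_id = sentences$post_id,
                           index = sentences$index,
                           label = NA_character_)
  if (!is.null(config$classifier) && nrow(sentences) > 0) {
    pred <- predict_interest_group(sentences$text, config$classifier)
    groups$label <- pred$label
  }

  overlap <- disease_symptom_overlap_terms(config$lexicon)
  entities <- list(); times <- list(); abstract <- list()
  relations <- list()
  capability_notes <- character(0)
  for (i in seq_len(nrow(sentences))) {
    sent <- sentences[i, , drop = FALSE]
    key <- tibble::tibble(post_id = sent$post_id, index = sent$index)
    res <- tryCatch({
      withCallingHandlers({
        ents <- match_concepts(sent, config$lexicon, config$annotator)
        ents <- resolve_disease_symptom_overlap(ents, overlap)
        tms <- extract_time_mentions(sent, config$time_extractor)
        abst <- extract_abstract_mentions(
          sent, ents, config$templates,
          config$backends$entailment, config$backends$qa)
        mention_union <- dplyr::bind_rows(
          if (nrow(ents)) tibble::tibble(
            type = ents$concept_type, surface = ents$surface,
            start = ents$start, end = ents$end),
          if (nrow(tms)) tibble::tibble(
            type = tms$time_class, surface = tms$surface,
            start = tms$start, end = tms$end))
        rels <- extract_relations(sent, mention_union, config$schema,
                                  config$backends$entailment,
                                  keep_norel = config$keep_norel)
        list(ents = ents, tms = tms, abst = abst, rels = rels)
      }, warning = function(w) {
        if (inherits(w, "patientlens_capability_warning")) {
          capability_notes <<- unique(c(capability_notes,
                                        conditionMessage(w)))
          invokeRestart("muffleWarning")
        }
      })
    }, error = function(e) {
      note(sprintf("sentence %s#%d failed: %s", sent$post_id, sent$index,
                   conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    if (nrow(res$ents)) {
      entities[[length(entities) + 1L]] <-
        dplyr::bind_cols(key[rep(1, nrow(res$ents)), ], res$ents)
    }
    if (nrow(res$tms)) {
      times[[length(times) + 1L]] <-
        dplyr::bind_cols(key[rep(1, nrow(res$tms)), ], res$tms)
    }
    if (nrow(res$abst)) {
      abstract[[length(abstract) + 1L]] <-
        dplyr::bind_cols(key[rep(1, nrow(res$abst)), ], res$abst)
    }
    if (nrow(res$rels)) {
      relations[[length(relations) + 1L]] <-
        dplyr::bind_cols(key[rep(1, nrow(res$rels)), ], res$rels)
    }
  }
  log <- c(log, capability_notes)

  bind0 <- function(lst, proto) {
    if (length(lst)) dplyr::bind_rows(lst) else proto
  }
  key_proto <- tibble::tibble(post_id = character(), index = integer())
  structure(list(
    posts = posts, sentences = sentences, groups = groups,
    entities = bind0(entities, dplyr::bind_cols(key_proto,
                                                new_mention_tbl())),
    times = bind0(times, dplyr::mutate(
      key_proto, time_class = character(), surface = character(),
      start = integer(), end = integer())),
    abstract = bind0(abstract, dplyr::mutate(
      key_proto, target = character(), trigger_surface = character(),
      trigger_start = integer(), trigger_end = integer(),
      answer_text = character(), answer_start = integer(),
      answer_end = integer(), score = numeric())),
    relations = bind0(relations, dplyr::mutate(
      key_proto, arg1_type = character(), arg1_surface = character(),
      arg1_start = integer(), arg1_end = integer(),
      arg2_type = character(), arg2_surface = character(),
      arg2_start = integer(), arg2_end = integer(),
      relation = character(), direction = character(),
      score = numeric())),
    log = log,
    provenance = list(
      seed = config$seed,
      backends = vapply(config$backends, function(b) b$name, character(1)),
      threshold = config$schema$threshold,
      config_hash = rlang::hash(list(
        seed = config$seed,
        backends = vapply(config$backends, function(b) b$name,
                          character(1)),
        threshold = config$schema$threshold,
        dedupe = config$dedupe, pseudonymize = config$pseudonymize)))),
    class = "patientlens_result")
}

#' @export
print.patientlens_result <- function(x, ...) {
  cat(sprintf(
    "<patientlens_result> %d posts, %d sentences | %d entities, %d times, %d abstract, %d relations\n",
    nrow(x$posts), nrow(x$sentences), nrow(x$entities), nrow(x$times),
    nrow(x$abstract), nrow(x$relations)))
  if (length(x$log)) cat(sprintf("log: %d message(s)\n", length(x$log)))
  invisible(x)
}

#' Sentence-level co-occurrence table
#'
#' Counts sentences containing at least one target-term mention (the
#' focus disease or its synonyms) together with at least one mention of
#' the filtered concept type -- a first, deliberately relation-free look
#' at challenges (symptoms) or support (treatments, drugs): mere
#' co-occurrence carries no relation claim, so rows carry counts only.
#'
#' @param result A `patientlens_result`.
#' @param target_terms Surfaces counted as the target (normalized);
#'   defaults to the configured disease synonyms recorded at run time is
#'   not available here, so pass the same list.
#' @param concept_type Concept type to tabulate (`"SY"`, `"TR"`, `"DR"`,
#'   `"DI"`).
#' @return Tibble `surface`, `concept_type`, `n_sentences`, ranked by
#'   descending count, ties alphabetical.
#' @export
cooccurrence_table <- function(result, target_terms, concept_type) {
  ents <- result$entities
  if (nrow(ents) == 0) {
    return(tibble::tibble(surface = character(),
                          concept_type = character(),
                          n_sentences = integer()))
  }
  targets <- normalize_term(target_terms)
  ents$norm <- normalize_term(ents$surface)
  ents$sent_key <- paste(ents$post_id, ents$index)
  target_sents <- unique(ents$sent_key[ents$norm %in% targets])
  hits <- ents[ents$sent_key %in% target_sents &
                 ents$concept_type == concept_type &
                 !(ents$norm %in% targets), , drop = FALSE]
  if (nrow(hits) == 0) {
    return(tibble::tibble(surface = character(),
                          concept_type = character(),
                          n_sentences = integer()))
  }
  counts <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(hits, .data$norm, .data$sent_key),
                    surface = .data$norm),
    n_sentences = dplyr::n(), .groups = "drop")
  counts$concept_type <- concept_type
  counts <- counts[order(-counts$n_sentences, counts$surface), ]
  counts[, c("surface", "concept_type", "n_sentences")]
}

#' Onset-day records for the focus disease
#'
#' For every sentence that reports the onset of the focus disease --
#' either through an is-time-of relation attached to a target-disease
#' mention, or through a detected diagnosis of the target disease
#' co-occurring with exactly one resolvable past-pointing time expression
#' -- resolves the time expression against the post's publication date
#' and records the elapsed days, alongside the sentence's interest group.
#' Unresolvable expressions are skipped.
#'
#' @param result A `patientlens_result`.
#' @param disease_synonyms Normalized surfaces of the focus disease.
#' @return Tibble `post_id`, `index`, `group`, `text`, `abs_days`, `via`
#'   (`"ito"` or `"diagnosis"`).
#' @export
compute_onset_days <- function(result,
                               disease_synonyms = c(
                                 "idiopathic pulmonary fibrosis", "ipf",
                                 "pulmonary fibrosis",
                                 "idiopathic lung fibrosis")) {
  synonyms <- normalize_term(disease_synonyms)
  out <- list()
  pub <- setNames(result$posts$published_at, result$posts$post_id)
  for (i in seq_len(nrow(result$sentences))) {
    sent <- result$sentences[i, , drop = FALSE]
    sel <- function(tbl) tbl[tbl$post_id == sent$post_id &
                               tbl$index == sent$index, , drop = FALSE]
    ents <- sel(result$entities)
    target <- ents[normalize_term(ents$surface) %in% synonyms, ,
                   drop = FALSE]
    if (nrow(target) == 0) next
    tms <- sel(result$times)
    tms <- normalize_time_mentions(tms, pub[[sent$post_id]])
    via <- NULL
    days <- NA_integer_
    rels <- sel(result$relations)
    ito <- rels[rels$relation == "ITO" &
                  normalize_term(rels$arg2_surface) %in% synonyms, ,
                drop = FALSE]
    if (nrow(ito) > 0) {
      hit <- tms[tms$start == ito$arg1_start[[1]] &
                   tms$end == ito$arg1_end[[1]], , drop = FALSE]
      if (nrow(hit) == 1 && hit$resolvable[[1]]) {
        days <- hit$days[[1]]
        via <- "ito"
      }
    }
    if (is.null(via)) {
      abst <- sel(result$abstract)
      diag <- abst[abst$target == "DIAGNOSIS" &
                     !is.na(abst$trigger_surface) &
                     normalize_term(abst$trigger_surface) %in% synonyms, ,
                   drop = FALSE]
      resolvable <- tms[tms$resolvable, , drop = FALSE]
      if (nrow(diag) > 0 && nrow(resolvable) == 1) {
        days <- resolvable$days[[1]]
        via <- "diagnosis"
      }
    }
    if (is.null(via)) next
    grp <- sel(result$groups)
    out[[length(out) + 1L]] <- tibble::tibble(
      post_id = sent$post_id, index = sent$index,
      group = if (nrow(grp)) grp$label[[1]] else NA_character_,
      text = sent$text, abs_days = as.integer(days), via = via)
  }
  if (length(out) == 0) {
    return(tibble::tibble(post_id = character(), index = integer(),
                          group = character(), text = character(),
                          abs_days = integer(), via = character()))
  }
  dplyr::bind_rows(out)
}

#' Serialize a pipeline result to a directory of JSONL/CSV files
#'
#' @param result A `patientlens_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_posts(result$posts, file.path(dir, "posts.jsonl"))
  write_sentences(result$sentences, file.path(dir, "sentences.jsonl"))
  for (name in c("groups", "entities", "times", "abstract", "relations")) {
    utils::write.csv(result[[name]],
                     file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  writeLines(jsonlite::toJSON(result$provenance, auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
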
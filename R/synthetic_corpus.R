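# Gold-annotated synthetic corpora.  Real annotated patient-listening
# corpora are proprietary, so the pipeline's correctness surface is a
# generator that plants interest-group labels, entity/time mentions (with
# exact offsets, by template-slot construction), relation triples and
# abstract targets -- plus oracle backends that are consistent with the
# plants by construction.  The oracle path tests pipeline logic, not model
# quality.

#' Build a generation configuration
#'
#' Defaults describe the emulated study conditions: the interest-group
#' mix follows the annotated-corpus label distribution (PA 230, CG 144,
#' PAA 104, SC 132, O 713 of 1323 sentences), and relation/abstract
#' planting rates echo the relative frequencies of the relation inventory
#' (associative and is-used-for links common, ameliorates/exacerbates
#' rare), with the remainder of each group's sentences relation-free to
#' exercise no-relation behaviour and screening rejection.
#'
#' @param n_posts Number of posts.
#' @param seed Mandatory integer seed; generation is deterministic under
#'   it.
#' @param group_dist Named distribution over `PA, CG, PAA, SC, O`; must
#'   sum to 1.  Realized proportions are quota-allocated, so they match
#'   the target within rounding.
#' @param relation_rates Per-sentence planting probability of each
#'   relation payload for groups that support it.
#' @param abstract_rates Same for the abstract targets.
#' @param sentences_per_post Candidate sentence counts per post (sampled
#'   uniformly).
#' @return A `generation_config` list.
#' @export
generation_config <- function(n_posts,
                              seed,
                              group_dist = c(PA = 230, CG = 144, PAA = 104,
                                             SC = 132, O = 713) / 1323,
                              relation_rates = c(AM = 0.04, CR = 0.10,
                                                 DG = 0.08, EX = 0.03,
                                                 IAW = 0.12, ITO = 0.13,
                                                 IUF = 0.16),
                              abstract_rates = c(NEED = 0.06,
                                                 SUPPORT = 0.45,
                                                 DIAGNOSIS = 0.10,
                                                 MISDIAGNOSIS = 0.03),
                              sentences_per_post = 1:4) {
  if (missing(seed)) {
    abort_pl("generation_config requires a seed",
             class = "patientlens_config_error")
  }
  if (abs(sum(group_dist) - 1) > 1e-9 || any(group_dist < 0)) {
    abort_pl("group_dist must be a distribution summing to 1",
             class = "patientlens_config_error")
  }
  if (!setequal(names(group_dist), interest_group_labels())) {
    abort_pl("group_dist must cover PA, CG, PAA, SC, O",
             class = "patientlens_config_error")
  }
  for (grp in c("PA", "CG")) {
    load <- sum(relation_rates) + sum(abstract_rates[c(
      "NEED", "DIAGNOSIS", "MISDIAGNOSIS")])
    if (load > 1) {
      abort_pl("relation + abstract rates exceed 1 for patient/caregiver",
               class = "patientlens_config_error")
    }
  }
  structure(list(
    n_posts = as.integer(n_posts), seed = as.integer(seed),
    group_dist = group_dist, relation_rates = relation_rates,
    abstract_rates = abstract_rates,
    sentences_per_post = sentences_per_post),
    class = "generation_config")
}

# time expressions the generator plants, with their gold day offsets
pl_time_inventory <- tibble::tibble(
  surface = c("2 years ago", "two weeks ago", "last year", "3 months ago",
              "yesterday", "six weeks ago", "last month"),
  time_class = "DT",
  days = c(730L, 14L, 365L, 90L, 1L, 42L, 30L)
)

pl_supporters <- c("local volunteers", "a regional charity",
                   "community donors")

# payload templates; slots {e1}/{e2} are lexicon entities, {t1} a time
# expression, {x1} a free phrase.  rel = planted relation (a1/a2 name the
# head/tail slots); abs = planted abstract target.
payload_bank <- function() {
  rec <- function(kind, group, template, slots = c(), rel = NULL,
                  abs = NULL) {
    list(kind = kind, group = group, template = template, slots = slots,
         rel = rel, abs = abs)
  }
  list(
    rec("CR", "PA", "My {e1} causes {e2}.", c(e1 = "DI", e2 = "SY"),
        rel = list(code = "CR", a1 = "e1", a2 = "e2")),
    rec("CR", "CG", "Her {e1} causes {e2}.", c(e1 = "DI", e2 = "SY"),
        rel = list(code = "CR", a1 = "e1", a2 = "e2")),
    rec("CR", "SC", "Researchers report that {e1} often causes {e2}.",
        c(e1 = "DI", e2 = "SY"), rel = list(code = "CR", a1 = "e1",
                                            a2 = "e2")),
    rec("EX", "PA", "My {e1} made my {e2} worse.", c(e1 = "DI", e2 = "SY"),
        rel = list(code = "EX", a1 = "e1", a2 = "e2")),
    rec("EX", "CG", "His {e1} made his {e2} worse.", c(e1 = "DI", e2 = "SY"),
        rel = list(code = "EX", a1 = "e1", a2 = "e2")),
    rec("AM", "PA", "Taking {e1} helped reduce my {e2}.",
        c(e1 = "DR", e2 = "SY"), rel = list(code = "AM", a1 = "e1",
                                            a2 = "e2")),
    rec("AM", "CG", "Taking {e1} helped decrease her {e2}.",
        c(e1 = "DR", e2 = "SY"), rel = list(code = "AM", a1 = "e1",
                                            a2 = "e2")),
    rec("AM", "SC", "The trial found that {e1} reduced {e2}.",
        c(e1 = "DR", e2 = "SY"), rel = list(code = "AM", a1 = "e1",
                                            a2 = "e2")),
    rec("IUF", "PA", "I take {e1} for my {e2}.", c(e1 = "DR", e2 = "DI"),
        rel = list(code = "IUF", a1 = "e1", a2 = "e2")),
    rec("IUF", "CG", "My father takes {e1} for his {e2}.",
        c(e1 = "DR", e2 = "DI"), rel = list(code = "IUF", a1 = "e1",
                                            a2 = "e2")),
    rec("IUF", "SC", "A new study reports that {e1} is used for {e2}.",
        c(e1 = "DR", e2 = "DI"), rel = list(code = "IUF", a1 = "e1",
                                            a2 = "e2")),
    rec("IAW", "PA", "My {e1} is linked to my {e2}.",
        c(e1 = "SY", e2 = "DI"), rel = list(code = "IAW", a1 = "e1",
                                            a2 = "e2")),
    rec("IAW", "CG", "Her {e1} is linked to her {e2}.",
        c(e1 = "SY", e2 = "DI"), rel = list(code = "IAW", a1 = "e1",
                                            a2 = "e2")),
    rec("IAW", "SC", "A recent paper says {e1} is associated with {e2}.",
        c(e1 = "SY", e2 = "DI"), rel = list(code = "IAW", a1 = "e1",
                                            a2 = "e2")),
    rec("DG", "PA", "My {e1} appointment detected the {e2}.",
        c(e1 = "TR", e2 = "DI"), rel = list(code = "DG", a1 = "e1",
                                            a2 = "e2")),
    rec("DG", "CG", "Her {e1} appointment detected the {e2}.",
        c(e1 = "TR", e2 = "DI"), rel = list(code = "DG", a1 = "e1",
                                            a2 = "e2")),
    rec("ITO", "PA", "My {e1} started {t1}.", c(e1 = "DI", t1 = "TIME"),
        rel = list(code = "ITO", a1 = "t1", a2 = "e1")),
    rec("ITO", "CG", "Her {e1} started {t1}.", c(e1 = "DI", t1 = "TIME"),
        rel = list(code = "ITO", a1 = "t1", a2 = "e1")),
    rec("DIAGNOSIS", "PA", "I was diagnosed with {e1} {t1}.",
        c(e1 = "DI", t1 = "TIME"), abs = list(target = "DIAGNOSIS",
                                              trigger = "e1")),
    rec("DIAGNOSIS", "CG", "My mother was diagnosed with {e1} {t1}.",
        c(e1 = "DI", t1 = "TIME"), abs = list(target = "DIAGNOSIS",
                                              trigger = "e1")),
    rec("MISDIAGNOSIS", "PA", "My {e1} was missed by the first physician.",
        c(e1 = "DI"), abs = list(target = "MISDIAGNOSIS", trigger = "e1")),
    rec("MISDIAGNOSIS", "CG", "Her {e1} was missed by the local clinic.",
        c(e1 = "DI"), abs = list(target = "MISDIAGNOSIS", trigger = "e1")),
    rec("NEED", "PA", "I am in need of {e1}.", c(e1 = "TR"),
        abs = list(target = "NEED", answer = "e1",
                   question = "What is needed?")),
    rec("NEED", "CG", "My mother is in need of {e1}.", c(e1 = "TR"),
        abs = list(target = "NEED", answer = "e1",
                   question = "What is needed?")),
    rec("SUPPORT", "PAA", "Our association receives support from {x1}.",
        c(x1 = "SUPPORTER"),
        abs = list(target = "SUPPORT", answer = "x1",
                   question = "Who provides support?"))
  )
}

plain_bank <- function() {
  list(
    PA = c("As a patient I try to stay hopeful.",
           "Living with this illness changed my routine.",
           "I keep notes about how I feel."),
    CG = c("Caring for my husband takes most of my energy.",
           "My family adjusted the house for easier access.",
           "I drive my mother to her appointments."),
    PAA = c("Join our walk to raise awareness this autumn.",
            "Our members meet online to share stories.",
            "The association published a new family guide."),
    SC = c("The conference highlighted several new findings.",
           "Researchers presented an updated cohort analysis.",
           "The journal issued a call for abstracts."),
    O = c("But not this.",
          "That is not the situation we are dealing with.",
          "Thanks for sharing this with everyone.",
          "I will look into it soon.",
          "We would love to relocate, but it is not feasible.")
  )
}

# fill a {slot} template, recording 0-based half-open slot spans
fill_template <- function(template, values) {
  text <- ""
  spans <- list()
  rest <- template
  repeat {
    m <- stringr::str_locate(rest, "\\{[a-z0-9]+\\}")
    if (is.na(m[1, 1])) {
      text <- paste0(text, rest)
      break
    }
    text <- paste0(text, substr(rest, 1, m[1, 1] - 1))
    key <- substr(rest, m[1, 1] + 1, m[1, 2] - 1)
    val <- values[[key]]
    spans[[key]] <- c(start = nchar(text), end = nchar(text) + nchar(val))
    text <- paste0(text, val)
    rest <- substr(rest, m[1, 2] + 1, nchar(rest))
  }
  list(text = text, spans = spans)
}

#' Generate a gold-annotated synthetic corpus
#'
#' Template-slot generation: each sentence is drawn from a group-specific
#' phrasing template whose entity slots are filled from the packaged
#' fixture lexicon and whose time slots come from the
#' normalization-supported expression inventory, so every gold span is
#' exact by construction and the lexicon matcher reproduces every planted
#' primary-entity mention.
#'
#' @param config A [generation_config()].
#' @param lexicon Concept lexicon the slots are filled from; defaults to
#'   the packaged fixture lexicon.
#' @return A list with `posts` (corpus-format tibble), `gold` (tibbles
#'   `groups`, `entities`, `times`, `relations`, `abstract`, all keyed by
#'   `post_id` + `index` and carrying the sentence `text`), `lexicon` and
#'   `config`.
#' @export
generate_corpus <- function(config, lexicon = NULL) {
  stopifnot(inherits(config, "generation_config"))
  if (is.null(lexicon)) {
    lexicon <- read_lexicon(patientlens_example("lexicon/terms.tsv"))
  }
  entries <- lexicon$entries
  overlap <- disease_symptom_overlap_terms(lexicon)
  pools <- list(
    DI = entries[entries$concept_type == "DI" &
                   !(entries$term_norm %in% overlap), , drop = FALSE],
    SY = entries[entries$concept_type == "SY", , drop = FALSE],
    DR = entries[entries$concept_type == "DR", , drop = FALSE],
    # blacklisted entries are already excluded at lexicon construction
    TR = entries[entries$concept_type == "TR", , drop = FALSE]
  )
  bank <- payload_bank()
  plains <- plain_bank()

  withr::with_seed(config$seed, {
    n_sent <- sample(config$sentences_per_post, config$n_posts,
                     replace = TRUE)
    total <- sum(n_sent)
    groups <- quota_labels(config$group_dist, total)
    dates <- as.Date("2021-10-01") +
      sample.int(760, config$n_posts, replace = TRUE) - 1L

    g_groups <- list(); g_entities <- list(); g_times <- list()
    g_relations <- list(); g_abstract <- list()
    posts <- list()
    seen_posts <- character(0)
    cursor <- 0L
    for (p in seq_len(config$n_posts)) {
      post_id <- sprintf("post%05d", p)
      for (attempt in 1:25) {
        sents <- lapply(seq_len(n_sent[[p]]), function(s) {
          gen_sentence(groups[[cursor + s]], config, bank, plains, pools)
        })
        text <- paste(vapply(sents, function(x) x$text, character(1)),
                      collapse = " ")
        if (!text %in% seen_posts) break
      }
      seen_posts <- c(seen_posts, text)
      for (s in seq_along(sents)) {
        idx <- s - 1L
        sent <- sents[[s]]
        key <- tibble::tibble(post_id = post_id, index = idx,
                              text = sent$text)
        g_groups[[length(g_groups) + 1L]] <-
          dplyr::mutate(key, label = sent$group)
        if (!is.null(sent$entities) && nrow(sent$entities)) {
          g_entities[[length(g_entities) + 1L]] <-
            dplyr::bind_cols(key[rep(1, nrow(sent$entities)), ],
                             sent$entities)
        }
        if (!is.null(sent$times) && nrow(sent$times)) {
          g_times[[length(g_times) + 1L]] <-
            dplyr::bind_cols(key[rep(1, nrow(sent$times)), ], sent$times)
        }
        if (!is.null(sent$relation)) {
          g_relations[[length(g_relations) + 1L]] <-
            dplyr::bind_cols(key, sent$relation)
        }
        if (!is.null(sent$abstract)) {
          g_abstract[[length(g_abstract) + 1L]] <-
            dplyr::bind_cols(key, sent$abstract)
        }
      }
      cursor <- cursor + n_sent[[p]]
      posts[[p]] <- tibble::tibble(
        post_id = post_id, source = "synthetic-forum",
        url = sprintf("https://forum.example/%s", post_id),
        published_at = dates[[p]], text = text, lang = "en")
    }
  })

  empty0 <- function(x, proto) if (length(x)) dplyr::bind_rows(x) else proto
  key_proto <- tibble::tibble(post_id = character(), index = integer(),
                              text = character())
  list(
    posts = if (length(posts)) dplyr::bind_rows(posts) else
      empty_posts()[, -7],
    gold = list(
      groups = empty0(g_groups, dplyr::mutate(key_proto,
                                              label = character())),
      entities = empty0(g_entities, dplyr::bind_cols(key_proto,
                                                     new_mention_tbl())),
      times = empty0(g_times, dplyr::mutate(
        key_proto, time_class = character(), surface = character(),
        start = integer(), end = integer(), days = integer())),
      relations = empty0(g_relations, dplyr::mutate(
        key_proto, relation = character(), direction = character(),
        arg1_type = character(), arg1_surface = character(),
        arg1_start = integer(), arg1_end = integer(),
        arg2_type = character(), arg2_surface = character(),
        arg2_start = integer(), arg2_end = integer())),
      abstract = empty0(g_abstract, dplyr::mutate(
        key_proto, target = character(), trigger_surface = character(),
        trigger_start = integer(), trigger_end = integer(),
        answer_text = character(), answer_start = integer(),
        answer_end = integer(), question = character()))
    ),
    lexicon = lexicon,
    config = config
  )
}

# largest-remainder quota allocation of group labels, then shuffled
quota_labels <- function(dist, n) {
  counts <- floor(dist * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- dist * n - counts
    bump <- order(-frac)[seq_len(rem)]
    counts[bump] <- counts[bump] + 1
  }
  sample(rep(names(dist), counts))
}

gen_sentence <- function(group, config, bank, plains, pools) {
  kinds <- available_kinds(group)
  rates <- c(config$relation_rates, config$abstract_rates)[kinds]
  p_plain <- 1 - sum(rates)
  kind <- sample(c(kinds, "plain"), 1, prob = c(rates, p_plain))
  if (kind == "plain") {
    return(list(group = group,
                text = sample(plains[[group]], 1),
                entities = NULL, times = NULL, relation = NULL,
                abstract = NULL))
  }
  variants <- Filter(function(r) r$kind == kind && r$group == group, bank)
  rec <- variants[[sample.int(length(variants), 1)]]
  values <- list()
  ent_rows <- list()
  time_row <- NULL
  for (slot in names(rec$slots)) {
    pool <- rec$slots[[slot]]
    if (pool == "TIME") {
      t <- pl_time_inventory[sample.int(nrow(pl_time_inventory), 1), ]
      values[[slot]] <- t$surface
      time_row <- t
    } else if (pool == "SUPPORTER") {
      values[[slot]] <- sample(pl_supporters, 1)
    } else {
      repeat {
        e <- pools[[pool]][sample.int(nrow(pools[[pool]]), 1), ]
        if (!e$term %in% unlist(values)) break
      }
      values[[slot]] <- e$term
      ent_rows[[slot]] <- e
    }
  }
  filled <- fill_template(rec$template, values)
  span_of <- function(slot) filled$spans[[slot]]

  entities <- NULL
  if (length(ent_rows)) {
    entities <- dplyr::bind_rows(lapply(names(ent_rows), function(slot) {
      sp <- span_of(slot)
      tibble::tibble(
        concept_type = ent_rows[[slot]]$concept_type,
        surface = substr0(filled$text, sp[["start"]], sp[["end"]]),
        start = as.integer(sp[["start"]]), end = as.integer(sp[["end"]]),
        canonical_id = ent_rows[[slot]]$canonical_id,
        source = ent_rows[[slot]]$source)
    }))
    entities <- entities[order(entities$start), ]
  }
  times <- NULL
  if (!is.null(time_row)) {
    sp <- span_of(names(rec$slots)[rec$slots == "TIME"][[1]])
    times <- tibble::tibble(
      time_class = time_row$time_class, surface = time_row$surface,
      start = as.integer(sp[["start"]]), end = as.integer(sp[["end"]]),
      days = time_row$days)
  }
  relation <- NULL
  if (!is.null(rec$rel)) {
    arg_tbl <- function(slot) {
      sp <- span_of(slot)
      if (identical(rec$slots[[slot]], "TIME")) {
        list(type = time_row$time_class, surface = time_row$surface,
             start = sp[["start"]], end = sp[["end"]])
      } else {
        list(type = ent_rows[[slot]]$concept_type,
             surface = values[[slot]], start = sp[["start"]],
             end = sp[["end"]])
      }
    }
    a1 <- arg_tbl(rec$rel$a1)
    a2 <- arg_tbl(rec$rel$a2)
    sym <- relation_types()$symmetric[relation_types()$code ==
                                        rec$rel$code]
    if (sym && a1$start > a2$start) { tmp <- a1; a1 <- a2; a2 <- tmp }
    relation <- tibble::tibble(
      relation = rec$rel$code,
      direction = if (sym) "symmetric" else "forward",
      arg1_type = a1$type, arg1_surface = a1$surface,
      arg1_start = as.integer(a1$start), arg1_end = as.integer(a1$end),
      arg2_type = a2$type, arg2_surface = a2$surface,
      arg2_start = as.integer(a2$start), arg2_end = as.integer(a2$end))
  }
  abstract <- NULL
  if (!is.null(rec$abs)) {
    if (!is.null(rec$abs$trigger)) {
      sp <- span_of(rec$abs$trigger)
      abstract <- tibble::tibble(
        target = rec$abs$target,
        trigger_surface = values[[rec$abs$trigger]],
        trigger_start = as.integer(sp[["start"]]),
        trigger_end = as.integer(sp[["end"]]),
        answer_text = NA_character_, answer_start = NA_integer_,
        answer_end = NA_integer_, question = NA_character_)
    } else {
      sp <- span_of(rec$abs$answer)
      abstract <- tibble::tibble(
        target = rec$abs$target,
        trigger_surface = NA_character_, trigger_start = NA_integer_,
        trigger_end = NA_integer_,
        answer_text = values[[rec$abs$answer]],
        answer_start = as.integer(sp[["start"]]),
        answer_end = as.integer(sp[["end"]]),
        question = rec$abs$question)
    }
  }
  list(group = group, text = filled$text, entities = entities,
       times = times, relation = relation, abstract = abstract)
}

available_kinds <- function(group) {
  switch(group,
    PA = c("AM", "CR", "DG", "EX", "IAW", "ITO", "IUF",
           "NEED", "DIAGNOSIS", "MISDIAGNOSIS"),
    CG = c("AM", "CR", "DG", "EX", "IAW", "ITO", "IUF",
           "NEED", "DIAGNOSIS", "MISDIAGNOSIS"),
    SC = c("AM", "CR", "IAW", "IUF"),
    PAA = c("SUPPORT"),
    O = character(0)
  )
}

#' Oracle backends consistent with a synthetic corpus
#'
#' The entailment oracle returns exactly 1 for hypotheses instantiated
#' from planted relations and abstract targets in their true direction and
#' 0 for everything else; the answering oracle returns the planted answer
#' span for the planted question; the embedding oracle returns
#' label-separable vectors (one-hot by the sentence's planted interest
#' group).  With these backends the pipeline must recover the gold
#' annotations exactly -- any deviation is a pipeline defect, not model
#' noise.
#'
#' @param corpus Output of [generate_corpus()].
#' @param schema Relation schema used to instantiate the true relation
#'   hypotheses; must match the schema the pipeline runs with.
#' @param templates Template bank for the abstract-entity hypotheses.
#' @return List with entailment, qa and embedding backends.
#' @export
oracle_backends <- function(corpus, schema = default_relation_schema(),
                            templates = default_template_bank()) {
  gold <- corpus$gold
  sep <- "␞"
  truths <- new.env(parent = emptyenv())
  mark <- function(premise, hypothesis) {
    assign(paste0(premise, sep, hypothesis), TRUE, envir = truths)
  }
  rel <- gold$relations
  for (i in seq_len(nrow(rel))) {
    for (pattern in schema$templates[[rel$relation[[i]]]]) {
      mark(rel$text[[i]], instantiate_template(
        pattern, rel$arg1_surface[[i]], rel$arg2_surface[[i]]))
    }
  }
  abs_tbl <- gold$abstract
  for (i in seq_len(nrow(abs_tbl))) {
    target <- abs_tbl$target[[i]]
    rows <- templates[templates$target == target, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      hyp <- rows$pattern[[j]]
      if (target %in% pl_grounded_targets) {
        hyp <- stringr::str_replace(hyp, stringr::fixed("{entity}"),
                                    abs_tbl$trigger_surface[[i]])
      }
      mark(abs_tbl$text[[i]], hyp)
    }
  }
  entailment <- entailment_backend(function(premise, hypothesis) {
    if (exists(paste0(premise, sep, hypothesis), envir = truths)) 1 else 0
  }, name = "oracle")

  answers <- new.env(parent = emptyenv())
  qa_rows <- abs_tbl[!is.na(abs_tbl$question), , drop = FALSE]
  for (i in seq_len(nrow(qa_rows))) {
    assign(paste0(qa_rows$question[[i]], sep, qa_rows$text[[i]]),
           list(text = qa_rows$answer_text[[i]],
                start = qa_rows$answer_start[[i]],
                end = qa_rows$answer_end[[i]], confidence = 1),
           envir = answers)
  }
  qa <- qa_backend(function(question, context) {
    key <- paste0(question, sep, context)
    if (exists(key, envir = answers)) get(key, envir = answers) else NULL
  }, name = "oracle")

  lab_idx <- setNames(seq_along(interest_group_labels()),
                      interest_group_labels())
  text2lab <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(gold$groups))) {
    assign(gold$groups$text[[i]], gold$groups$label[[i]], envir = text2lab)
  }
  dim_ <- length(lab_idx) + 1L
  embedding <- embedding_backend(function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dim_)
    for (i in seq_along(texts)) {
      if (exists(texts[[i]], envir = text2lab)) {
        out[i, lab_idx[[get(texts[[i]], envir = text2lab)]]] <- 1
      } else {
        out[i, dim_] <- 1
      }
    }
    out
  }, dim = dim_, name = "oracle")

  list(entailment = entailment, qa = qa, embedding = embedding)
}
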
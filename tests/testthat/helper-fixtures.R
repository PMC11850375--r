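# Shared fixtures and independent oracles for the test suite.

new_mention_tbl_ <- function() patientlens:::new_mention_tbl()

tiny_lexicon <- function(blacklist = list()) {
  concept_lexicon(tibble::tibble(
    term = c("idiopathic pulmonary fibrosis", "IPF", "pulmonary fibrosis",
             "emphysema", "cough",
             "cough", "fatigue", "clubbing", "shortness of breath",
             "pirfenidone", "nintedanib",
             "lung transplant", "oxygen therapy", "application"),
    concept_type = c(rep("DI", 5), rep("SY", 4), rep("DR", 2),
                     rep("TR", 3)),
    canonical_id = sprintf("ID%02d", 1:14),
    source = c(rep("mesh", 5), rep("symp", 4), rep("dron", 2),
               rep("wikidata", 3))
  ), blacklist = blacklist)
}

packaged_lexicon <- function() {
  read_lexicon(patientlens_example("lexicon/terms.tsv"))
}

write_posts_file <- function(lines, path = withr::local_tempfile(
                               fileext = ".jsonl",
                               .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

post_line <- function(post_id, text, published_at = "2023-01-15",
                      url = "https://x.example/p", source = "forum",
                      lang = "en") {
  jsonlite::toJSON(list(post_id = post_id, source = source, url = url,
                        published_at = published_at, text = text,
                        lang = lang), auto_unbox = TRUE)
}

# ---- independent brute-force matcher oracle ------------------------------
# Scans every token-boundary substring, checks lexicon membership, then
# applies leftmost-longest resolution.  Kept independent of the package's
# scanning matcher: own tokenization, own candidate enumeration.
brute_match_oracle <- function(text, lexicon) {
  m <- gregexpr("[A-Za-z0-9_]+(?:['-][A-Za-z0-9_]+)*", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer(),
                                     concept_type = character(),
                                     surface = character()))
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  entries <- lexicon$entries
  precedence <- c("DR", "TR", "DI", "SY")
  cands <- list()
  for (i in seq_along(starts)) {
    for (j in seq(i, length(starts))) {
      sub <- substr(text, starts[[i]], ends[[j]])
      norm <- gsub("\\s+", " ", trimws(tolower(sub)))
      hit <- entries[entries$term_norm == norm, , drop = FALSE]
      if (nrow(hit) == 0) next
      hit <- hit[order(match(hit$concept_type, precedence)), ]
      cands[[length(cands) + 1L]] <- data.frame(
        start = starts[[i]] - 1L, end = ends[[j]],
        concept_type = hit$concept_type[[1]], surface = sub)
    }
  }
  if (length(cands) == 0) return(data.frame(start = integer(),
                                            end = integer(),
                                            concept_type = character(),
                                            surface = character()))
  cands <- do.call(rbind, cands)
  cands <- cands[order(cands$start, -(cands$end - cands$start)), ]
  keep <- rep(FALSE, nrow(cands))
  last_end <- -1L
  for (k in seq_len(nrow(cands))) {
    if (cands$start[[k]] >= last_end) {
      keep[[k]] <- TRUE
      last_end <- cands$end[[k]]
    }
  }
  cands[keep, , drop = FALSE]
}

mention_key <- function(d) {
  paste(d$start, d$end, d$concept_type, tolower(d$surface), sep = "|")
}

# random fixture sentences mixing lexicon terms and filler words
random_fixture_sentence <- function(lexicon) {
  fillers <- c("she", "takes", "it", "every", "morning", "and", "feels",
               "that", "the", "doctor", "said", "about", "her", "his",
               "new", "plan", "was", "good", "after", "visit")
  terms <- lexicon$entries$term
  n <- sample(3:10, 1)
  pieces <- vapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.35) {
      t <- sample(terms, 1)
      if (stats::runif(1) < 0.3) t <- toupper(t)
      t
    } else {
      sample(fillers, 1)
    }
  }, character(1))
  out <- paste(pieces, collapse = " ")
  substr(out, 1, 200)
}

# ---- independent confusion-matrix metrics oracle -------------------------
oracle_eval_metrics <- function(gold, pred, labels) {
  conf <- matrix(0, nrow = length(labels), ncol = length(labels),
                 dimnames = list(labels, labels))
  for (i in seq_along(gold)) {
    conf[gold[[i]], pred[[i]]] <- conf[gold[[i]], pred[[i]]] + 1
  }
  per <- lapply(labels, function(l) {
    tp <- conf[l, l]
    col_sum <- sum(conf[, l])
    row_sum <- sum(conf[l, ])
    p <- if (col_sum > 0) tp / col_sum else 0
    r <- if (row_sum > 0) tp / row_sum else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p * 100, recall = r * 100, f1 = f * 100,
      support = row_sum)
  })
  per <- do.call(rbind, per)
  rownames(per) <- labels
  supported <- labels[per[, "support"] > 0]
  w <- per[supported, "support"] / sum(per[supported, "support"])
  list(
    per_label = per,
    accuracy = sum(diag(conf)) / sum(conf) * 100,
    macro_f1 = mean(per[supported, "f1"]),
    weighted_f1 = sum(w * per[supported, "f1"]),
    macro_precision = mean(per[supported, "precision"]),
    weighted_precision = sum(w * per[supported, "precision"]),
    macro_recall = mean(per[supported, "recall"]),
    weighted_recall = sum(w * per[supported, "recall"])
  )
}

# oracle-backed pipeline run over a fresh synthetic corpus
oracle_pipeline_run <- function(n_posts = 50, seed = 7) {
  corpus <- generate_corpus(generation_config(n_posts = n_posts,
                                              seed = seed))
  backends <- oracle_backends(corpus)
  model <- train_interest_classifier(
    tibble::tibble(text = corpus$gold$groups$text,
                   label = corpus$gold$groups$label),
    embedder = backends$embedding, seed = seed)
  config <- pipeline_config(backends = backends, classifier = model,
                            seed = seed)
  list(corpus = corpus, config = config,
       result = run_pipeline(corpus$posts, config))
}

relation_key <- function(d) {
  paste(d$post_id, d$index, d$relation, d$direction, d$arg1_surface,
        d$arg1_start, d$arg2_surface, d$arg2_start, sep = "|")
}

entity_key <- function(d) {
  paste(d$post_id, d$index, d$concept_type, d$start, d$end, d$surface,
        sep = "|")
}
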
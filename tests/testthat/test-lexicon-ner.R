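test_that("treatment lexicon compilation = include descendants minus exclude descendants", {
  h <- class_hierarchy(
    tibble::tibble(
      child = c("oxygen_therapy", "spirometry", "medical_test"),
      parent = c("therapy", "medical_test", "medical_procedure")),
    c(oxygen_therapy = "oxygen therapy", spirometry = "spirometry",
      medical_test = "medical test", therapy = "therapy",
      medical_procedure = "medical procedure"))
  out <- compile_treatment_lexicon(h, c("therapy", "medical_procedure"),
                                   c("medical_test"))
  # brute-force reachability oracle on the toy graph
  edges <- list(oxygen_therapy = "therapy", spirometry = "medical_test",
                medical_test = "medical_procedure")
  reaches <- function(node, root) {
    while (!is.null(node)) {
      if (node == root) return(TRUE)
      node <- edges[[node]]
    }
    FALSE
  }
  all_nodes <- c("oxygen_therapy", "spirometry", "medical_test",
                 "therapy", "medical_procedure")
  included <- Filter(function(n) reaches(n, "therapy") ||
                       reaches(n, "medical_procedure"), all_nodes)
  excluded <- Filter(function(n) reaches(n, "medical_test"), all_nodes)
  expect_setequal(out$canonical_id, setdiff(included, excluded))
  expect_true(all(out$concept_type == "TR"))

  # empty exclude set keeps every included descendant
  out_all <- compile_treatment_lexicon(h, c("therapy", "medical_procedure"))
  expect_setequal(out_all$canonical_id, included)

  # a node under both include and exclude roots is excluded
  h2 <- class_hierarchy(
    tibble::tibble(child = c("x", "x"), parent = c("inc", "exc")),
    c(x = "x term", inc = "included root", exc = "excluded root"))
  expect_false("x" %in%
                 compile_treatment_lexicon(h2, "inc", "exc")$canonical_id)

  expect_error(compile_treatment_lexicon(h, "not_a_node"),
               class = "patientlens_config_error")
})

test_that("matcher finds case-insensitive leftmost-longest token-aligned mentions", {
  lex <- tiny_lexicon()
  m <- suppressWarnings(
    match_concepts(list(text = "She takes pirfenidone daily"), lex))
  expect_equal(nrow(m), 1)
  expect_equal(m$concept_type, "DR")
  expect_equal(m$surface, "pirfenidone")

  # leftmost-longest: the full term wins over its embedded sub-term
  m2 <- suppressWarnings(match_concepts(
    list(text = "my Idiopathic Pulmonary Fibrosis got confirmed"), lex))
  expect_equal(m2$surface, "Idiopathic Pulmonary Fibrosis")
  expect_equal(m2$concept_type, "DI")

  # token boundaries: no match inside a longer word
  m3 <- suppressWarnings(match_concepts(
    list(text = "the coughing fits kept coming"), lex))
  expect_equal(nrow(m3), 0)

  expect_equal(nrow(suppressWarnings(match_concepts(
    list(text = "anything"),
    concept_lexicon(tibble::tibble(term = character(),
                                   concept_type = character(),
                                   canonical_id = character(),
                                   source = character()))))), 0)
})

test_that("organization and head-noun filters drop false positives", {
  lex <- tiny_lexicon()
  ann <- make_annotator(
    org_patterns = "Canadian Pulmonary Fibrosis Foundation")
  m <- suppressWarnings(match_concepts(
    list(text = "donated to the Canadian Pulmonary Fibrosis Foundation"),
    lex, ann))
  expect_equal(nrow(m), 0)

  # same sentence without the organization span keeps the DI mention
  m2 <- suppressWarnings(match_concepts(
    list(text = "donated to the Canadian Pulmonary Fibrosis Foundation"),
    lex, reference_annotator()))
  expect_equal(m2$surface, "Pulmonary Fibrosis")

  # head filter: a non-nominal phrase head suppresses the match
  pos <- c(cough = "VERB", patients = "NOUN", often = "ADV", at = "ADP",
           night = "NOUN")
  ann2 <- make_annotator(pos_lexicon = pos)
  m3 <- suppressWarnings(match_concepts(
    list(text = "patients cough at night"), lex, ann2))
  expect_equal(nrow(m3), 0)
  pos["cough"] <- "NOUN"
  m4 <- suppressWarnings(match_concepts(
    list(text = "patients cough at night"),
    lex, make_annotator(pos_lexicon = pos)))
  expect_equal(m4$surface, "cough")
})

test_that("missing annotator capabilities skip filters with a warning", {
  lex <- tiny_lexicon()
  expect_warning(
    expect_warning(
      match_concepts(list(text = "she has a cough"), lex),
      class = "patientlens_capability_warning"),
    class = "patientlens_capability_warning")
})

test_that("blacklisted terms are never matchable and blacklists are monotone", {
  lex <- tiny_lexicon(blacklist = list(wikidata = "application"))
  m <- suppressWarnings(match_concepts(
    list(text = "submit the application today"), lex))
  expect_equal(nrow(m), 0)

  # monotonicity: adding a blacklist term can only remove mentions
  base <- tiny_lexicon()
  more <- tiny_lexicon(blacklist = list(mesh = "emphysema"))
  withr::with_seed(5, {
    for (i in 1:20) {
      text <- random_fixture_sentence(base)
      a <- suppressWarnings(match_concepts(list(text = text), base))
      b <- suppressWarnings(match_concepts(list(text = text), more))
      expect_true(all(mention_key(b) %in% mention_key(a)))
    }
  })
})

test_that("matcher output equals the brute-force substring oracle on random sentences", {
  lex <- tiny_lexicon()
  withr::with_seed(23, {
    for (i in 1:60) {
      text <- random_fixture_sentence(lex)
      got <- suppressWarnings(match_concepts(list(text = text), lex))
      want <- brute_match_oracle(text, lex)
      expect_identical(mention_key(got), mention_key(want))
      # returned mentions never overlap
      if (nrow(got) > 1) {
        g <- got[order(got$start), ]
        expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
      }
    }
  })
})

test_that("disease/symptom overlaps are relabeled as symptoms", {
  lex <- tiny_lexicon()
  overlap <- disease_symptom_overlap_terms(lex)
  expect_equal(overlap, "cough")

  m <- suppressWarnings(match_concepts(
    list(text = "a cough and some fatigue with emphysema"), lex))
  # identical-span precedence put "cough" under DI before resolution
  expect_equal(m$concept_type[m$surface == "cough"], "DI")
  fixed <- resolve_disease_symptom_overlap(m, overlap)
  expect_equal(fixed$concept_type[fixed$surface == "cough"], "SY")
  # everything else untouched
  expect_equal(fixed$concept_type[fixed$surface == "emphysema"], "DI")
  expect_identical(resolve_disease_symptom_overlap(m, character(0)), m)

  # mixed batch: exactly the overlapping rows flip
  batch <- tibble::tibble(
    concept_type = c("DI", "DI", "DI", "SY", "DI"),
    surface = c("cough", "Cough", "emphysema", "fatigue", "IPF"),
    start = c(0L, 10L, 20L, 40L, 50L), end = c(5L, 15L, 29L, 47L, 53L),
    canonical_id = "x", source = "s")
  out <- resolve_disease_symptom_overlap(batch, overlap)
  expect_equal(sum(out$concept_type == "SY"), 3)
  expect_equal(out$concept_type[[5]], "DI")
})
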
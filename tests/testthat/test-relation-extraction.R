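pair_of <- function(t1, s1, t2, s2, starts = c(0L, 30L)) {
  tibble::tibble(type = c(t1, t2), surface = c(s1, s2),
                 start = starts,
                 end = starts + c(nchar(s1), nchar(s2)))
}

test_that("hypothesis generation swaps arguments and prunes by type", {
  schema <- default_relation_schema()
  sent <- list(text = "irrelevant for generation")
  pair <- pair_of("DI", "pulmonary fibrosis", "SY", "clubbing")
  hyps <- generate_hypotheses(sent, pair, schema)
  cr <- hyps[hyps$relation == "CR", ]
  expect_setequal(cr$hypothesis,
                  c("pulmonary fibrosis leads to clubbing",
                    "clubbing leads to pulmonary fibrosis"))
  expect_setequal(cr$direction, c("forward", "reverse"))
  # IAW gets a single symmetric instantiation
  expect_equal(sum(hyps$relation == "IAW"), 1)
  # DG between two non-diagnostic types exists only where admissible
  expect_equal(nrow(hyps[hyps$relation == "DG", ]), 0)

  # a disease cannot cause a point in time: only ITO survives the pruning
  tpair <- pair_of("DI", "idiopathic pulmonary fibrosis", "DT",
                   "yesterday")
  thyps <- generate_hypotheses(sent, tpair, schema)
  expect_equal(nrow(thyps[thyps$relation == "CR", ]), 0)
  ito <- thyps[thyps$relation == "ITO", ]
  expect_equal(ito$hypothesis,
               "yesterday is the time of idiopathic pulmonary fibrosis")
  # no pair, no hypotheses
  expect_equal(nrow(generate_hypotheses(sent, pair[1, ], schema)), 0)
})

test_that("relation selection is a thresholded argmax with fixed tie-breaks", {
  schema <- default_relation_schema()
  scored <- tibble::tibble(
    relation = c("CR", "CR", "IAW"),
    direction = c("forward", "reverse", "symmetric"),
    score = c(0.9, 0.1, 0.6))
  sel <- select_relation(scored, schema)
  expect_equal(sel$relation, "CR")
  expect_equal(sel$direction, "forward")
  expect_equal(sel$score, 0.9)

  # nothing above the threshold -> NOREL (boundary included)
  low <- tibble::tibble(relation = c("CR", "IUF"),
                        direction = c("forward", "forward"),
                        score = c(0.2, 0.15))
  expect_equal(select_relation(low, schema)$relation, "NOREL")
  expect_equal(select_relation(low, schema)$score, 0.2)

  empty <- select_relation(
    tibble::tibble(relation = character(), direction = character(),
                   score = numeric()), schema)
  expect_equal(empty$relation, "NOREL")
  expect_equal(empty$score, 0)

  # score tie resolved by relation precedence DG > ... > IAW
  tie <- tibble::tibble(relation = c("IAW", "DG"),
                        direction = c("symmetric", "forward"),
                        score = c(0.7, 0.7))
  expect_equal(select_relation(tie, schema)$relation, "DG")
})

test_that("micro-relations demote to macro-relations without an in-sentence cue", {
  schema <- default_relation_schema()
  am <- list(relation = "AM", direction = "forward", score = 0.8)
  demoted <- apply_cue_demotion(
    am, "the drug was taken for the symptom", schema)
  expect_equal(demoted$relation, "IUF")
  expect_equal(demoted$direction, "forward")

  kept <- apply_cue_demotion(
    am, "the drug helped reduce the symptom", schema)
  expect_equal(kept$relation, "AM")

  ex <- list(relation = "EX", direction = "forward", score = 0.8)
  expect_equal(apply_cue_demotion(
    ex, "stress can worsen the cough", schema)$relation, "EX")
  expect_equal(apply_cue_demotion(
    ex, "stress accompanies the cough", schema)$relation, "IAW")

  # CR demotion canonicalizes to the symmetric direction
  cr <- list(relation = "CR", direction = "reverse", score = 0.8)
  out <- apply_cue_demotion(cr, "the two conditions appear together",
                            schema)
  expect_equal(out$relation, "IAW")
  expect_equal(out$direction, "symmetric")

  # word-boundary matching: "IPF cough" carries no causal cue
  expect_equal(apply_cue_demotion(
    list(relation = "CR", direction = "forward", score = 0.9),
    "my IPF cough is awful", schema)$relation, "IAW")
})

test_that("extract_relations composes generation, selection and demotion", {
  schema <- default_relation_schema()
  sent <- list(text = paste(
    "I have severe clubbing of my fingers due to my Pulmonary Fibrosis",
    "and I sometimes do not read what I have tweeted"))
  mentions <- tibble::tibble(
    type = c("SY", "DI"), surface = c("clubbing", "Pulmonary Fibrosis"),
    start = c(14L, 47L), end = c(22L, 65L))
  # scorer favoring the causal reading disease -> symptom
  scorer <- entailment_backend(function(p, h) {
    if (h == "Pulmonary Fibrosis leads to clubbing") 0.9 else 0.05
  }, name = "fixture")
  rels <- extract_relations(sent, mentions, schema, scorer)
  expect_equal(nrow(rels), 1)
  expect_equal(rels$relation, "CR")  # cue "due to" licenses the micro-relation
  expect_equal(rels$arg1_surface, "Pulmonary Fibrosis")
  expect_equal(rels$arg2_surface, "clubbing")
  expect_equal(rels$score, 0.9)

  expect_equal(nrow(extract_relations(sent, mentions[0, ], schema,
                                      scorer)), 0)

  three <- tibble::tibble(
    type = c("DI", "SY", "DR"),
    surface = c("emphysema", "fatigue", "pirfenidone"),
    start = c(0L, 20L, 40L), end = c(9L, 27L, 51L))
  all_pairs <- extract_relations(sent, three, schema,
                                 constant_entailment_backend(0),
                                 keep_norel = TRUE)
  expect_equal(nrow(all_pairs), 3)
  expect_true(all(all_pairs$relation == "NOREL"))
})

test_that("is-associated-with instances are invariant under argument swap", {
  schema <- default_relation_schema()
  sent <- list(text = "the cough comes along with the IPF somehow")
  mentions <- tibble::tibble(
    type = c("SY", "DI"), surface = c("cough", "IPF"),
    start = c(4L, 31L), end = c(9L, 34L))
  scorer <- entailment_backend(function(p, h) {
    if (grepl("is associated with", h, fixed = TRUE)) 0.8 else 0
  }, name = "fixture")
  a <- extract_relations(sent, mentions, schema, scorer)
  b <- extract_relations(sent, mentions[2:1, ], schema, scorer)
  expect_identical(a, b)
  expect_equal(a$relation, "IAW")
  expect_equal(a$arg1_surface, "cough")  # smaller offset is arg1
})

test_that("schema files round-trip through the YAML reader", {
  schema <- read_relation_schema(patientlens_example("relation_schema.yaml"))
  expect_equal(schema$threshold, 0.2)
  expect_equal(schema$templates$CR, "{concept 1} leads to {concept 2}")
  expect_setequal(names(schema$cues), c("AM", "CR", "EX"))
  # a schema violating the ITO time-argument rule is rejected
  bad <- default_relation_schema()
  bad$admissible$ITO$arg1 <- c("DI")
  expect_error(patientlens:::validate_relation_schema(bad),
               class = "patientlens_config_error")
})
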
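test_that("hypothesis templates enforce the slot/question contract", {
  expect_error(hypothesis_template("DIAGNOSIS", "no slot here"),
               class = "patientlens_config_error")
  expect_error(hypothesis_template("NEED", "{entity} needs something.",
                                   questions = "What?"),
               class = "patientlens_config_error")
  expect_error(hypothesis_template("NEED", "Someone needs something."),
               class = "patientlens_config_error")
  bank <- default_template_bank()
  expect_true(all(bank$threshold >= 0 & bank$threshold <= 1))
  tsv <- read_template_bank(patientlens_example("templates.tsv"))
  expect_equal(as.data.frame(tsv), as.data.frame(bank))
})

test_that("screening passes on strict threshold exceedance only", {
  need <- default_template_bank()[1, ]
  # score exactly at the threshold fails
  at <- screen_sentence(list(text = "anything"), need,
                        constant_entailment_backend(0.5))
  expect_false(at$pass)
  above <- screen_sentence(list(text = "anything"), need,
                           constant_entailment_backend(0.51))
  expect_true(above$pass)
  # the printed need sentence passes under the reference scorer
  ref <- screen_sentence(list(text = paste(
    "A local resident in need of a lung transplant is struggling to",
    "survive due to severe complications.")), need,
    reference_entailment_backend())
  expect_true(ref$pass)
  expect_error(screen_sentence(list(text = "x"),
                               default_template_bank()[3, ],
                               constant_entailment_backend(1)),
               class = "patientlens_contract_error")
})

test_that("question order is priority and spans are extractive", {
  sent <- list(text = "X is in need of a lung transplant")
  need <- default_template_bank()[1, ]
  ans <- extract_target_span(sent, need, reference_qa_backend())
  expect_equal(ans$text, "a lung transplant")
  expect_null(extract_target_span(list(text = "nothing relevant"), need,
                                  reference_qa_backend()))

  # both questions match: the first wins
  tpl <- hypothesis_template("SUPPORT", "Someone receives support.",
                             questions = c("q1", "q2"))
  log <- character(0)
  answerer <- qa_backend(function(q, ctx) {
    log <<- c(log, q)
    list(text = substring(ctx, 1, 4), start = 0L, end = 4L,
         confidence = 1)
  }, name = "spy")
  ans2 <- extract_target_span(list(text = "some context"), tpl, answerer)
  expect_equal(log, "q1")
  expect_equal(ans2$text, "some")
})

test_that("diagnosis status is grounded in DI/SY mentions, misdiagnosis wins", {
  bank <- default_template_bank()
  sent <- list(text = paste(
    "my health took a turn when I received a diagnosis of pulmonary",
    "fibrosis this spring"))
  entity <- tibble::tibble(concept_type = "DI",
                           surface = "pulmonary fibrosis",
                           start = 53L, end = 71L)
  hit <- classify_diagnosis_status(sent, entity, bank,
                                   reference_entailment_backend())
  expect_equal(hit$target, "DIAGNOSIS")
  expect_gt(hit$score, 0.5)

  # a scorer validating both targets resolves to the more specific one
  both <- classify_diagnosis_status(sent, entity, bank,
                                    constant_entailment_backend(0.9))
  expect_equal(both$target, "MISDIAGNOSIS")

  # below threshold on both -> no mention
  expect_null(classify_diagnosis_status(sent, entity, bank,
                                        constant_entailment_backend(0.1)))

  expect_error(classify_diagnosis_status(
    sent, tibble::tibble(concept_type = "DR", surface = "pirfenidone",
                         start = 0L, end = 11L),
    bank, constant_entailment_backend(1)),
    class = "patientlens_contract_error")
})

test_that("question answering never runs on sentences that failed screening", {
  bank <- default_template_bank()
  bomb <- qa_backend(function(q, ctx) stop("must not be called"),
                     name = "bomb")
  out <- extract_abstract_mentions(
    list(text = "a sentence without any target"), new_mention_tbl_(),
    bank, constant_entailment_backend(0), bomb)
  expect_equal(nrow(out), 0)
})

test_that("emitted abstract mentions always clear their threshold", {
  bank <- default_template_bank()
  sent <- list(text = "X is in need of a lung transplant")
  out <- extract_abstract_mentions(sent, new_mention_tbl_(), bank,
                                   reference_entailment_backend(),
                                   reference_qa_backend())
  expect_equal(out$target, "NEED")
  expect_equal(out$answer_text, "a lung transplant")
  expect_true(all(out$score > 0.5))

  # without an extractable answer the mention is suppressed by default
  none <- extract_abstract_mentions(
    list(text = "support was great all around"), new_mention_tbl_(),
    bank, constant_entailment_backend(0.9),
    qa_backend(function(q, ctx) NULL, name = "mute"))
  expect_equal(nrow(none), 0)
  kept <- extract_abstract_mentions(
    list(text = "support was great all around"), new_mention_tbl_(),
    bank, constant_entailment_backend(0.9),
    qa_backend(function(q, ctx) NULL, name = "mute"),
    require_answer = FALSE)
  expect_setequal(kept$target, c("NEED", "SUPPORT"))
})
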
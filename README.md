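# patientlens

Social-media listening for patient-focused drug development: an
offline-runnable NLP pipeline that mines patient, caregiver and community
perspectives on a disease (the packaged configuration focuses on
idiopathic pulmonary fibrosis, IPF) from social-media posts.

Reaching patients and caregivers at scale through interviews is
impractical; their posts on forums and social platforms are a rich
substitute, but unstructured. `patientlens` turns a corpus of posts into
sentence-level structured annotations for three questions: *who* is
speaking (interest groups), *what challenges* the disease poses
(symptoms, needs, diagnoses and misdiagnoses, onset timing), and *what
treatment and support* is available (drugs, treatments, support
providers, treatment–disease relations).

## What the pipeline does

All analysis runs at the **sentence level**, because a single post can
shift perspective mid-way (caregiver one sentence, patient the next).

1. **Corpus ingestion** (`read_posts`, `deduplicate_posts`,
   `pseudonymize`, `segment_posts`) — JSONL posts are deduplicated by
   normalized text (reposts under different URLs would bias every count),
   direct identifiers are replaced (random substitution for person names,
   the `[EMAIL]` tag for emails), and posts are split into offset-exact
   sentences.
2. **Interest groups** (`train_interest_classifier`,
   `predict_interest_group`, `aggregate_post_labels`) — few-shot
   classification of each sentence into patient (PA), caregiver (CG),
   patient's association (PAA), scientific/medical community (SC) or
   other (O): sentence embeddings plus a multinomial logistic head;
   post-level labels are the union of non-O sentence labels.
   `evaluate_classifier` reports per-label precision/recall/F1 with
   macro and support-weighted averages.
3. **Primary biomedical entities** (`match_concepts`) — dictionary NER
   for disease (DI), drug (DR), symptom (SY) and treatment (TR) driven by
   ontology-derived term lists, with precision filters: per-ontology
   blacklists, matches inside ORGANIZATION spans dropped (disease names
   inside foundation names), non-nominal phrase heads dropped, and every
   disease/symptom ontology overlap treated as a symptom.  A treatment
   vocabulary can be compiled from a class hierarchy with
   `compile_treatment_lexicon` (therapy and medical-procedure
   descendants, minus diagnostic categories).
4. **Time expressions** (`extract_time_mentions`,
   `normalize_to_day_offset`) — date/duration/time/set mentions; past
   date and duration expressions normalize to an absolute day offset from
   the posting date under coarse calendar conventions (year 365, month
   30, week 7 days; *now*/*currently* are dates meaning "day 0").
5. **Abstract entities** (`screen_sentence`, `extract_target_span`,
   `classify_diagnosis_status`) — needs, support, diagnoses and
   misdiagnoses are detected zero-shot: a hypothesis such as `"Someone
   needs something."` is scored against the sentence by an entailment
   model, and sentences that pass are sent to extractive question
   answering (`"What is needed?"`).  Diagnosis hypotheses are grounded in
   extracted entities (`"<entity> was diagnosed."`), which injects
   ontology knowledge into a general-domain inference model.
6. **Relations** (`extract_relations`) — for every mention pair,
   two-slot hypothesis templates (e.g. `"{concept 1} leads to
   {concept 2}"` for *creates*) are instantiated in both argument orders
   (the swapped hypothesis decides direction), type-inadmissible
   relations are pruned (a disease cannot cause a point in time), the
   highest-scoring hypothesis above the threshold (default 0.2) wins, and
   the micro-relations *ameliorates*/*creates*/*exacerbates* are demoted
   to their macro-relations (*is used for* / *is associated with*) when
   no cue word ("reduce", "due to", "worsen", ...) occurs in the
   sentence.

Every learned step hides behind a backend contract (entailment, question
answering, embeddings) with deterministic reference implementations, so
the whole pipeline — and its test suite — runs offline.  Transformer
adapters with the same contracts can be plugged in via
`register_backend`.  A gold-annotated synthetic corpus generator
(`generate_corpus`) with generation-consistent oracle backends
(`oracle_backends`) provides the end-to-end correctness surface.

## Worked example

```r
library(patientlens)
posts <- tibble::tibble(
  post_id = c("p1", "p2"), source = "forum", url = "",
  published_at = as.Date(c("2023-11-15", "2023-10-02")),
  text = c(paste("Two weeks ago I received a diagnosis of IPF.",
                 "My pulmonary fibrosis causes clubbing and fatigue."),
           "I am in need of a lung transplant. My cough is linked to my IPF."),
  lang = "en")
result <- run_pipeline(posts, pipeline_config(seed = 42))
result
#> <patientlens_result> 2 posts, 4 sentences | 7 entities, 1 times, 2 abstract, 5 relations

result$abstract[, c("post_id", "target", "trigger_surface", "answer_text", "score")]
#>   post_id    target trigger_surface       answer_text score
#> 1      p1 DIAGNOSIS             IPF              <NA>     1
#> 2      p2      NEED            <NA> a lung transplant     1

compute_onset_days(result)
#>   post_id index group                                         text abs_days via
#> 1      p1     0  <NA> Two weeks ago I received a diagnosis of IPF.       14 ito

cooccurrence_table(result, pipeline_config()$disease_synonyms, "SY")
#>   surface  concept_type n_sentences
#> 1 clubbing           SY           1
#> 2 cough              SY           1
#> 3 fatigue            SY           1
```

Reading the output: the diagnosis of IPF in `p1` was detected via the
grounded hypothesis and its onset expression "Two weeks ago" resolved to
14 days before the posting date; the explicit need in `p2` was answered
extractively as "a lung transplant"; the symptom co-occurrence table is a
deliberately relation-free first look at disease burden.  Interest-group
labels are `NA` here because no classifier was configured; relation
scores under the lexical reference backend are coarse (the
`pulmonary fibrosis`–`clubbing` pair lands on *is associated with*
because no template predicate is matched verbatim) — a transformer-backed
entailment adapter sharpens them without any pipeline change.

A command-line front end ships in `inst/cli/patientlens`
(`ingest`, `segment`, `ner`, `times`, `relations`, `simulate`,
`analyze`).

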
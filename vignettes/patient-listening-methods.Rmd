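---
title: "Methods: sentence-level patient listening with zero-shot extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sentence-level patient listening with zero-shot extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patientlens)
```

`patientlens` structures social-media posts about a disease into
sentence-level annotations: who speaks (interest groups), which
biomedical concepts and time expressions are mentioned, which abstract
targets (needs, support, diagnoses, misdiagnoses) are expressed, and
which relations hold between mentions.  This vignette explains the
models and conventions, the parameters that matter, and what the test
evidence does and does not show.

## Why the sentence is the unit

A single post can switch perspective mid-way — a caregiver sentence
followed by a patient sentence — and long posts bury specific
information.  Every classifier and extractor therefore operates on
sentences carrying exact character offsets (0-based, half-open) into
their post, so any annotation can be located in the original text.
Deduplication precedes everything: users repost identical content under
different URLs, and duplicated text would bias all downstream counts.
The deduplication key is the casefolded, whitespace-collapsed full text;
exact-after-normalization was chosen over near-duplicate detection
because verbatim reposting is the observed failure mode, and a fuzzy key
would silently merge genuinely distinct posts.  Within a key the
earliest post survives (ties by identifier) so dates remain meaningful.

## Backend contracts instead of models

Three learned operations are abstracted behind contracts: entailment
scoring (premise + hypothesis to a probability), extractive question
answering (question + context to a span or abstention), and sentence
embedding.  The package ships deterministic reference implementations so
everything runs offline:

* the **reference entailment scorer** is a documented lexical formula:
  content tokens of the hypothesis (stopwords and the indefinite
  placeholders *someone/something* removed, regular suffixes stripped)
  are matched against the premise by stem equivalence; a full match
  scores 1, a partial match scores `m/(2k)`.  The halving is deliberate:
  a grounded hypothesis such as `"pulmonary fibrosis was misdiagnosed."`
  should not clear a 0.5 threshold on the strength of the entity tokens
  alone — the predicate has to match too;
* the **reference answerer** is a per-question table of capture
  patterns (at most three word tokens per answer) — adequate for
  fixtures, explicitly not production quality;
* the **reference embedder** hashes bag-of-words features into 256
  dimensions with a seeded sign hash.

A transformer-backed adapter swaps in through the same contract without
touching pipeline code.  Scores are always clamped to `[0, 1]`, and a
crashing backend raises a typed error so it can never be mistaken for a
low score.

## Dictionary NER and its precision filters

Primary biomedical entities (disease, drug, symptom, treatment) are
matched from ontology-derived term lists: medical vocabularies are
largely unambiguous, so case-insensitive token-boundary matching with
leftmost-longest resolution buys high precision without any annotation.
Term normalization is casefold plus whitespace collapse — no stemming,
as medical terms rarely need it and stemming would invite false
positives.  Three filters address the residual error sources:

* matches inside ORGANIZATION spans are dropped (foundations embed
  disease names in their titles);
* matches whose phrase head — approximated by the final token — is not
  a noun or proper noun are dropped;
* per-ontology blacklists remove entries with overly broad semantics
  (*group*, *role*, *application*).

Both linguistic filters degrade gracefully: an annotator without
part-of-speech tags or organization spans skips the filter with a logged
warning, so the model-free reference annotator still runs.  When several
concept types match the identical span, the precedence drug > treatment
> disease > symptom applies — except for disease/symptom ontology
overlaps, which are always relabeled as symptoms: lay authors use the
two categories interchangeably, so the distinction cannot be trusted and
the more specific reading (a manifestation) is kept.  A treatment
vocabulary is compiled from a generic class hierarchy by taking all
descendants of *therapy* and *medical procedure* and removing the
diagnostic branches (*health assessment*, *invasive test*, *medical
diagnosis*, *medical test*), exclusion winning on conflict.

## Time normalization conventions

Four time classes are tagged: date, duration, time-of-day, set
(frequency).  Onset analysis needs day offsets, so past-pointing date
and duration expressions normalize against the posting date under
deliberately coarse conventions:

| convention | value |
|---|---|
| year / month / week / day | 365 / 30 / 7 / 1 days |
| `last <unit>` | exactly one unit |
| *now*, *currently*, *today* | 0 days |
| `[earlier] this <unit>` with no finer anchor | 0 days |
| named month | day 1 of that month, true calendar days, previous year if the month lies ahead of the posting date |
| bare year | January 1 of that year, true calendar days |
| bare duration ("3 months") | read as illness duration: onset that many days back |

*Now*/*currently* are always tagged as dates regardless of what a
backend says, because the present moment pins an onset to day 0.
Expressions too vague to resolve ("a while back", "several years") and
future-pointing ones are reported unresolvable rather than guessed —
onsets precede posts, so offsets are never negative.  The month-name
rule is a stated convention, not a verified reproduction: published
worked examples with month anchors presuppose unprinted posting dates.
Full TIMEX-style normalization and interval algebra are out of scope; a
single onset relation admittedly oversimplifies temporal structure.

## Zero-shot abstract entities

Needs and support cannot be enumerated in a lexicon — they may be
social, psychological, financial.  They are detected by entailment
screening (hypothesis `"Someone needs something."` against the sentence)
followed, for sentences that pass, by extractive question answering
(`"What is needed?"`, questions asked in priority order).  Screening
before answering is what keeps extractive false positives down; a
sentence that fails screening is never shown to the answerer, and by
default a passing sentence without an extractable span is suppressed.
Diagnosis and misdiagnosis are *grounded*: the hypothesis is
instantiated from an already-extracted disease/symptom mention
(`"<entity> was diagnosed."` / `"<entity> was detected."`, maximum over
variants — they are alternative phrasings of one claim), which is how
ontology knowledge reaches an otherwise general-domain inference model.
When both diagnosis and misdiagnosis clear the threshold the more
specific misdiagnosis wins.  All four targets default to threshold 0.5
(screening thresholds are an empirical knob; 0.5 is the neutral default
and every template row carries its own overridable value), and passing
is strict (`score > threshold`).  Only the need hypothesis/question pair
and the two diagnosis variants are canonical formulations; the support
and misdiagnosis rows are package defaults, replaceable via the
template TSV.

## Relation extraction

Seven relations are extracted between mention pairs: *ameliorates*,
*creates*, *diagnoses*, *exacerbates*, *is associated with* (the only
symmetric one), *is used for*, *is time of*.  *Creates* and
*exacerbates* are micro-relations of *is associated with*; *ameliorates*
of *is used for*.  The procedure per unordered pair:

1. **Generate** hypotheses from two-slot templates for every admissible
   relation, in both argument orders for directed relations — the
   swapped hypothesis is what determines direction.  Type admissibility
   prunes up front: *diagnoses*/*is used for*/*ameliorates* take a
   treatment or drug as head and a disease or symptom as tail; *is time
   of* takes a date/duration as head; a disease cannot cause a point in
   time.
2. **Select** by thresholded argmax — only one relation can hold
   between two concepts, so the highest-scoring hypothesis wins if it
   strictly exceeds the threshold (default 0.2, the operating point of
   the procedure); otherwise the pair is NoRel.  Score ties break by the
   fixed precedence DG > ITO > AM > EX > CR > IUF > IAW, then forward
   direction — an artifact decision for determinism where the method is
   silent.
3. **Demote** a selected micro-relation whose cue words (e.g.
   "reduce", "due to", "worsen") do not occur in the sentence to its
   macro-relation: causal and ameliorative readings require an explicit
   connective, so "IPF cough" alone never yields *creates*.  Matching
   is case-insensitive at word boundaries.  The ameliorates and
   exacerbates cue lists are the published inventories plus regular
   inflections (word-boundary matching would otherwise miss
   "reduces"); the creates list covers the standard explicit-causation
   connectives.  All lists live in a data file, not code.

Relations are extracted *as stated in the text*, not as they hold in
reality — lay authors assert scientifically untenable links, and the
pipeline's evidence is the sentence alone (no knowledge base is
consulted at extraction time).  The symmetric *is associated with* is
canonicalized by argument offset, so extraction is invariant under
argument swap.  Multiple templates per relation aggregate by maximum,
consistent with the argmax selection.  NoRel pairs are suppressed by
default and kept under a flag for evaluation against pair-annotated
datasets.  Cross-sentence relations and supervised relation classifiers
are out of scope.

## Interest groups

Five mutually exclusive sentence labels: patient, caregiver, patient's
association, scientific/medical community, other.  The few-shot design
embeds sentences and trains a multinomial logistic head
(`nnet::multinom`, weight decay `1e-4`, fixed-seed initialization) on
the embeddings; a contrastive Siamese adaptation of the embedder is an
optional plugin hook, skipped for the deterministic reference embedder
so tests stay offline.  Ties in predicted probability break by the
fixed label order PA, CG, PAA, SC, O.  Post-level output is multi-label:
the union of non-O sentence labels, with O surviving only when every
sentence is O — O exists to absorb uninformative sentences, so it
carries no information at post level.  Evaluation reports per-label
precision/recall/F1 on the percent scale with accuracy, macro averages
(over labels with nonzero gold support — a label absent from the gold
would otherwise contribute an undefined row) and support-weighted
averages.  Stratified 60/20/20 splitting with largest-remainder
rounding is provided for reproducible experiments.

## The synthetic corpus and what passing tests mean

Annotated patient-listening corpora are proprietary, so the package's
end-to-end evidence comes from a generator that *plants* annotations by
template-slot construction: group-specific phrasing templates are
filled with entities from the packaged fixture lexicon and time
expressions from the normalization-supported inventory, making every
gold offset exact by construction.  Defaults mirror the emulated study
conditions: the interest-group mix follows the annotated-corpus label
distribution (patients 17%, caregivers 11%, associations 8%, scientific
community 10%, other 54%), and planting rates echo the relative relation
frequencies of the corresponding annotation inventory (associative and
is-used-for links common, ameliorates/exacerbates rare), with the
remainder of sentences relation-free.  Group proportions are
quota-allocated, so realized proportions match the configuration within
rounding.

Oracle backends are derived from the gold annotations: the entailment
oracle validates exactly the hypotheses instantiated from planted
relations and targets in their true direction, the answerer returns the
planted span, the embedder emits label-separable one-hot vectors.  With
these backends the pipeline must recover the gold *exactly* — entity
F1, relation accuracy including direction, and group accuracy all 1.0 —
and the test suite asserts this on a 50-post corpus, alongside
property-style suites (matcher versus a brute-force substring oracle on
random sentences, cue-demotion and symmetry invariants corpus-wide,
threshold semantics under forced scores, metric agreement with an
independent confusion-matrix oracle).

What this does and does not show: oracle recovery certifies the
*plumbing* — offsets, directionality, thresholds, demotion, aggregation
— under a model that is right by construction.  It says nothing about
model quality on real prose: synthetic sentences are short, templated,
and free of sarcasm, misspellings, code-switching and discourse
phenomena.  Reference-backend behaviour on real text is deliberately
conservative (coarse lexical scores tend to land on the macro-relation
*is associated with*), and published evaluation scores on proprietary
annotated data are not reproducible here and are not claimed.

## Numerical and degenerate-input choices

Scores and confidences are clamped to `[0, 1]` and never NaN; empty
inputs yield typed empty tables; a single malformed corpus line is
skipped with a logged line number (or aborts, configurable); a sentence
that fails inside the pipeline is logged and never aborts the corpus;
all randomness (generation, splitting, head training) is seeded and
every run records seed, backend names and a configuration hash in its
provenance, so identical configurations reproduce identical serialized
results.  Test problem sizes (50-post oracle corpora, 200-sentence
matcher equivalence, 100 random metric vectors) were chosen as the
smallest sizes that exercise every payload template and both branches
of every invariant.
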
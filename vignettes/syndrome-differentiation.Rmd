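---
title: "Inquiry-based syndrome differentiation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inquiry-based syndrome differentiation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmsdm)
```

## The problem

TCM diagnosis rests on four procedures — inspection, auscultation,
inquiry and palpation. The first three can be instrumented with cameras
and sensors and typically yield a shortlist of candidate syndromes;
inquiry, by contrast, is a dialogue, and most diagnostic evidence is
obtained through it. `tcmsdm` models that dialogue: given candidate
syndromes, generate exactly the questions that discriminate among them,
collect the patient's answers, and rank the candidates.

No consultation dataset exists at the scale deep learning would need,
so the model is knowledge-driven rather than learned: domain knowledge
is encoded once, as structured question-answer mappings, and the runtime
system is deterministic symbolic reasoning over that encoding.

## Knowledge representation

A **symptom** is a question-answer pair `z = (q, a)` — e.g. ("Fear of
cold?", "Fear of cold"). A **syndrome** is an ordered sequence of
symptoms `h = {z_1, ..., z_n}`; order matters because the consultation
is contextual (duration is only asked after fever is established). The
sequence's last pair carries the syndrome's name in its `next` field —
the *terminal link* — which doubles as the reverse index from pairs to
syndromes.

The **question base** groups questions into the 13 inquiry topics of the
Ten Brief Inquiries mnemonic (cold and heat, sweat, pain, taste, ears,
eyes, chest, hypochondrium, stomach and abdomen, sleep, thirst,
appetite, stool and urine) and numbers them sequentially across topics,
so ascending id order reproduces the canonical consultation order.
Every answer points forward: either to a later question or to a
syndrome. Forward-only pointers are the package's acyclicity rule — the
source material never states one, and this is the weakest rule that
makes every consultation provably terminate (ids strictly increase along
any chain).

The validator (`validate_kb()`) enforces these invariants as coded
findings rather than exceptions, so authoring errors surface all at
once. Category/id monotonicity is a warning by default and an error
under `strict = TRUE`: hand-authored bases may violate it harmlessly,
but generated ones never should. Reachability (`UNREACHABLE_QUESTION`)
is advisory: a question no syndrome uses and no answer points to is
suspicious but not inconsistent. An answer whose `next` names a
syndrome without being that syndrome's stored terminal pair is accepted
silently — it is an extra entry link, and the reverse index stays a
function — but a syndrome whose own last pair does not name it, or two
syndromes claiming one pair, are errors (`NO_TERMINAL`).

## The three reasoning steps

1. **Deduction** (`deduce_qa_list()`): the union of the candidates'
   question ids, deduplicated, sorted ascending, each question carrying
   its *full* candidate-answer list (the worked example shows all nine
   body-location answers even with two candidates). Sorting by global
   id rather than candidate-traversal order is a design choice: the ids
   were constructed to encode consultation order, and the worked
   example's printed order is consistent with it.
2. **Consultation** (`run_consultation()`): questions are asked strictly
   in list order, one closed-vocabulary answer each; `"none"` is always
   accepted and contributes no symptom. Policies: `scripted` (a fixed
   map), `random` (uniform over candidate answers — the simulation
   protocol's patient; it never answers "none" unless `none_prob > 0`),
   `oracle` (answers as a patient who truly has a planted syndrome:
   its stored answer inside the syndrome's sequence, "none" outside),
   and `interactive`.
3. **Differentiation** (`differentiate()`): the *matching degree* of
   candidate `h` is `|h ∩ patient| / |h|`, intersecting on (question id,
   answer id). The source describes comparing the syndrome's symptom
   set to the patient's and ranking by matching degree without printing
   a formula; the containment fraction is the minimal faithful reading
   and reproduces the worked example's outcome. Extra patient symptoms
   outside `h` neither help nor penalize it, and a contradictory answer
   costs exactly the lost match — no additional penalty. The
   confirmation threshold τ defaults to 0.6: unstated in the source,
   chosen as the smallest round value that confirms the example's full
   match (1.0) and rejects its half match (0.5). Ties break by degree,
   then matched count, then name, making output deterministic and
   order-invariant.

## The Bayesian framework

Independently of the matcher, the package implements the diagnostic
probability framework: `P(y|x) = P(x|y) P(y) / P(x)` per symptom, with
`P(x)` supplied or marginalized (`Σ_y P(x|y) P(y)`, under which
posteriors sum to 1), and the four-modality combination
`P(y | s1 ∪ s2 ∪ s3 ∪ s4) = Σ_i P(y|s_i)`. Two choices deserve note:

- The combination is implemented *literally as the printed sum*, which
  is not a probability (it can reach the number of modalities). A
  `normalize` flag (default off) rescales across syndromes; ranking is
  unaffected. Faithfulness to the stated equation was preferred over
  reinterpretation.
- Only single-symptom posteriors are stated in the source; for a
  modality's whole symptom set the package applies the naive-Bayes
  product, which is the standard consequence of the source's explicit
  within-lesion independence assumption.

The source never connects this framework to the deployed matcher, so it
is an optional, clearly separated scoring path (`kb_bayes_model()`
bridges a KB to it with uniform priors and hit/miss likelihoods,
default `p_hit = 0.9`, for exploration only).

## The synthetic-data generator

The real knowledge base (225 syndromes) was never published, so all
simulation runs on generated bases that emulate its *structure*:
categories assigned first and questions numbered sequentially across
ranks (strict monotonicity holds by construction), ascending sequences
with forward chains, one private terminal answer per syndrome, and a
`overlap` parameter controlling how often syndromes share questions.

Defaults are desk-scale but structurally realistic: 20 syndromes, all
13 categories with 3 questions each (39 questions), 4 answers per
question, sequence lengths uniform on 2–6, overlap 0.3. The published
averages of 4.6 questions for two candidates and 6.4 for three imply
sequences of roughly 2–4 questions with moderate sharing; our defaults
bracket that regime while leaving room for dedup effects. These
defaults were fixed before the acceptance checks were run and are not
tuned to them.

What a green test does establish: structural validity, determinism,
termination, the set-union and containment semantics, and that an
oracle patient is always recovered (generated syndromes are pairwise
non-subset *by construction*, because one syndrome's terminal answer
can never appear inside another's sequence). What it does not: any
clinical claim — synthetic texts are meaningless, answer choices are
uniform rather than epidemiological, and the published question-count
averages and expert 1–5 scores depend on the unpublished base and human
raters, so they are out of reach by design.

## Numerical and format choices

- **Determinism.** Every random operation takes a seed; the protocol
  uses one stream seeded once, consumed in a documented order (all
  candidate sets first, then per-set truth and answer draws), so a
  report is a pure function of `(kb, config)` and serializes
  byte-identically. Seeded helpers restore the caller's RNG state.
- **Serialization.** JSON (schema_version "1") is canonical and
  lossless, with questions sorted by id and syndromes by name. The CSV
  dialect mirrors the five-column question-base table with continuation
  rows; it cannot carry categories or symptom sequences, so CSV import
  assigns the first category and synthesizes a one-pair syndrome per
  terminal answer — a documented reconstruction that keeps references
  resolvable. Round-trip identity therefore holds fully for JSON, and
  for CSV after one import normalization.
- **Text normalization.** Fields are trimmed and marked UTF-8. A true
  Unicode NFC pass would require ICU, which this environment lacks;
  inputs are assumed NFC. Syndrome names are foreign keys and matched
  case-sensitively — silent case-folding would hide authoring errors.
- **Degenerate inputs.** Empty candidate sets deduce an empty list;
  an empty patient record scores 0 everywhere; threshold 0 confirms
  all candidates and any threshold above 1 none; `trim_mean()` needs
  three values and returns `NA` with a warning below that.
- **Open points resolved here.** One ordered sequence per syndrome (the
  source never shows a syndrome with disjoint chains); single-select
  answers (the worked example shows one selection per question); the
  "ten times to obtain 20 sets" reading is ten sets per size, two
  sizes.

## Limitations

- The matcher is set containment; it is deliberately uncalibrated and
  should not be read as a probability.
- CSV is an interchange convenience, not an archival format.
- The evaluation replaces expert judgment with oracle recovery; the two
  agree only insofar as full-sequence match is the right notion of a
  correct differentiation.
- No ontology mapping (ICD/SNOMED/TCM standards) and no free-text
  understanding: answers are closed-vocabulary by design.
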
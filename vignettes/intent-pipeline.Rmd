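---
title: "Classifying firearm-injury intent from clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying firearm-injury intent from clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firearmintent)
```

## The problem and the model

Intent coding in hospital discharge data — whether a gunshot injury was an
assault, an accident, self-harm, legal intervention, or remains unknown —
drives firearm-injury surveillance, yet the ICD external-cause codes that
carry it are assigned for billing and systematically inflate the accident
category. The narrative notes of the encounter usually contain the evidence
a human abstractor would use. `firearmintent` operationalises that
abstraction as a three-stage pipeline: lexicon-driven term extraction with
clinical context, an expert rule system producing binary features, and a
shallow boosted classifier mapping features to the five intent classes.

The hybrid design is deliberate. Rules encode domain knowledge that small
labelled samples cannot teach a classifier (negation, historical mentions,
role of the shooter), while the classifier learns how to weigh imperfect,
sometimes conflicting rule outputs — and can be retrained cheaply when it
moves to a new institution, without touching the rules.

## Term extraction

**Tokenization.** One tokenizer is shared by every stage: case-folding,
with word characters (letters, digits, apostrophes) forming tokens and each
punctuation mark kept as its own token. Keeping punctuation preserves scope
terminators (";") as positions, and guarantees that candidate scoring,
matching, and context detection agree on token indices. Spans are 0-based
and half-open, which makes the containment test behind confusion-term
suppression unambiguous.

**Matching.** Lexicon terms are 1–5 tokens. Matching is greedy
longest-match, left to right; at equal length and start position, the
category earlier in the registry wins (the registry puts `confusion_term`
first so that "police report" beats "police" whenever lengths tie). A match
consumes its tokens, so a term nested inside a matched confusion term is
suppressed by construction; confusion matches are still emitted, flagged,
for audit. Matching is deterministic and invariant to case and surrounding
whitespace.

**Context modifiers.** Each non-confusion match gains three flags. A
negation trigger ("denies", "no", "negative for", …) must sit at most
*W* = 6 tokens *before* the match in the same sentence, with no scope
terminator ("but", ";") between — the asymmetry reflects clinical phrasing,
where negation precedes its object. History ("history of", "years ago",
"old") and other-subject ("brother", "friend") triggers work in both
directions within the same window, because clinical text places them on
either side ("history of GSW" / "GSW 10 years ago"). Scopes never cross
sentence boundaries; W is configurable and 6 is the conventional
clinical-negation window. Sections are recognised from a configured header
list (`HPI:`, `ED COURSE:`, `ASSESSMENT:`, …); text before the first header
is a `preamble` section, so sections always tile the note.

**Candidate scoring.** New lexicon terms are ranked by
score(term, class) = relative frequency of the term among cases of that
class ÷ relative frequency among all cases, on case-level presence rather
than raw counts. A minimum support of 3 cases suppresses noise; by
construction the case-count-weighted mean of a term's per-class scores is
1, which the tests assert.

## Dependency roles

For every sentence containing a shooting-verb term, a dependency parse is
obtained from a pluggable provider (`function(tokens) -> parse`). From the
parse, the verb's `nsubj` is the shooter and its `obj` the person shot; a
passive clause (an `nsubjpass` child) flips the roles, with the by-phrase
object as shooter — essential in clinical prose, which is heavily passive
("pt was shot by police"). Adverb children and prepositional subtrees
(capped at 8 tokens) become circumstance phrases. A reflexive person shot
with a shooter present flags the event self-directed, the minimal mechanism
linking grammatical roles to self-harm. The package ships a deterministic
heuristic parser adequate for the synthetic grammar and fixtures; it is a
provider like any other, and a trained parser can be injected through the
same contract. Event extraction depends only on tokens and arcs, so two
providers that agree on arcs yield identical events — a tested invariant.

## The rule system

Rules are data, not code: a TSV of (id, kind, intent, clauses) in a small
clause language (`require_category`, `require_tag`, `forbid_modifier`,
`event_role`, `pair_count_cmp`, `count_explicit`, `distinct_intents`).
Mention-level clauses combine conjunctively on a single mention, so
`require_category=explicit_intent_self_harm` +
`forbid_modifier=negated,historical` means "some affirmed, non-historical
self-harm cue exists" — without the modifier constraint, "denies suicidal
ideation" would fire the self-harm rule, which is precisely what modifier
extraction exists to prevent. Meta rules may only count explicit-intent
rules, so no cycles are possible. Conflict counts *distinct intents*, not
rule instances: two assault cues corroborate, they do not conflict.

The information-density rules address the unknown class, which is defined
by absence of information. `high_info_note` is true when any single note
reaches the high threshold in unique (term, context) pairs (boundary
inclusive, a fixed and tested decision); `low_info_case` when the case
total stays below the low threshold. A pair is (surface, category, section,
negated, historical, other_subject). Both per-note and per-case scopes are
implemented because published descriptions leave the deduplication scope
open; the per-note maximum feeds the high-info rule and the case union the
low-info rule. Counting unique pairs makes every feature invariant to
verbatim duplication of notes — the documentation-drift robustness the
error analysis of the original study calls for, asserted by an ablation
test in which a raw-mention-count variant demonstrably flips under drift
while the shipped rules do not.

Threshold tuning sweeps an integer grid; at each value the density features
are recomputed, the classifier specification is refitted on the tuning
cases, and the unknown-class F-score of its resubstitution predictions is
measured. Ties resolve to the smallest threshold. Resubstitution (rather
than an inner split) keeps the procedure deterministic and cheap at desk
scale; since only two features change across the grid, the risk of
overfitting the threshold is limited to them.

## The classifier

The production algorithm is gradient boosting with depth-1 trees, learning
rate 0.1 and 300 trees — stumps over binary features make each tree a
single rule test, so the model stays close to an interpretable weighted
vote. Training is deterministic given the seed (single-threaded boosting).
Prediction assigns the argmax probability; exact ties break by descending
training prevalence then class order, a fixed decision that favours the
dominant class (assault) and keeps runs reproducible. Five comparison
algorithms (random forest, multinomial logistic as maximum entropy, SVM
with Platt probabilities, SAMME AdaBoost over stumps — implemented
in-package — and k-nearest neighbours) share the interface; their
probability constructions follow their libraries' standard contracts, and
classes absent from a training split get probability 0 with the matrix
renormalised. Saved models are single-file archives carrying a manifest
(format version, algorithm, hyperparameters, feature names, class order,
ruleset hash, seed) plus serialized state; loading refuses a wrong format
version, and prediction refuses features from a different ruleset (hash
check). Recalibration refits the identical specification on local data with
no weights carried over. Tree ensembles report split-gain importances
normalised to sum to one; other algorithms fall back to seeded permutation
importance (mean accuracy drop, floored at zero).

## Evaluation

Confusion matrices are 5×5 with predicted rows and adjudicated columns in a
fixed class order, the orientation of the published tables, so printed
matrices load directly as fixtures. Metrics come from integer counts
(TP = diagonal, FP = row remainder, FN = column remainder, TN = rest):
specificity TN/(TN+FP), precision TP/(TP+FP), recall TP/(TP+FN),
F = 2PR/(P+R). Division by zero yields 0 — except specificity, which is 1
when there are no true negatives to misclassify — a convention needed for
the tiny legal-intervention class and recorded in reports. Rounding is
half-up to 2 decimals and happens only at report time. AUROC is the
trapezoid over the one-vs-rest ROC with tied scores grouped into one
operating point; AUPRC is the step-wise interpolated area (precision ×
recall increment per threshold). A class absent from the truth gets `NA`
areas, not 0. Splits are a seeded uniform permutation with contiguous
allocation (sizes within one case of the target fractions), unstratified by
default — mirroring designs that freeze splits before labels exist — with an
optional stratified mode. The ICD comparison drops cases without a
discharge code from both arms first, so the two arms are always scored on
the identical case set.

## The synthetic generator

No shareable EHR corpus exists, so the generator *is* the study's data
source and its defaults are the study conditions. A site profile fixes the
adjudicated intent distribution — (0.075, 0.708, 0.018, 0.054, 0.145) for
the development-site profile and (0.148, 0.664, 0.036, 0.114, 0.036) for
the external-site profile, taken from the published site marginals — the
ICD miscoding matrix, notes per case (1–3 with probabilities 0.5/0.3/0.2),
cue emission probabilities (0.9 for the four known intents, 0.35 for the
unknown-intent attestation, reflecting that most unknown cases simply lack
information), informative-sentence counts (4–6 for known-intent cases; 0–1
for unknowns at the development site, equal to known cases at the external
site, whose records were uniformly information-rich), a 0.3 distractor
probability, negative-binomial filler (mean 6, size 8), and a documentation
redundancy factor. Because joint tables of ICD versus adjudicated intent
are not published, the miscoding matrix is reconstructed from the two
marginals by iterative proportional fitting from a diagonal-heavy prior
with extra affinity on the assault-truth → ICD-accident cell, reproducing
the documented accident-inflation pattern while matching both marginals
exactly; 9% of development-profile cases lack an ICD code entirely.

Every sentence the grammar can emit is annotated with the terms and
modifiers it contains; this generation log, not the rendered text, is the
oracle that extraction and rule tests check against. The grammar is
deliberately template-based: determinism and oracle-checkability outrank
realism. Consequences worth stating plainly: synthetic notes have none of
the misspellings, ungrammatical fragments, copy-forward noise, or
out-of-grammar negations of real clinical text, and the shipped heuristic
parser is only exercised within the grammar it was built for. Passing tests
demonstrate that the pipeline's logic is correct and robust to the
phenomena the generator *does* model (negation, history, confusion traps,
documentation drift, site shift); they do not certify performance on real
records, where the published figures (average F about 0.58 at the
development site) are far from the near-perfect synthetic scores.

## Problem sizes and numerical choices

The shipped analyses use 1000 synthetic cases for the end-to-end study
(60/20/20 split, threshold grid 1–12) and 400 cases per site for the
two-site importance contrast; these sizes give stable results for the
properties asserted while keeping a full run in tens of seconds on one
core. Probability rows are validated to sum to 1 within 1e-6 and
renormalised after zero-filling absent classes; argmax ties use a 1e-12
tolerance; metric identities are exact on integer counts before rounding.
Degenerate inputs are errors, not silent defaults: empty note lists, mixed
case ids, single-class training labels, fraction vectors that do not sum to
1, probability rows that do not.

## Known limitations

The lexicon is a starter covering every category the rules consume, not a
site-tuned inventory; real deployments grow it via candidate scoring and
error review. The heuristic parser is not a general dependency parser.
Cross-sentence phenomena (coreference, discourse-level negation) are out of
scope, as are UMLS normalisation and spelling correction. The unknown class
remains the hardest: its rules depend on tuned density thresholds that are
sensitive to documentation style, which is exactly the drift pattern the
two-site contrast quantifies.
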
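# firearmintent

Hospital discharge data record every firearm injury arriving in an emergency
department, but the *intent* attached to those records — assault, accident
(unintentional), self-harm, legal intervention, or unknown — is coded from
billing-oriented ICD external-cause codes and is known to be unreliable, most
visibly by inflating the share of "accidental" shootings. `firearmintent` is
an R implementation of a hybrid NLP + machine-learning pipeline that assigns
intent directly from the free-text clinical notes of a case, together with
the evaluation harness needed to compare it against ICD-coded intent, and a
synthetic multi-note case generator so the entire pipeline can be developed
and tested without access to protected health data.

## The method

A case (one injury encounter, possibly several notes) passes through three
stages:

1. **Term extraction.** A specialized lexicon of 1–5-token terms, each with
   a category (shooting verbs, explicit intent cues, incident locations with
   `inside`/`outside` attribute tags, police actors, no-information
   attestations, …), is matched greedily (longest match first) over the
   case-folded tokens of every sentence. *Confusion terms* such as "police
   report" suppress the informative terms they contain ("police"). Every
   match carries clinical context: its note section, and whether it is
   negated ("denies SI"), historical ("GSW 10 years ago"), or about another
   subject ("brother was shot"). Sentences containing a shooting verb also
   get a dependency parse from which the pipeline reads the verb's subject
   as the **shooter**, its object as the **person shot** (with passive-voice
   role flipping, so "pt was shot by police" works), and adverbial /
   prepositional phrases as circumstances. Candidate lexicon terms can be
   ranked by a tf-idf-style score: the frequency of a term among cases of
   one intent divided by its frequency over all cases.

2. **Rule evaluation.** A declarative rule set (shipped as data, editable
   without code changes) turns each case into a binary feature vector:
   explicit-intent rules (an affirmed, non-historical cue of each class),
   role rules (assault shooter, legal shooter, self-directed shooting),
   location rules, meta rules (no explicit intent; conflicting intents), and
   two information-density rules. The density rules compare counts of unique
   *(term, context)* pairs against tuned thresholds — `high_info_note`
   (any note with ≥ *T* unique pairs) and `low_info_case` (case total
   < *t* pairs) — because unknown-intent cases are defined by the absence of
   information. Counting unique pairs rather than raw mentions makes the
   features invariant to duplicated documentation.

3. **Classification.** The binary features feed a gradient-boosted
   classifier of depth-1 trees (learning rate 0.1, 300 trees; everything
   else library defaults), which assigns a probability to each of the five
   intents; the argmax is the label. Models can be saved, applied to new
   data without retraining, and recalibrated (retrained with the identical
   specification) on a new site's labelled data. Random forest, maximum
   entropy, SVM, AdaBoost, and k-nearest-neighbour baselines share the same
   interface for comparison.

Evaluation reports per-class specificity, precision, recall and F-score
from 5×5 confusion matrices (predicted rows, adjudicated columns), one-vs-
rest AUROC/AUPRC, the unweighted average F-score, and a paired comparison of
the model arm vs the ICD-coded arm on the identical case set.

## Worked example

```r
library(firearmintent)

# a labelled synthetic corpus from the development-site profile
corpus <- generate_corpus(300, mds_profile(), seed = 11)
cases  <- extract_corpus(corpus_notes(corpus))          # lexicon + context + parses
feats  <- build_feature_matrix(cases)                   # 14 binary rule features

sp  <- split_cases(corpus$case_id, seed = 3)
tr  <- sp$split == "train"; te <- sp$split == "test"
mod <- train_intent_model(feats[tr, ], corpus$true_intent[tr], seed = 5)
ev  <- evaluate_predictions(predict_intent(mod, feats[te, ]),
                            corpus$true_intent[te])
ev
#> Intent evaluation on 60 cases
#> Unweighted average F-score: 1.00
#>
#>               class specificity precision recall f_score auroc auprc
#>            accident           1         1      1       1     1     1
#>             assault           1         1      1       1     1     1
#>  legal_intervention           1         1      1       1     1     1
#>           self_harm           1         1      1       1     1     1
#>             unknown           1         1      1       1     1     1
```

The perfect scores are a property of the synthetic grammar at its default
cue strength (the templates are deliberately unambiguous), not a claim about
clinical text; the methods vignette discusses what the generator does and
does not emulate. `autoplot(ev)`, `autoplot(ev$confusion)`,
`tidy(mod)` / `glance(mod)` and `plot_feature_importance(mod)` give the
usual tidy summaries, and `compare_to_icd()` produces the model-vs-ICD
report. A thin command-line wrapper over the same functions ships in
`inst/cli/firearm-intent.R` (subcommands `simulate`, `extract`, `train`,
`predict`, `evaluate`, `tune-threshold`, `compare-icd`).

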
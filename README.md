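# delirnlp

Delirium — an acute syndrome of inattention and fluctuating cognitive
dysfunction — affects up to a quarter of hospitalized patients, yet the ICD
billing codes most EHR studies rely on miss the large majority of cases
(validation studies report sensitivities under 20% at high specificity).
The detail is in the narrative notes instead, and often without explicit
negation ("alert and oriented x3" asserts the *absence* of confusion).

`delirnlp` is an R toolkit for detecting delirium episodes directly from
free-text clinical notes.  It implements the full pipeline:

* **Keyword sentence extraction** — abbreviation-aware sentence
  segmentation and a 23-term delirium lexicon with case-insensitive,
  word-boundary, stem-prefix matching.
* **Always patterns** — expert-authored regular expressions that force a
  label wherever they match; label propagation, conflict routing, and
  coverage analysis.
* **Three-class sentence classifiers** — every keyword sentence is scored
  over {POSITIVE, NEGATIVE, NEITHER} by one of three keyword-anchored
  models: a linear SVM over unigram+bigram counts (margins mapped to the
  probability simplex by a softmax), a 3-layer bidirectional LSTM, or a
  3-layer self-attention encoder (both classifying from the hidden vector
  at the keyword position, built on a small built-in autodiff engine —
  CPU-only, seed-reproducible).
* **Active learning** — the labeling loop that made the gold standard:
  entropy-uncertainty queries plus greedy k-center diversity queries on a
  2-D embedding map, with per-round pattern propagation.
* **Evaluation** — micro/macro F1, row/column-normalized confusion
  matrices, one-vs-rest ROC/AUC (tie-corrected Mann–Whitney), percentile
  bootstrap CIs, pairwise per-category interrater agreement.
* **Construct validity** — patient-level ±1 aggregation (any POSITIVE
  sentence → +1) and φ-coefficient associations against ICD codes,
  deliriogenic medications, restraints/sitter orders, mortality and CAM
  assessments, plus mortality by delirium-day burden.
* **Synthetic cohorts** — a template-grammar note generator with known
  sentence labels, latent patient truth, and indicator error rates, so the
  whole pipeline is testable without protected health information
  (`generator_config()`, `generate_cohort()`, `expected_phi()`).

See `vignettes/delirium-note-pipeline.Rmd` for the methods and design
choices in detail.

## Worked example

```r
library(delirnlp)

notes    <- read_corpus(system.file("extdata", "demo_notes.jsonl",
                                    package = "delirnlp"))
patterns <- read_patterns(system.file("extdata", "always_patterns.tsv",
                                      package = "delirnlp"))

sentences <- extract_keyword_sentences(notes)
nrow(sentences)
#> [1] 9

res <- propagate_patterns(patterns, sentences)
table(res$labeled$label)
#> NEGATIVE  NEITHER POSITIVE
#>        4        1        4

pattern_coverage(patterns, sentences)$fraction
#> [1] 1

det <- detect_delirium(notes, patterns)
det$indicators
#>   patient_id nlp
#> 1       P001   1
#> 2       P002  -1
#> 3       P003  -1

delirium_days(det$sentence_labels, notes)
#>   patient_id delirium_days
#> 1       P001             2
#> 2       P002             0
#> 3       P003             0
```

Nine of the demo corpus's sentences contain delirium keywords.  The always
patterns label all of them (coverage 1.0): four assert delirium features
(P001's confusion, agitation and altered mental status), four assert their
absence, and one uses a keyword irrelevantly ("wife confused about
medication schedule" — which is why P002's record never flips positive).
Patient P001 is flagged `+1` with positive sentences on two distinct
calendar days; the other patients are `-1`.

On larger corpora the unmatched remainder is classified by a trained
model: `train_model(model_config("attention"), labeled)` →
`predict_scores(fit, sentences)`, or in one step `detect_delirium(notes,
patterns, model_config("attention"))`.  A thin command-line front-end with
`extract`, `propagate`, `coverage`, `synth`, `train`, `predict`,
`evaluate` and `associate` subcommands is installed at `exec/delirnlp`.

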
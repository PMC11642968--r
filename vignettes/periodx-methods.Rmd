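---
title: "Methods: synthetic periodontal records and two classification tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic periodontal records and two classification tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periodx)
```

`periodx` classifies periodontitis stage (I–IV, coded 1–4) and grade (A–C,
coded 1–3) from electronic dental records along two tracks: a
pattern-extraction + feed-forward-network baseline over a structured feature
table, and a windowed-encoder text classifier over the raw note. Everything
is exercised on synthetic records, so this vignette spells out what is being
modelled, which knobs matter, and what the results do and do not show.

## The staging/grading rule engine

Real staging and grading follow a clinical framework, not a closed formula.
To give the synthetic generator an internal ground truth the package fixes a
deliberately simplified rule set:

* **Stage** from severity and complexity: stage I if maximum clinical
  attachment loss (CAL) ≤ 2 mm with no periodontitis-attributed tooth loss;
  stage II if maximum CAL is 3–4 mm; stage III if maximum CAL ≥ 5 mm with at
  most 4 teeth lost; stage IV if maximum CAL ≥ 5 mm and either ≥ 5 teeth
  lost or fewer than 20 teeth remaining. A record with CAL ≤ 2 mm but
  periodontal tooth loss sits outside this table; we escalate it to stage II
  because loss implies destruction beyond stage I. The complexity clause is
  checked before the stage III clause, so "CAL ≥ 5 mm, few teeth lost, but
  < 20 teeth present" resolves to stage IV.
* **Grade** from the progression ratio `r = bone_loss_percent / age`:
  A if `r < 0.25`, B if `0.25 ≤ r ≤ 1`, C if `r > 1`; smoking or diabetes
  raises the grade one level, capped at C.

These thresholds are conventional in spirit but **not validated against the
2017 World Workshop text**; the package is a methods artifact, not a
diagnostic tool. Their virtue is testability: for every generated record,
`assign_stage()`/`assign_grade()` reproduce the stored labels with 100%
agreement, which the test suite asserts on 1000-patient cohorts.

## The synthetic-record generator

`generate_cohort(n, stage_counts, grade_counts, seed)` matches requested
class histograms *exactly*. Per-patient measurements are proposed from
stage- and grade-conditioned distributions and re-checked through the rule
engine (rejection sampling), so distribution conservation is by construction
rather than approximation. Defaults emulate the reference study's conditions:

* class imbalance 6/36/206/61 (stage) and 17/202/87 (grade), rescaled to `n`
  by largest-remainder apportionment — the published grade counts sum to 306,
  not 309, so a rescaling step is unavoidable;
* medical histories matching the published descriptives of the extractable
  note variables (heart rate mean 72.4, SD 10.45, truncated to 44–118;
  systolic 129.3 ± 15.5 on 79–187; diastolic 78.1 ± 40.32 on 43–120 with
  systolic > diastolic enforced by redraw);
* universal tooth numbering 1–32, ISO-8601 dates, absent teeth carrying no
  measurements.

Notes are rendered from a synonym template bank: each of the 16 extractable
variables appears with probability `1 − omission_rate` (blood pressure is one
phrase carrying systolic and diastolic; the diagnosis sentence carries stage
and grade together), phrasing is drawn at random per note, neutral filler
sentences are interleaved, and `case_jitter` randomly upper/lower-cases
sentences to exercise case-insensitive matching. What the generator does
**not** emulate: spelling errors, negation scope ambiguity, local
abbreviations, longitudinal visits, and any correlation structure beyond the
rule engine — so perfect extraction on synthetic notes bounds what patterns
can do when the note style is known, and says nothing about robustness to
unseen phrasings.

## Extraction track

Patterns are data, not code: `inst/extdata/extraction_schema.yaml` lists, per
variable, ordered case-insensitive patterns (first match wins) and a
converter (numeric, yes/no → 1/0, none/light/medium/heavy → 0–3, Roman
stage, grade letter, ISO date). Negated phrasings are listed before positive
ones so "non-smoker" resolves to 0 even though a later pattern would match
"smoker". Missing information never raises an error and is never fabricated:
a field is non-missing only if a pattern matched, and each captured value is
traceable to a character offset (returned as an attribute). Chart summaries
use pocket threshold PPD ≥ 4 mm, CAL threshold ≥ 3 mm, and a
localized/generalized extent cutoff of 30% of present teeth — conventional
defaults, all configurable, since the source material never states its own.

## Tabular classifier

A two-hidden-layer ReLU network with softmax output, categorical
cross-entropy on one-hot targets, Adam, batch size 16, 30 epochs, 70/30
stratified split; the architecture grid spans 4–20 units per layer with
validation accuracy on a 20% carve-out as the selection metric (the grid is
fixed at exactly two layers; deeper variants degraded accuracy in the
reference study). Implementation choices the source leaves open:

* **Missing cells** (the extractor legitimately produces them): median
  imputation for general numerics, 0 for 0/1 flags, plus a per-field
  missingness indicator column; non-flag columns are standardized by
  training mean/SD.
* **Learning rate** 0.01 by default: Adam's textbook 1e-3 reliably
  underfits these small standardized tables within the fixed 30-epoch
  budget (training loss still falling), while 0.01 converges; the rate is a
  plain argument.
* **Ties** in the output argmax resolve to the lowest class code;
  stratified splitting uses largest-remainder apportionment so each class's
  training share is within one row of the requested fraction.
* No R package provides a two-hidden-layer MLP of this exact shape
  (`nnet` stops at one layer), so forward/backward passes are written in
  package code and checked against numerical gradients in the tests.

## Text classifier

Architecture: tokenize → hash tokens into a fixed vocabulary → wrap each
100-token content window in `[CLS]`/`[SEP]` → encoder embedding per window →
LSTM over the window sequence → dense(64, ReLU) → dropout(0.2) → softmax(K).
Windows are consecutive and non-overlapping (the simplest reading of a
window "swiping" over long text), and the partition is lossless: stripping
markers and padding recovers the token sequence. `window_length` counts
content tokens, with the two markers added on top — this matches the
documented worked examples (a 250-token note yields 3 windows, the last with
50 content tokens; a 1-token note yields 99 padding positions).

Training follows the reference configuration: Adam, balanced class weights
`w_k = n/(K·n_k)` applied to the training loss only (validation loss is
unweighted, matching common framework behaviour, so a single rare-class
example cannot dominate early stopping), per-epoch exponential
learning-rate decay 0.97, 40 epochs, batch 20, 80/20 split, early stopping
on validation loss with best-weight restoration. Unstated details resolved
here: patience defaults to 5 epochs; the validation set for early stopping
is a 20% stratified carve-out of the *training* portion (the held-out test
set stays untouched); classes with a single training example stay entirely
in the training portion; the tabled "momentum 0.5" has no role under Adam
and is recorded but unused; the "decay rate 0.97" is applied as the
learning-rate decay.

The **encoder is a contract**, not a fixed dependency: anything providing
tokenization to ids and a fixed-dimension window embedding works. The
reference configuration is a 12-layer, 12-head, 768-dimensional pretrained
encoder; the shipped fixture is a single-head self-attention block with
residual connection and masked mean pooling over randomly initialized hashed
token embeddings (default dimension 32, vocabulary 1024 — large enough that
hash collisions rarely merge informative tokens). With `fine_tune = TRUE`
(default) the embeddings and attention matrices receive gradients through
exact backpropagation; frozen encoders get their window embeddings
precomputed once. The reference learning rate 5e-6 is appropriate for
fine-tuning a 110M-parameter pretrained model; the fixture-scale experiments
in the tests and acceptance script pass 0.01, the counterpart choice for a
randomly initialized network four orders of magnitude smaller.

## Evaluation and explanation

Per-class precision, recall and F1 use the 0-when-undefined convention
(matching published tables that print 0.00 rows for never-predicted
classes); accuracy is trace over total, which equals micro-averaged recall.
Internal values stay at full precision; presentation rounding is two
decimals, half-up, with an option to recompute F1 from the *rounded*
precision/recall because several published rows were evidently produced that
way. Rows whose printed F1 is inconsistent with both conventions (four rows
across the published per-class tables, each off by one in the second
decimal) are treated as pre-rounding artifacts: the tests reproduce every
arithmetically consistent row and leave the inconsistent ones undisturbed.

The explainer fits a weighted ridge-stabilized linear surrogate over
unique-token presence indicators: random token-deleted variants of one note
(deletion rather than a reserved mask id, so any encoder works) are scored by
the model and weighted by `exp(-(1 - kept_fraction)^2 / kernel_width^2)`.
Coefficients are the token importances; a constant model yields all-zero
importances and a single-token oracle ranks its trigger first in ≥ 95% of
seeds, both asserted in the tests.

## Problem sizes and what passing shows

The test and acceptance workloads were sized for a single-CPU desk run:
extraction round-trips on 500 notes (exact recovery at omission 0; per-field
recovery within (0.4, 0.6) at omission 0.5, a comfortable band at binomial
n = 500), label consistency on 1000 records, tabular parameter recovery on
n = 1000, and text-model recovery on 200 notes. The tabular recovery
experiment trains on the **determinant features**
(`stage_determinants()`, `grade_determinants()`: max CAL, tooth loss,
residual dentition; bone loss, age, their ratio, smoking, diabetes) because
labels are deterministic functions of exactly those columns — the 22-column
extracted table does not determine the labels (it lacks max CAL in
millimetres, tooth counts, bone-loss percentage and age), which is also why
pipeline accuracy on extracted features plateaus near the published ~70%
level rather than approaching 1. The text-model experiment uses notes whose
diagnosis sentence states the label, so a keyword rule attains 1.0 and the
≥ 0.85 bar tests the architecture's ability to find that signal, not
clinical realism. None of these results transfer to real records; they
verify the machinery, the contracts and the reproducibility (same seed,
byte-identical outputs), which is all synthetic data can verify.

## Known limitations

* The rule engine ignores furcation involvement, probing-depth extent,
  ridge defects and the other complexity factors real staging weighs.
* The fixture encoder carries no language knowledge; pretrained-encoder
  behaviour (and the 5e-6 fine-tuning regime) is untested here by design.
* The explainer is the plain linear-surrogate variant: no superpixel
  grouping, no feature selection, and importances for heavily collinear
  tokens are ridge-shared.
* Grid search retrains the winning cell on the full training set; with very
  rare classes the 20% validation carve-out can be small enough that ties
  are common (resolved deterministically toward smaller layers).
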
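---
title: "Temporal EHR risk models and perturbation-based contribution analysis"
author: "seqrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal EHR risk models and perturbation-based contribution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given longitudinal electronic medical records of patients with a condition
of interest (here, PTSD), the package predicts whether a patient will
receive an alcohol/substance-use-disorder (ASUD) diagnosis within the next
3 months, using the diagnoses, medication fills and abnormal laboratory
results of the preceding year, plus social determinants of health (SDoH)
and psychotherapy status extracted from clinical notes. Beyond prediction,
it quantifies how much each coded feature pushes the predicted risk up or
down, producing ranked tables of risk-associated and protective features.

## Cohort definition

A case is a patient with an ASUD code inside the 3-month window after an
index encounter; a control has none. The index date is the latest encounter
after the first PTSD code and before the first ASUD code whose outcome
window is observable within the patient's data span. Patients with PTSD
and ASUD on the same day, ASUD before PTSD, or an ASUD record in the year
before the index date are excluded, each with a recorded reason, so every
input patient is exactly one of case, control or excluded.

Two arithmetic conventions are deliberately fixed because calendar-month
arithmetic is not deterministic across locales: "3 months" is 90 days and
"one year" is 365 days. Interval endpoints, which the clinical definition
leaves open, are pinned by unit tests: the outcome interval is half-open on
the left and closed on the right, `(index, index + 90]`; the lookback and
washout intervals are closed, `[index - 365, index]`. Patients whose data
end less than 90 days after the only eligible index date are excluded as
"insufficient follow-up" rather than mislabelled as controls.

## Encoding

Diagnosis codes are grouped to their first three characters (the ICD-10
category; ICD-9 codes are grouped by the same prefix rule, a choice pinned
by test). Medication names map to DrugBank identifiers through a lookup
table; unmapped names are dropped and counted. Laboratory events are
tokenized only when flagged ABNORMAL, HIGH or LOW, and only for analytes
with at least `min_lab_freq = 100` abnormal events cohort-wide; the
threshold is computed once, before any split, so the vocabulary does not
depend on the split. Token namespaces (`DX:`, `RX:`, `LAB:`, `SDOH:`,
`SEX:`, `RACE:`, `AGE:`, `THX:`) prevent collisions between modalities.

Continuous zip-level SDoH features are z-scored over the cohort and binned
into quintile tokens; ties share the rank of their first occurrence, so a
degenerate all-equal feature places everyone in Q1. The raw z-scored
vector is kept alongside the tokens for the regression-coefficient
analysis. Static tokens (demographics, SDoH quintiles, therapy flags) are
appended as one extra visit at the index date, which is how static context
enters a visit-sequence model without a separate input channel.

The vocabulary is frequency-ranked and truncated to `max_vocab` (default
30,000, far above what any synthetic cohort needs; index 0 is reserved for
padding). The grouped PTSD token is force-retained because the
contribution analysis scales to it. Out-of-vocabulary tokens are dropped
rather than mapped to an UNK placeholder, matching bag-of-codes EHR
practice; visits emptied by the drop are omitted and elapsed times
recomputed.

## Psychotherapy status from notes

Sentences containing a keyword phrase (cognitive processing therapy,
prolonged exposure, eye movement desensitization and reprocessing,
cognitive behavioral therapy) are extracted case-insensitively and
classified active/inactive by cosine similarity against anchor sentences:
a sentence is active iff its similarity to the nearest active anchor
exceeds that to the nearest inactive anchor by more than `margin`
(default 0) and reaches `threshold` (default 0.5); ties fall to inactive,
the conservative side. Negation and historical phrasing are handled by the
inactive anchors rather than a rule engine. Notes dated after the index
date are ignored, so the flags cannot leak outcome-era information.

The embedding backend is a pluggable contract: any deterministic
text-to-vector function works, e.g. a pre-trained 768-dimensional sentence
transformer. The package ships a deterministic character-trigram hashing
embedder so the full pipeline is reproducible bit-exactly with no trained
weights; it captures lexical overlap, not meaning, which is sufficient for
the template-structured notes the generator emits but would need replacing
with a trained encoder for real clinical text.

## Models

Three classifiers share one fitting interface (`seqrisk_fit()`):

* **TLSTM** — a stacked LSTM whose cell memory is decomposed before each
  step: a learned short-term component `tanh(W_d c + b_d)` is discounted by
  `g(dt) = 1/log(e + dt)` (dt in days since the previous visit) and
  recombined with the long-term remainder. When `dt <= 0` the adjustment is
  skipped entirely, so with all-zero gaps the network is *bit-identical* to
  a standard LSTM with the same weights — a limiting case used as an
  acceptance check. Visit embeddings are sums of token embeddings, hence
  order-free within a visit.
* **RETAIN** — two stacked-LSTM encoders scan the visit embeddings in
  reverse time order; one yields scalar visit-attention logits
  (softmax-normalized to weights that are non-negative and sum to one), the
  other coordinate-level attention vectors through `tanh`. The context
  vector is the attention-weighted sum of visit embeddings and a sigmoid
  head gives the risk. The attention weights are returned for
  interpretation.
* **LR** — logistic regression (via `stats::glm`) on bag-of-token counts
  plus the continuous SDoH covariates, providing the baseline and the
  coefficients for the repeated-split SDoH analysis.

The default architecture is the configuration common in deep EHR
frameworks: embedding 128, hidden size 128, dropout 0.2, depth 8 (for
RETAIN the depth is split 4+4 across the two encoders), input capacity
30,000, early-stopping patience 3. Dropout is applied between recurrent
layers and before the output head during training only, as inverted
dropout; the depth allocation and dropout placement are package choices
pinned in `model_config()`.

All forward and backward passes are implemented directly in R with
hand-derived gradients (verified against finite differences in the test
suite); training uses per-sample Adam on binary cross-entropy. Class
imbalance is left unweighted because the cohorts are near-balanced.
Early stopping follows the standard convention: training stops after
`patience` consecutive epochs without a new validation-AUROC best and the
best-validation weights are returned.

## Evaluation

Datasets are shuffled with a seeded permutation and split 8:1:1
(train/validation/test, sizes `floor(0.8n)` / `floor(0.1n)` / remainder),
one sample per patient so the split is patient-level. AUROC is the
normalized rank statistic with ties counted one half; precision, recall
and F1 use a 0.5 threshold, the conventional default.
`repeat_runs()` re-randomizes split and initialization seeds jointly and
reports per-repeat values with mean and sample (n-1) standard deviation,
mirroring the published metrics-table layout.

## Contribution analysis

The feature contribution (FC) of a token for one patient is the change in
predicted probability when every occurrence of the token is deleted from
the visit sequence and the forward pass is recomputed (occlusion). A
per-occurrence mode deletes one visit's occurrences at a time and sums the
deltas; all-at-once is the default. Per patient, FCs are normalized by the
sum of *absolute* raw FCs — absolute values so that signed contributions
cannot cancel into a near-zero denominator — giving signed shares whose
absolute values sum to one. This normalization also cancels the
probability-scale saturation factor shared by all of a patient's features,
which would otherwise shrink every contribution of confidently-predicted
patients.

The relative contribution (RC) of a token is the median normalized FC
among cases divided by the median among controls, then scaled so the
reference token (the grouped PTSD diagnosis) has RC exactly 1: after
scaling, RC > 1 marks risk-associated and RC < 1 protective features. A
zero control median leaves the RC undefined; such tokens are still
reported, with support counts and p value, never silently dropped.
Significance per token is the two-sided Wilcoxon rank-sum test comparing
case and control FC values — exact by full enumeration of group
assignments for combined n of 10 or fewer (valid under ties), otherwise
the normal approximation with midrank tie correction and continuity
correction — followed by Benjamini–Hochberg FDR adjustment at alpha 0.05 (BH rather
than the more conservative BY, since the features are positively
dependent at worst). Report rows are ranked by q ascending, then total
support descending, then token name — a deterministic tie-broken ordering
of "most supported, most significant first".

The repeated-split SDoH analysis refits the logistic model on ten
re-randomized splits and reports, per continuous covariate, the mean
coefficient, sample standard deviation and two-sided one-sample t-test
against zero (df = 9). A zero standard deviation across repeats yields an
NA p value flagged as degenerate rather than an exact zero.

## The synthetic cohort generator

Real EMR data of this kind are only available under data-use agreements,
so the generator is a first-class, tested module that defines the study
conditions for every end-to-end check. Per patient it draws a homogeneous
Poisson visit process (default 10 visits/patient-year over a 3-year span,
giving irregular gaps), sparse per-visit token occurrences, zip-code-level
SDoH values shared by patients of the same zip, and note text with
keyword sentences phrased as ongoing (active) or declined/historical
(inactive). The outcome is drawn from a logistic model on the *presence*
of planted tokens inside the one-year lookback of the generator's index
encounter plus SDoH and psychotherapy terms; positive draws place an ASUD
code uniformly inside the 90-day window. Ground truth (linear predictor,
outcome date, exposures) is stored separately from the timelines so no
pipeline stage can read labels. All randomness flows from one master seed
through per-patient child seeds, making output byte-identical across runs.

Default planted effects emulate a strong-signal EMR regime in which a
well-fitted sequence model attains test AUROC around 0.9 (the benchmark
run of `scripts/acceptance.R` measures this directly): one +2 and one -2
log-odds token, twelve ±1.5 tokens, four null tokens, SDoH coefficients
-1.2 (neighborhood SES) and -0.4 (vegetation index), psychotherapy effects
-0.8/-0.4, and intercept 0.4 yielding a near-balanced cohort (~51% cases).
The recurring PTSD diagnosis token carries +1.25: the reference-scaling
step presumes the reference feature has a stable, meaningfully nonzero
contribution, and a zero-effect reference would make the scale factor a
ratio of noise medians. Its per-visit rate matches the other planted
tokens so the models learn it at comparable fidelity.

What the generator does **not** emulate: realistic code vocabularies at
scale, correlated comorbidity structure, informative visit timing (visits
are independent of health state), free-text beyond keyword templates, and
measurement error in SDoH tables. Passing recovery tests therefore shows
the pipeline's statistics and optimization are correct under the stated
generative model, not that the models transfer to real EMR data.

## Numerical choices and degenerate inputs

* `dt <= 0` skips the TLSTM memory decomposition (exact LSTM limit).
* Softmax attention is computed with max-subtraction.
* Weight init: uniform ±1/sqrt(hidden) for recurrent weights, N(0, 0.1)
  embeddings, forget-gate bias 1.
* Predicted probabilities are clamped by 1e-12 inside the loss only.
* An encoding-emptied sequence predicts `sigmoid(b_out)` (zero hidden
  state / zero context), the model's no-information output.
* Quintile ties: rank-then-first-bin (all-equal features land in Q1).
* Exact Wilcoxon two-sided p: `min(1, 2 * min(P(W <= w), P(W >= w)))`.
* All-tied samples: p = 1. Zero-norm embeddings raise an error rather
  than silently classifying.

## Problem sizes used by tests and the acceptance script

Unit tests run on cohorts of tens to hundreds of patients. The end-to-end
benchmark uses 4,000 patients with a 2-layer, 16-unit RETAIN (a reduced
configuration of the default architecture chosen to keep a pure-R training
loop comfortably interactive), 15 epochs maximum, learning rate 0.005;
null-token false-positive control uses twenty replicated null simulations
of 300 patients each. These sizes are package choices for the standard
benchmark and are encoded in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`.

## Known limitations

* **Null features in mixed-signal cohorts.** The per-patient
  normalization divides by the patient's total contribution mass, which
  genuinely differs between classes whenever real effects exist. A truly
  outcome-independent token therefore has class-dependent *normalized*
  FC distributions, and with enough patients the rank-sum test will flag
  it. Type-I control should be assessed under replicated null simulations
  (where the test's null hypothesis actually holds), as the acceptance
  suite does; q values of weak features in strong-signal cohorts should
  be read with this caveat. This is a property of the published
  normalization scheme, which remains an active research area.
* Deep-model attributions are noisier than logistic-regression
  attributions at small sample sizes; RC magnitudes (not directions) vary
  across training seeds.
* The hashing embedder is lexical; real clinical notes need a trained
  sentence encoder behind the same contract.
* The pure-R training loop is practical to a few thousand patients and
  tens of visits; the default 128/128/8 architecture on very large
  cohorts would call for a compiled backend behind the same interfaces.
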
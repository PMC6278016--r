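---
title: "picosift: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{picosift: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picosift)
```

## The problem

Evidence-based medicine structures clinical questions as PICO:
Patient/Problem (P), Intervention (I), Comparison and Outcome (O).
Answering such questions from the literature requires locating, inside
each retrieved abstract, the sentence that states who was studied, what
was done to them, and what was measured. Treated as per-sentence
classification over the PIBOSO-style label set {Population,
Intervention, Outcome, Background, Study Design, Other}, the task is
hard for one structural reason above all: realistic corpora are heavily
skewed. In the kind of training material this package targets,
Population and Intervention sentences are rare (around 6.8% and 5.8% of
sentences) while Outcome sentences are abundant (around 36.6%). A
discriminative sequence model trained on such data has acceptable
precision but poor recall precisely on the two scarce classes, and the
problem is worst in unstructured abstracts, where no section headers
help it.

`picosift` implements a two-stage hybrid response to that diagnosis:

1. **Statistical stage (coarse-grained).** A feature-engineered
   linear-chain conditional random field (CRF) labels every sentence,
   with a repetition trick that widens its candidate sets, followed by a
   weighted assessment step that picks one sentence per element per
   abstract.
2. **Rule stage (fine-grained).** For abstracts where stage 1 produced
   *no* sentence for P or I (a "missed" abstract), hand-written rules
   over the same features propose one. The rules have high recall by
   construction, so the combination can only raise recall; stage 1
   selections are never overridden.

## The statistical stage

### Features

Each sentence is mapped to ten features:

| feature | meaning |
|---|---|
| f1 | count of demographic cue words (age/race/gender/group terms) |
| f2 | count of disorder terms |
| f3 | count of procedure/drug terms |
| f4 | count of outcome cue words |
| f5 | words shared with the title |
| f6 | words shared with the abstract keywords |
| f7 | normalized section header |
| f8 | sentence length in words |
| f9 | grouped structural position code |
| f10 | bag of `word|POS` unigrams |

Semantic counts (f1–f4) come from flat lexicon files rather than a
licensed terminology server: the shipped bundle has 60–80 terms per
category, which is sufficient for synthetic corpora and desk-scale
experiments, and `load_lexicons()` accepts richer user-supplied lists.
The outcome cue list in particular is the package's own construction.
Counts are fed to the model as *categorical* tokens (`MPt_3`, `MP_2`,
`MI_4`, `MT_2`) rather than raw numbers: a sequence of numeric values
disperses the model's alphabet, while the category-with-frequency form
keeps equal evidence levels in a single shared feature.

Two structural normalizations matter:

* **Header standardization.** Real structured abstracts use dozens of
  header variants; all are mapped onto OBJECTIVE / METHOD / RESULTS /
  CONCLUSION by a user-extensible table (`default_header_map()`).
  Unknown variants degrade to NOHEADING with a warning rather than
  failing.
* **Structural grouping.** The header and the sentence number are
  reconciled into one code per section — OBJECTIVE 3, METHOD 6,
  RESULTS 12, CONCLUSION 14 — so that every sentence of a section shares
  a single positional feature instead of scattering over raw indices.
  The codes sit near the cumulative average section sizes and are
  monotone in document order. For unstructured abstracts (no header) the
  raw index, capped at 14, is kept so that position information
  survives; this is the package's own choice for a case the grouping
  scheme leaves open.
* **Pseudo-structuring (training only).** Unstructured training
  abstracts get headers assigned from their gold labels (Background to
  OBJECTIVE; Population/Intervention/StudyDesign to METHOD; Outcome to
  RESULTS; Other to CONCLUSION), so their structural features carry the
  same information as structured ones. At test time gold labels are
  obviously unavailable, and unstructured abstracts keep NOHEADING —
  pseudo-structuring validation folds would leak labels into features.

### Model

The CRF assigns a label sequence $Y$ to the sentence sequence $X$ of an
abstract through
$P(Y\mid X) = \frac{1}{Z_X}\exp\sum_{t}\sum_k \lambda_k f_k(y_{t-1}, y_t, x, t)$,
with emission features tying each observation token to each label and a
full transition matrix between adjacent labels. Weights are estimated by
penalized maximum likelihood — a Gaussian prior with variance 10 (the
`crf_config()` default; smaller variance suits cleaner corpora) — using
L-BFGS with the analytic gradient from forward–backward. The
forward–backward and Viterbi recursions are implemented in C++ in the
log domain; Viterbi ties break toward the lower label index so decoding
is fully deterministic. No CRF implementation was available among the
package's permitted dependencies, so the estimator is part of the
package; it is deliberately standard.

Training sentences with several gold labels appear once per label,
duplicated in place — the "standard layout" of the exported training
file format (`write_feature_file()`), which also offers the redundant
0/1-prediction layout for comparison experiments.

### Repetition at test time

Each test sentence is duplicated three times consecutively before
decoding (`test_repetitions = 3`, one repetition per class of interest).
Identical copies can receive different Viterbi labels only through the
transition weights, which is exactly the point: the union of the copies'
labels is a *candidate set* wider than a single argmax, raising the
chance that the right label for a scarce class is present. The
aggregation across copies is this package's design: the candidate set is
defined as the plain (unrepeated) decode union the copies' labels, which
guarantees that repetition only ever adds candidates and reduces exactly
to plain decoding at `reps = 1`. The selection step, not the decoder,
arbitrates among candidates.

### Selection

When several sentences of an abstract are candidates for the same
element, each is scored with
`wTotal = wPoM + wPoT + wCo + wSe`:

* `wPoM` = 2 if the sentence is where the element typically lives
  (METHOD section, or first third of an unstructured abstract, for P
  and I; RESULTS or last third for O), else 0. The weights 2/0 slightly
  favour typical positions without letting position dominate.
* `wPoT` = f5 (title overlap).
* `wCo` = 2 if POPULATION and INTERVENTION are both in the candidate
  set (for P and I scoring; 0 for O).
* `wSe` = semantic evidence: f1 + f2 for P, f3 for I, f4 for O.

The highest total wins; ties break to the earliest sentence, since PICO
statements tend to open their sections — an unstated case fixed here for
determinism. The O-element variant (RESULTS / last third, `wSe = f4`,
no coexistence bonus) is this package's construction by symmetry with
the P and I rules. An element with no candidate anywhere in the
abstract is *missed* and handed to stage 2.

## The rule stage

Only P and I have fallback rules (Outcome is abundant enough that the
CRF rarely misses it). Each rule is a disjunction of three conjunctive
clauses — strong semantic evidence anywhere; weak evidence in METHOD;
weak evidence in the first three sentences of an unstructured abstract:

* **P**: `f1 ≥ 3 or f2 ≥ 3`, or `(f1 ≥ 1 or f2 ≥ 1) and header = METHOD`,
  or `f2 ≥ 1 and header = NOHEADING and index < 4`.
* **I**: `f3 ≥ 3`, or `f3 ≥ 1 and header = METHOD`, or
  `f3 ≥ 1 and header = NOHEADING and index < 4`.

The threshold 3 is the average semantic count observed in Population
sentences; both thresholds are configurable (`rbm_thresholds()`), and
lowering the strong threshold can only grow the hit set. `index < 4`
with 1-based indices means "the first three sentences", where P and I
usually sit in unstructured abstracts. When several sentences fire a
rule, the stage-1 scorer arbitrates among them (with the rule hits as
the candidate set); when none fires, the element stays missing — a
not-applicable outcome rather than a forced guess. The stage is applied
only to elements stage 1 missed, so combined recall is never below
CRF-only recall.

## Evaluation

`evaluate()` reports TP/FP/FN and precision/recall/F per element at two
granularities, and every report names its mode, because the two answer
different questions:

* `sentence_level` — every (sentence, element) pair counts; measures the
  classifier.
* `abstract_level` — one selected sentence per element per abstract; a
  TP requires the selected sentence to actually carry the gold label;
  a selected sentence with several gold labels counts for each matching
  element. Measures the extraction system a user sees.

Zero-denominator precision or recall is reported as `NA` (a flag), never
silently coerced to 0. `cross_validate()` folds at the abstract level so
no abstract straddles folds, deterministically from its seed.

## The synthetic corpus generator

`generator_spec()` encodes the study conditions the pipeline assumes,
and its defaults are fixed, not tuning knobs: the skewed label mix
(P 6.8%, I 5.8%, O 36.6%, Other 27.9%, Study Design 2.0%, Background
20.9%), a 314/800 structured fraction, 6–12 sentences per abstract and
8–25 words per sentence, a 0.3 chance that a structured section shows a
variant header rather than its common form, and a 0.05 chance that a
Population sentence also carries the Intervention label (and vice
versa). Sentence and abstract counts and the signal strength are the
experiment-level inputs.

The one free axis is **signal strength** `s`: with probability `s` a
sentence of class c draws 2–4 terms from c's lexicon and sits in its
typical location (its section in structured abstracts; the first three
sentences for P/I, the last third for O, in unstructured ones), and
titles are assembled from the abstract's P/I terms so title overlap is
informative. With probability `1 − s` it is plain filler, and 10% of all
sentences gain one random lexicon term irrespective of label, so lexical
evidence is never perfectly class-pure. At `s = 0` the labels are
independent of the text by construction; at `s = 1` every Population
sentence provably contains demographic or disorder terms and sits in
METHOD or the first third.

What the generator does *not* emulate is real biomedical language:
sentences are bags of filler around planted terms, with none of the
syntax, anaphora, hedging or out-of-lexicon synonymy that make real
abstracts hard. Passing tests on synthetic corpora therefore validate
the machinery — feature extraction, estimation, decoding, selection,
rules, evaluation — under the assumed statistical structure; they do not
certify performance on real corpora, which depends on lexicon coverage
and annotation quality.

## Numerical and degenerate-input choices

* Thirds boundaries use ceilings: first third is `index ≤ ⌈n/3⌉`, last
  third `index > ⌈2n/3⌉`; abstracts under three sentences are all
  first-third. One convention is used everywhere (position feature,
  selection, generator).
* L-BFGS runs for at most 200 iterations (default) with a relative
  function tolerance of about 1e-6; both are configurable. Weights start
  at zero, so training is deterministic; the only seeded step is
  training-set subsampling when `training_proportion < 1`.
* Unknown observation tokens at test time are dropped (the bias feature
  keeps every position scored); empty sentences are an error at feature
  extraction, not a silent skip.
* Rectified text marks protected periods with a same-width sentinel that
  segmentation restores, so offsets are preserved and joining the
  segmented sentences reproduces the input modulo whitespace.

## Problem sizes used by the test-suite and acceptance script

The shipped checks run entirely on generated corpora, at sizes chosen to
exercise the claimed properties cleanly: the signal-recovery experiment
uses 1000 abstracts (800 train / 200 held out) at `s = 0.9`; the
recall-ordering and hybrid-gain checks use 150–250 abstracts at
`s = 0.7` over multiple seeds; the chance-floor check uses 250 abstracts
at `s = 0`; monotonicity and repetition properties run over 10–20 small
seeded corpora. These sizes are the package's own choices and are stated
here so that anyone rescaling them knows what was actually measured.

## Known limitations

* The lexicons are compact stand-ins; real deployments need real
  terminology resources, and f1–f4 are only as good as the supplied
  lists. There is no concept normalization, negation or context
  detection.
* The POS tagger is a suffix heuristic feeding f10; it is not a
  reference tagger.
* No fallback rule exists for Outcome, and the Comparison element of
  PICO is not modelled at all (it is absent from the label set).
* Multi-label training sentences are handled by in-place duplication,
  which slightly inflates the effective length of their sequences.
* The repetition trick widens candidate sets but cannot rank them; its
  value depends entirely on the downstream selection step.
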
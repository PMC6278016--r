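# picosift

Hybrid CRF + rule-based extraction of PICO sentences from medical
abstracts.

Evidence-based medicine phrases clinical questions in terms of
Patient/Problem (P), Intervention (I) and Outcome (O). Answering them
from the literature means finding, in each abstract, the sentence that
says who was studied, what was done and what was measured. `picosift`
does this in two stages, built for the situation that makes the task
hard in practice: corpora in which Population and Intervention sentences
are rare (~6.8% and ~5.8% of sentences) while Outcome sentences are
abundant (~36.6%), and in which half the abstracts have no section
headers.

1. **Statistical stage.** A linear-chain conditional random field labels
   each sentence of an abstract via
   $P(Y\mid X)=\tfrac{1}{Z_X}\exp\sum_t\sum_k\lambda_k f_k(y_{t-1},y_t,x,t)$,
   over ten engineered features per sentence (lexicon-based semantic
   counts, title/keyword overlap, normalized section header, grouped
   structural position, length, `word|POS` bag-of-words), with a
   Gaussian prior of variance 10 and 3-fold test-sentence repetition to
   widen candidate sets. A weighted assessment
   `wTotal = wPoM + wPoT + wCo + wSe` (position, title overlap, P/I
   coexistence, semantic evidence) then selects one sentence per element
   per abstract.
2. **Rule stage.** Abstracts where stage 1 found no P or I sentence are
   handed to high-recall rules over the same features, e.g. for P:
   `f1 ≥ 3 or f2 ≥ 3`, or weak evidence (`≥ 1`) in a METHOD section, or
   `f2 ≥ 1` among the first three sentences of an unstructured abstract.
   The rules only fill gaps — a stage-1 selection is never overridden —
   so combined recall can only increase.

The package also provides corpus I/O for a documented JSON/CSV schema,
abbreviation-aware sentence segmentation, section-header normalization,
precision/recall/F evaluation at sentence and abstract level with
5-fold cross-validation, and a synthetic-corpus generator that
reproduces the skewed label mix and structured/unstructured blend, so
the whole pipeline is testable without any external corpus. See the
methods vignette (`vignettes/picosift-methods.Rmd`) for the model,
parameter and design details.

## Worked example

```r
library(picosift)

corpus <- generate_corpus(generator_spec(n_abstracts = 100,
                                         signal_strength = 0.9, seed = 7))
parts  <- split_train_test(corpus, sprintf("SYN%04d", 1:75))
fit    <- train_pipeline(parts$train, pico_config())
result <- run_hybrid(parts$test, fit)

print(result$reports$sentence_level)
print(result$reports$combined)
```

```
<pico_eval> mode: sentence_level 
 element tp fp fn precision recall f_score
       P  9 14  1     0.391  0.900   0.545
       I  9  6  3     0.600  0.750   0.667
       O 63 15 14     0.808  0.818   0.813
<pico_eval> mode: abstract_level 
 element tp fp fn precision recall f_score
       P  7  9  1     0.438  0.875   0.583
       I  8  4  1     0.667  0.889   0.762
       O 24  1  1     0.960  0.960   0.960
missed abstracts: P=9, I=13, O=0
```

Reading this: at the sentence level the CRF's 3-fold repetition
deliberately over-generates candidates for the scarce classes (high
recall, modest precision for P). The abstract-level report shows what a
user sees after selection and the rule fallback: for 25 held-out
abstracts, the chosen Population sentence was right in 7 of the 16
abstracts where one was claimed, Outcome extraction is near-perfect, and
"missed abstracts" counts abstracts where an element was never claimed —
most of which simply contain no such sentence (only 8 of these 25
abstracts have a gold Population sentence).

A thin command-line front end over the same functions lives at
`inst/cli/picosift.R`, with `simulate`, `train`, `extract` and
`evaluate` subcommands.

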
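---
title: "Character-level NER for adverse drug reactions: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Character-level NER for adverse drug reactions: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrner)
```

## The problem

Chinese drug descriptions (package inserts, drug-information portals)
mention three kinds of entities that matter for pharmacovigilance: drug
names (DRN), drug components (COM), and adverse drug reactions (ADR).
`adrner` implements the full pipeline for extracting them: corpus
construction by distant supervision against typed lexicons, a
character-level neural sequence labeler (embedding or ALBERT-style
transformer encoder, BiLSTM, linear-chain CRF), and entity-level
evaluation. Chinese has no word boundaries, so every operation is defined
per Unicode character; punctuation and ASCII characters are tokens too.

## Distant supervision

Manual annotation of drug text is expensive, so the corpus builder labels
text automatically by matching lexicon entries. Each sentence (split at
the ideographic full stop `。`, which stays with its sentence; commas do
not split) is scanned left to right; at each position the longest
matching lexicon surface wins, emits `B-X` followed by `I-X` labels, and
the scan resumes after the match, so spans never overlap. Three choices
here are deliberate and documented rather than inherited:

* **Greedy leftmost-longest matching.** Drug names very often extend a
  component name by a dose form (`联苯双酯片` = `联苯双酯` + `片`), so
  longest-match is what makes the drug name win at its own position.
* **Type priority DRN > COM > ADR at equal length.** Input-method
  lexicons overlap; the same surface can be listed under two types. A
  fixed priority makes annotation reproducible. Which type the original
  corpus used in this situation is unknowable from the outside; this is
  our documented convention.
* **Exact code-point matching, no normalisation** beyond trimming
  whitespace, so a corpus built twice from the same inputs is identical.

The lexicon index is a first-character bucket table with entries sorted
by decreasing length: a longest-match query touches only entries sharing
the query position's first character, keeping repeated queries cheap
while an exhaustive-scan oracle defines correctness in the tests.

Whether the original annotation scanned whole records or individual
sentences is unstated in the sources describing this family of pipelines;
we scan per sentence, since no lexicon surface contains a sentence
terminator, which makes the two readings equivalent.

## The sequence labeler

The model is the classic three-layer assembly:

1. **Input representation.** A trainable character embedding (width `E`,
   default 128; PAD is id 0 with a frozen zero row, UNK is id 1). An
   optional transformer-style encoder sits on top, with the two ALBERT
   parameter-reduction mechanisms: *factorized embedding* (characters
   embedded at width `E`, then projected to the hidden width `H`, so the
   vocabulary-sized table stays small) and *cross-layer parameter
   sharing* (one parameter collection referenced at every depth, making
   the parameter count independent of the number of layers — the package
   verifies this by enumeration). Attention is scaled dot-product
   `softmax(QK'/sqrt(d_k))V`; following standard practice `d_k` is the
   per-head width, not the full input width. Residual connections and
   layer normalisation follow the standard transformer encoder block.
   The shipped default is the plain embedding; the transformer encoder is
   a fixed featurizer (its weights are initialised, used in the forward
   pass, and not updated — fine-tuning pretrained checkpoints is out of
   scope for an offline-buildable package).
2. **Context encoding.** A BiLSTM with hidden width 100 by default: two
   completely independent LSTMs, one per direction, whose states are
   spliced position by position into a `2H` vector. The LSTM cell is the
   standard gated recurrence (forget gate, input gate, candidate state,
   output gate, elementwise products); zero initial states. The forget
   gate is what lets the cell state ("transmission band") carry
   information across long spans.
3. **Label decoding.** A linear projection maps the `2H` output to one
   emission score per label, and a linear-chain CRF scores a label
   sequence as emissions plus adjacent-label transition scores, with
   explicit START/STOP boundary states (transitions into START and out
   of STOP are `-Inf`, so they never occur on a valid path). The CRF is
   what lets the model learn that, e.g., `I-DRN` cannot follow `B-ADR`.
   Hard BIO constraints are off by default — the transition matrix
   learns them — with `constrain_bio()` available to force illegal
   bigrams to `-1e4`.

All CRF computation is in log space with log-sum-exp stabilisation; the
partition function uses the forward recursion, decoding uses Viterbi
with ties broken toward the lowest label index (determinism matters for
testing), and the training loss is the exact negative log-likelihood
with analytic gradients from forward--backward marginals. Tests check
all four quantities against exhaustive enumeration on small instances
and the gradients against central finite differences.

## Training protocol

`train_tagger()` minimises the mean sentence NLL with Adam
(β₁ = 0.9, β₂ = 0.999, ε = 1e-8 — the de-facto optimizer for this
architecture family; the reference protocol names only learning rates).
Defaults in `train_config()`: maximum sequence length 128 characters
(longer sentences are hard-split, and entities cut at a boundary are
counted in a warning), batch size 128, 7 epochs, dropout 0.5, two
learning-rate groups (5e-5 for a fine-tuned pretrained encoder, 1e-3
for everything else; with the plain embedding encoder, everything —
including the embedding — trains at the 1e-3 rate, since the tiny rate
only makes sense for pretrained weights). Dropout is applied to the
BiLSTM output before the projection, during training only; placement is
our choice, the protocol fixes only the rate. Batches are padded to
their longest member; padded positions are masked out of the BiLSTM
state updates, the CRF, and the embedding gradient. After every epoch
the model is scored on the validation set (entity-level micro F1) and
the best epoch's snapshot is returned — the fixed epoch budget and
best-epoch selection are both honoured, since reference reports of this
protocol are ambiguous about which was deployed. With a fixed seed the
whole procedure, dropout included, is bit-reproducible.

## Evaluation

Entity-level scoring with exact span-and-type matching, one-to-one: a
prediction is a true positive only if an unmatched gold entity has the
same type, start and end (and sentence). Precision `TP/(TP+FP)`, recall
`TP/(TP+FN)`, `F1 = 2PR/(P+R)`, per type and micro-averaged over pooled
counts; zero denominators yield 0 by convention (degenerate cases must
not crash a run). Exact matching is the strictest reading consistent
with entity-level reporting; no partial credit is given. Note that some
published descriptions of the TP/FP/FN vocabulary swap the wordings of
FP and FN; the formulas above are the standard ones and are what the
package implements. Presentation rounding is half-up to two decimals
(`round_half_up()`), matching how such tables are conventionally
printed; `report_table()` holds full-precision values until rendering.

The package ships a benchmark score table
(`inst/extdata/benchmark_scores.tsv`) with the published
precision/recall/F1 of the three model variants (BiLSTM-CRF,
BERT-BiLSTM-CRF, ALBERT-BiLSTM-CRF) on a 12,977-record Chinese ADR
corpus. The tests verify that every printed triple is harmonically
consistent at its printed precision (|2PR/(P+R) − F1| < 0.01; three of
the fifteen triples differ by up to 0.006 because the published P and R
are themselves rounded, so sub-0.005 agreement is not attainable from
the printed values).

## The synthetic-data generator

Training the full model on its original corpus requires that corpus and
pretrained Chinese checkpoints; neither is shipped. Instead `gen_config()`
/ `gen_lexicon()` / `gen_corpus()` generate data with the structural
statistics that matter to the pipeline:

* lexicon surfaces built from a fixed CJK syllable inventory, with half
  of the drug names (configurable) extending a component surface by a
  dose-form suffix — the prefix-collision phenomenon that makes
  longest-match and type priority load-bearing;
* records shaped `DRN:COM。` followed by adverse-reaction clauses, with
  record lengths normal around 148 characters (the average drug-record
  length the generator emulates);
* filler characters drawn from an inventory *disjoint* from all surface
  syllables, so every lexicon occurrence is intentional and the
  generation-time gold is exact — with zero noise, distant supervision
  reproduces the gold labels character for character (a cross-module
  identity the tests assert);
* a noise rate that withholds a fraction of inserted mentions from the
  gold (the mention stays in the text), emulating lexicon
  incompleteness. Noise is never injected as wrong lexicon entries, so
  the learning-capacity experiment below stays interpretable.

What the generator does **not** emulate: real lexical diversity,
synonymy ("增加" vs "升高"), vague ADR wording, OCR noise, or entity
mentions embedded in running prose without punctuation cues. Passing
the capacity test therefore shows that the architecture, gradients and
decoding work — not that the model reaches any particular accuracy on
real drug text.

## The learning-capacity experiment

The calibration experiment trains the small configuration (embedding
encoder `E = 32`, hidden 32, batch 16, learning rate 1e-2, ≤ 30 epochs,
dropout 0) on 300 zero-noise synthetic sentences over a 20/20/20
lexicon, split 6:2:2. A correct implementation memorises the training
set (entity F1 ≥ 99%) and generalises to held-out sentences built from
the same lexicon (F1 ≥ 90%); both margins hold comfortably across seeds
in our runs (typically 99–100%). The experiment takes well under a
minute on one CPU; these problem sizes are the package's chosen desk
scale for a fast, deterministic test suite.

## Numerical and degenerate-input choices

* Parameter initialisation Uniform(−0.1, 0.1), seeded; LSTM biases zero;
  layer-norm gain 1 / offset 0. All `set.seed` use is localised and the
  caller's RNG state is restored.
* `logsumexp` guards all-`-Inf` columns (structurally forbidden paths).
* Viterbi tie-break: lowest label index at every backpointer step.
* Zero-length inputs: empty lexicons and empty corpora are legal
  everywhere; a zero-length sentence is not (the CRF needs n ≥ 1).
* The 6:2:2 split cuts at `floor(0.6n)` and `floor(0.8n)` after a seeded
  shuffle (12,977 sentences → 7786/2595/2596); whether the original
  protocol shuffled is unstated, so the seed is recorded in the split
  object.

## Known limitations

* No pretrained-checkpoint loading; the transformer encoder trains
  nothing and the embedding path is the practical default. Reproducing
  published benchmark F1 on real corpora is therefore out of reach by
  design; the package's claims are the arithmetic and algorithmic ones
  its tests compute.
* Single-threaded, pure-R training: suitable for desk-scale corpora
  (hundreds to a few thousand short sentences), not for 10k+ records
  with BASE-size encoders.
* BIO only (no BIOES), exact-match evaluation only (no overlap credit),
  first-order CRF only.
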
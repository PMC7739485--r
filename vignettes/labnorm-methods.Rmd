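---
title: "Normalizing laboratory indicator names: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing laboratory indicator names: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Electronic health records from different hospitals name the same
laboratory examination item in many ways. In Chinese EHR data two
mechanisms dominate: *translation* variation (one analyte has several
accepted Chinese renderings) and *habit* variation (sites or physicians
reword, reorder, abbreviate or extend names). Analyses that group records
by indicator name silently drop every record filed under an unrecognized
synonym, so a normalization step — mapping each non-standard surface form
onto exactly one expert-designated standard indicator — is a prerequisite
for cross-hospital clinical analysis.

`labnorm` implements a two-stage normalization pipeline plus an annotation
-cost-reduction loop:

1. **Recall** (`generateCandidates()`): a character-level tf-idf retriever
   scores every standard indicator against each non-standard query and
   keeps a small candidate set — the union of the top-`k1` matches on the
   name field and the top-`k2` matches on the abbreviation field
   (defaults `k1 = 15`, `k2 = 5`). This shrinks the comparison space from
   |standards| to at most `k1 + k2` per query while keeping the true
   standard in the set with high probability.
2. **Classification** (`trainEsim()`, `classifyCandidates()`): an enhanced
   sequential inference model (ESIM) decides, per candidate pair, whether
   the two texts are synonymous, producing a probability `p_match`.
3. **Active learning** (`runALLoop()`): pool-based selection of which
   candidate sets to send to annotators, scored by per-set uncertainty
   (least confidence, Shannon entropy, or the gini index `2p(1-p)`),
   each averaged over the set to remove the length bias.

## Retrieval stage

Documents are the standards' channel values (name or abbreviation), one
token per unicode character after NFKC normalization and latin
lowercasing. Weights follow

  tf(d, w) = f(w, d) / |d|,  idf(w) = log(|D| / (N_w + 1)),

with the natural logarithm. Two consequences of this idf form are kept
deliberately: a token occurring in every document of a small corpus gets a
*negative* weight, and a corpus where every token occurs in all-but-one
document can produce all-zero vectors. Both are preserved as the formula
states them (the degenerate cases only matter for toy corpora; `show()` on
an index warns when negative idf is present).

Document and query vectors are L2-normalized, so the scoring dot product
is cosine similarity. Unnormalized dot products would let long standards
dominate every ranking and break the property that a query textually
identical to a standard retrieves it first with score 1 — a property the
test suite checks, and the basis of several degenerate-input guarantees.
Ties in `topK()` are broken by ascending standard id so rankings are
deterministic. Out-of-vocabulary characters contribute nothing.

Three reference retrievers ship for comparison: normalized edit-distance
similarity (`1 - lev/max(len)`), bag-of-characters cosine, and Okapi BM25
(`k1 = 1.5`, `b = 0.75`, the nonnegative `+1` idf variant) — conventional
parameter choices, since no values are prescribed for this task.
Retrieval is evaluated with recall@k and mean reciprocal rank; the rank is
taken over the merged, score-sorted candidate set, and a gold standard
missing from its set contributes reciprocal rank 0.

## Classifier

Query `a` is the non-standard indicator, hypothesis `b` the standard; each
is the concatenation of its name and (when present) abbreviation, so one
model serves both fields. Tokenization is character-level with a trainable
embedding table — the same unit as retrieval, and it avoids a Chinese word
-segmenter dependency.

The architecture is the standard ESIM stack: BiLSTM input encoding;
soft attention with scores `e[i, j] = â_i · b̂_j`; aligned representations
(row/column softmax-weighted sums); enhancement `[x; x̃; x − x̃; x ⊙ x̃]`;
a ReLU feedforward projection back to the hidden width followed by a
second BiLSTM composition; masked average and max pooling concatenated
to a fixed vector; a one-hidden-layer tanh MLP with two-way softmax.
Cross-entropy is the training loss, optimized by minibatch SGD.

Design choices the equations leave open:

* **Composition projection.** The enhancement quadruples the
  representation width, and composing it directly makes the composition
  BiLSTMs carry almost the entire parameter count, which overfits badly on
  corpora of a few hundred indicators. The default
  (`use_projection = TRUE`) therefore projects the enhanced vectors back
  to the hidden width with a ReLU feedforward layer before composition —
  the arrangement the original ESIM uses to control complexity.
  `use_projection = FALSE` composes the enhanced representation directly.
* **Weight sharing.** By default (`tie_weights = TRUE`) the query and
  hypothesis sides share their encoder and composer BiLSTMs, as in the
  original ESIM formulation. This is a deliberate choice with a large
  practical effect at small training scale: shared weights place both
  texts in a single representation space, so the attention dot product
  recognizes matching characters even in combinations never seen in
  training. With fully separate per-side parameter sets (available via
  `tie_weights = FALSE`) the model can fit the training pairs but
  generalizes much worse on corpora of a few hundred indicators.
* **Optimizer.** SGD with classical momentum (default 0.9;
  `momentum = 0` gives plain SGD) and an optional step learning-rate decay
  (halving every 20 epochs by default). Plain fixed-rate SGD stalls for
  many epochs at the base-rate plateau on this task's imbalanced pair
  data; momentum removes the stall without leaving the SGD family.
* **Initialization.** Glorot-uniform weight matrices, uniform(-0.5, 0.5)
  embeddings, forget-gate biases at 1, and a zeroed softmax head — the
  last so an untrained model predicts exactly `p_match = 0.5`, which the
  tests use as a fixed point, and the first epoch's loss starts at ln 2 on
  balanced data.
* **Masking.** Padding (token id 0) is stripped before the forward pass:
  padded positions receive no attention weight and are excluded from both
  poolings, so appending padding never changes a prediction.
* **MLP head.** One hidden tanh layer; "multilayer perceptron" is
  otherwise unconstrained. Dropout (default 0.2) applies to the pooled
  vector and the hidden layer during training only.
* **Training pairs.** Positives are (non-standard, gold standard) pairs
  whose gold was recalled into the candidate set; every other candidate of
  a labeled query is a negative. This reproduces the natural imbalance the
  recall stage creates (roughly one positive per candidate-set size).
  `buildTrainingPairs(negative_ratio =)` optionally downsamples negatives.
* **Decision threshold.** `classifyCandidates()` defaults to 0.5. The
  end-to-end pipeline instead selects the threshold maximizing F1 on its
  validation pairs (never the test side): the classifier's probabilities
  are not calibrated under the heavy pair imbalance, and the
  edit-similarity reference baseline already gets a threshold tuned on
  training data, so a fixed 0.5 would bias the comparison. In all cases
  every candidate above threshold is returned ranked by probability, with
  unmapped queries reported, leaving one-vs-many resolution to the
  consumer.

The compiled core is verified two ways: every block (attention weights,
alignment, enhancement, pooling) is compared against independent plain-R
implementations, and the full analytic gradient is checked against central
finite differences over all parameter groups, tied and untied.

## Active learning

The loop is pool-based simulation: gold labels stand in for the expert
annotator. Each round selects `B` candidate sets (default 100; the first
round is always a uniform random draw, since an untrained model has no
meaningful uncertainty), reveals their labels, retrains the classifier on
all revealed pairs — from scratch by default, or continuing from the
previous round's parameters with `warm_start = TRUE` — evaluates
pair-level F1 on a fixed held-out test split, and scores the remaining
pool with the chosen strategy. The package's own strategy-comparison
study warm-starts: at desk scale, a from-scratch retraining on a few
dozen labeled sets is dominated by the initialization lottery (some
retrainings never leave the all-negative plateau), and that variance
swamps the differences between selection strategies. Warm starting with
a fixed per-round update budget removes the lottery, lets competence
accumulate across rounds so the uncertainty estimates carry signal, and
is also what a practitioner would run for cost reasons. Uncertainties are
means over each candidate set's predictions, which removes the bias that
longer sets would otherwise accumulate. Entropy uses the natural log — the
base rescales all scores by one constant and never changes a selection.
Selection ties break by ascending candidate-set id, making selection
invariant to presentation order; every source of randomness is seeded.

`compareALStrategies()` packages the full experiment: all four strategies
(random baseline included) across replicate seeds on one shared split,
plus a per-seed full-pool reference model, so learning curves can be
summarized as area-under-curve and as the labeled fraction needed to reach
a given fraction of the full-data F1 (`fractionToReach()`).

## Synthetic corpora

Hospital indicator lists with expert gold mappings are not publicly
available, so `generateCorpus()` fabricates corpora that reproduce the
*statistical* structure driving the method, with no attempt at clinically
meaningful Chinese:

* Standard names are sequences of 2–4 multi-character concept tokens
  (`name_tokens_min`/`name_tokens_max`) over a compact CJK character
  pool. The pool grows sublinearly with corpus
  size (about `8 * sqrt(n_standard)` characters): real indicator
  vocabularies reuse a small clinical character set heavily, which is both
  why character-level retrieval works and why candidate sets contain
  confusable distractors.
* **Translation variants**: `synonym_table_size` token groups (default 40)
  of interchangeable renderings. Group tokens are deliberately frequent —
  about half of all name positions — because concepts with competing
  translations are common concepts; alternates are drawn with skewed
  (1/rank) preference, mirroring how one alternative rendering usually
  dominates in practice. Swaps happen per occurrence with
  `synonym_swap_rate` (default 0.4).
* **Habit variants**: with `habit_rate` (default 0.3) a variant gets an
  adjacent-token swap, a tail-token drop, or a prepended modifier token.
* **Character noise**: per-character substitution/deletion/insertion at
  `char_edit_rate` (default 0.05).
* **Abbreviation noise**: absent with `abbrev_missing_rate` (default 0.2),
  otherwise perturbed (truncation, letter edits) with
  `abbrev_perturb_rate` (default 0.3).

Every variant links to exactly one standard (the normalization model is
one-to-one), rates of zero reproduce the standard exactly, and any nonzero
name noise guarantees the variant differs from its standard. Generation is
fully seeded and byte-reproducible.

What the generator does **not** emulate: real synonym phenomena that share
no surface characters (pure semantic synonyms), reference-value or unit
fields, hospital-specific numeric codes, and the scale of a real platform
(tens of thousands of indicators). Passing tests on these corpora
demonstrate that the pipeline's machinery works and that its comparative
claims (tf-idf vs simpler retrievers, uncertainty sampling vs random) hold
under the emulated noise structure — not that the absolute metric values
transfer to any particular hospital dataset.

## Study fixtures and problem sizes

All package-level analyses run on two fixed corpora (`fixtureSpec()`):

* `benchmark` — 200 standards, 1–6 variants each (≈660 non-standards),
  default noise, seed 20201215; also shipped as
  `inst/extdata/fixture_corpus.tsv`. Used for retrieval comparisons (both
  name-only and name+abbreviation settings), classifier evaluation under a
  seeded 7:3 indicator-level split, and the two reference baselines: an
  unconditional map-to-top-1-candidate rule, and an edit-similarity
  threshold classifier whose threshold is tuned on the same validation
  pairs the classifier's operating point is selected on (matched
  model-selection data for both systems).
  The classifier for this corpus uses embedding/hidden width 64, MLP 128,
  20 epochs (batch 16, learning rate halved every 10 epochs) — the
  schedule with the best validation F1 among those tried, sized so the
  full pipeline trains in a few minutes on one CPU. A 15% slice of the
  train split serves as validation for best-epoch selection and threshold
  choice; the final model is then refit on train+validation at the
  selected epoch count, the usual final-model protocol. The zero-noise
  control run keeps the plain 0.5 threshold — it checks the classifier's
  degenerate-input behavior, not operating-point selection.
* `active_learning` — 120 standards, 1–4 variants each with 2–3 concept
  tokens per name, seed 20201216; batch size 20, 10 rounds, 5 replicate
  seeds, split seed 1. Retrainings warm-start from the previous round
  (embedding/hidden 24, MLP 48, learning rate 0.05, at least 400 SGD
  updates per round, negatives downsampled 3:1); the full-data reference
  model gets the same cumulative update budget as one whole loop. See
  the discussion above for why the comparison is run warm-started.

The indicator-level 7:3 split (never pair-level) prevents a query's other
candidates from leaking across the split. The evaluation convention for
degenerate cases: with zero predicted positives, precision and F1 are
reported as 0.

## Known limitations

* Synonymy evidence is purely textual; a variant whose rewording shares no
  characters (and no recurring synonym-group pattern learnable from the
  training pairs) with its standard is irrecoverable by construction for
  both stages.
* The classifier is trained per corpus; no pretrained language model or
  cross-corpus transfer is attempted (a deliberate scope choice — the
  pipeline targets settings where a large pretrained stack is
  unavailable or too heavy).
* Thresholded mapping can return several standards above threshold;
  the package reports them ranked rather than forcing a unique decision.
* The gini/entropy/least-confidence scores are equivalent up to
  monotone transforms for a *single* prediction; their selections differ
  only through the per-set averaging, so strategy differences are
  expected to be modest and seed-dependent on small corpora.
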
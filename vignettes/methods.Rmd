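---
title: "Multimodal relation extraction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal relation extraction: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ctxrel` extracts *context-specific molecular relations* from biomedical
sentences: statements of the form "molecule A increases molecule B in
disease C". The task is framed as 8-way sentence classification — Increase,
Decrease, Regulate and Binding, the first three split by textual direction
(forward when the causal agent is mentioned before the affected molecule,
backward otherwise), plus a False class for co-occurring entities with no
asserted relation. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic generators do and do not emulate,
and the choices we made where the design was genuinely open.

## Pipeline overview

1. **Text preparation** (`split_sentences`, `normalize_text`, `tokenize`):
   rule-based sentence splitting on raw text, then lowercasing with a spared
   punctuation set — parentheses, comma, slash, hyphen, exclamation mark,
   question mark, quotation mark — separated into standalone tokens because
   downstream parses need them. Everything else outside `[a-z0-9']`,
   whitespace and the period is removed.
2. **Entity recognition and normalization** (`recognize_entities`,
   `assign_roles`): a pluggable NER surface whose shipped backend is greedy
   leftmost-longest gazetteer matching over normalized surfaces, followed by
   exact-match concept normalization against a pre-disambiguated lexicon.
   Role filtering is a pure function of the semantic group and type:
   molecules are GENE/CHEM plus the cell-component type `celc` (protein
   complexes); contexts are DISO minus `fndg` (findings describe a
   diagnosis, not the disease itself).
3. **Three representation models** (`train_skipgram`, `train_depembed`,
   `train_convkb`): linear-window skip-gram embeddings, dependency-context
   embeddings, and a convolutional knowledge-graph embedding over a
   semantic network of entity types.
4. **Corpus conversion** (`parse_standoff`, `decompose_events`,
   `build_instance`): BioNLP-ST standoff events flattened to signed binary
   relations by sign composition, then realized as tagged token sequences
   with a 3-row knowledge matrix.
5. **Classification** (`mgnc_init`, `pretrain`, `finetune`): a multi-group
   norm-constraint CNN over the three representation groups, trained by
   pre-training on context-free corpora and fine-tuning on the
   context-specific corpus.
6. **Post-processing** (`aggregate_relations`): grouping by concept-ID
   triple, a top-quantile frequency threshold, and majority voting with
   tie abstraction.

## The embedding models

**Skip-gram (group N).** Standard skip-gram with negative sampling, single
worker, so results are bit-reproducible per seed. Defaults follow
biomedical-NLP practice: dimension 200, window 16, 50 epochs, learning rate
0.05 with linear decay, subsampling threshold 1e-5, 10 negatives from the
unigram distribution raised to 0.75 (the classic choice; the negative
distribution is not otherwise specified by the method we follow). The window
size is drawn uniformly in `[1, 16]` per position, as in the original
implementation.

The subsampling threshold deserves a note. On natural corpora, 1e-5 prunes
only ubiquitous function words. On a template corpus with a vocabulary of a
few dozen types, *every* word exceeds the threshold and the corpus would be
discarded almost entirely. For synthetic-corpus training the wrapper
`corpus_embeddings()` therefore uses 1e-3, which down-weights exactly the
words that occur in every sentence (fillers, placeholders); the topic-recovery
check disables subsampling altogether, since with an eight-word sentence and
a 40-word vocabulary there is nothing "frequent" to prune in the intended
sense. The user-facing default of `train_skipgram` stays at 1e-5.

**Dependency embeddings (group D).** The same objective with syntactic
contexts instead of windows: an arc head→modifier labelled `L` contributes
(head, `modifier/L`) and the inverse pair (modifier, `head/LI`). Inverse
contexts are included because the dependency-embedding method this follows
uses them by default. Arcs to tokens labelled `punct` are skipped. Words and
contexts get separate vocabularies; word vectors are returned. Dimension 200
so the classifier's filter width is shared with group N.

**Knowledge-graph embedding (group K).** Entities are embedded at the
semantic-type level: the graph's nodes are entity types, and a concept's
vector is its type's node vector (concepts with several types would use the
first listed; unknown types give the zero vector). The scorer stacks
subject, predicate and object vectors into an m × 3 matrix and convolves it
with 1 × 3 filters; with one fixed filter `[1, 1, −1]`, linear activation,
zero bias and unit score weights the score is exactly the translational
residual Σᵢ(sᵢ + pᵢ − oᵢ), i.e. the scorer strictly generalizes
translation-based embedding. Training minimizes a softplus soft-margin loss
(true triples against endpoint-corrupted triples filtered against the true
set) with L2 on the score weights and Adam. Dimension 10 and learning rate
0.001 are the method's stated values; filter count defaults to 50, mirroring
the classifier's knowledge-group filter count, and filters initialize near
0.1·[1, 1, −1], the standard translation-prior initialization for this
scorer family. Training runs full-batch; the default of 1000 epochs gives
roughly a thousand optimizer steps, which on the planted toy graphs is the
point where held-out ranking clearly beats the random baseline. Scores are
oriented so that higher means more plausible.

## Corpus conversion

Nested regulation events flatten by sign composition: positive regulation
contributes +1, negative −1, plain regulation 0; nesting multiplies and 0
absorbs. The Theme chain is followed to its innermost physical entity, and a
Cause that is itself an event is resolved through its own Theme chain with
its signs composed too. Binding events emit one undirected record per
unordered Theme pair. The sign and trigger-mapping tables ship as an
editable rule configuration (`default_event_rules()`), since in the original
description they live in supplementary material; the defaults above are this
package's declared rules, not a claim about the exact supplementary tables.

Entity tagging replaces each argument mention with a role placeholder
(`<mol_a>`, `<mol_b>`, `<context>`). Placeholders are ordinary vocabulary
items for the embedding models — the linguistic tables are trained on tagged
sentences — which realizes the "marked entity" feature without a bespoke
encoding. Sequences are padded to at least 23 tokens with `<pad>`, which
embeds to the zero vector and whose positions are masked out of the
max-pool, so padding never changes eval-mode features. Context-free
instances put a zero row in the knowledge matrix's middle slot so one
architecture serves both corpora. Negative (False) instances are sampled
without replacement from co-occurring but unannotated tuples. Where several
context mentions occur in a sentence, all combinations are enumerated; the
method description does not fix a selection rule and enumeration is the
choice that loses no candidates.

## The classifier

Per linguistic group, filters of lengths 21, 22 and 23 (100 each) spanning
the full 200-dim embedding width convolve over the token axis; each filter
max-pools over valid positions to one scalar. The knowledge group convolves
the 3 × m knowledge matrix once, without stride, with 50 filters of exactly
that shape. Concatenating yields 650 features with all three groups
(3×100 + 3×100 + 50). Dropout 0.5 is applied to the concatenated vector,
then an 8-way softmax. Rectifier activations and max pooling are the
standard choice for this architecture family and are used here.

Training: Adam at learning rate 0.001, mini-batch 50 for pre-training and 5
for fine-tuning, early stopping on a stratified 10% held-out split with
patience 2 and a hard cap of 10 epochs (the method reports early stopping
below 10 epochs throughout). After *every* optimizer step, each group's
block of softmax weights is projected onto an L2 ball of radius λ_g; the
norm caps are not stated by the method, so λ_g = 3.0 per group, a common
norm-cap magnitude, logged and configurable. All convolution and softmax
parameters transfer from pre-training to fine-tuning — the label sets of the
two corpora are identical — and the pre-trained embedding tables stay frozen
during classifier training (configurable in principle; frozen is the
default because they are representations, not task parameters). No class
reweighting is applied: the corpora are skewed, and the evaluation metric is
chosen accordingly. Prediction is the argmax with ties broken toward the
earlier class in canonical order.

The 2:1 train:test language of the evaluation protocol is read as 3-fold
cross-validation with 2/3 train and 1/3 test per fold, which makes the two
statements consistent; folds are stratified with per-class balance within
one instance.

## Post-processing

Predictions grouped by the CUI triple (context, molA, molB); Binding is
symmetric, so molecule IDs are sorted within Binding records before
grouping, while directed records keep their order. The support threshold is
the largest support value v such that at least a fraction q (default 0.01,
"top 1%") of keys have support ≥ v; an absolute `min_support` override
exists because the source narrative also mentions absolute counts, and the
derivation connecting the two cannot be reconstructed — the quantile rule is
primary. Within surviving groups a strict majority wins; ties abstract:
Increase/Decrease (or a signed class with Regulate) sharing a direction
becomes Regulate with that direction, contradictory directions become
Binding, and any tie involving Binding stays Binding. Multi-way ties apply
the direction rule first, then the sign rule, terminating at Binding.

## Evaluation conventions

Micro-F1 pools TP/FP/FN over the seven non-False classes by default,
treating False as the negative class. The alternative — pooling over all
eight classes — is identically the accuracy for single-label multi-class
prediction, so the exclusion is what makes the metric informative under
skew; the convention is therefore `exclude_false = TRUE`, stated here
prominently because the method text does not fix it. The degenerate case
(no positives in gold or prediction) reports 1.0 with a `degenerate`
attribute and a warning rather than NaN. The knowledge-only ablation subset
is rejected by construction: without a linguistic group the model never
sees the sentence.

## What the synthetic generators emulate — and what they do not

`gen_kg` plants a translational structure: nodes sit on a 2-D lattice
spanned by two random directions u and v (plus jitter), and the relations
are u, v, u+v and near-aliases, so true triples are lattice moves with tiny
residuals while corrupting an endpoint breaks the geometry. This emulates
the transitional character of a semantic network at toy scale (20 nodes
versus 133 semantic types in the real network).

`gen_corpus` generates template sentences whose class is determined jointly
by a lexical trigger and, for a configurable fraction
(`knowledge_signal_fraction`, default 0.3), solely by the subject
molecule's semantic type under an ambiguous trigger ("targets") — in the
tagged token sequence those instances are *identical* across classes, so
only the knowledge modality can resolve them. This is the planted analogue
of the claim that background knowledge about the entities carries
information the sentence itself does not. Filler clauses bring every
sentence to ≥ 23 tokens so the longest filter fits without padding
dominating, and carry a class-correlated "echo" noun (neutral for
knowledge-dependent instances), mirroring how real abstracts describing
inhibition also use decrease-themed vocabulary nearby; without some such
lexical redundancy a template corpus makes same-direction triggers
distributionally indistinguishable, which no natural corpus is. Deterministic
dependency parses come from fixed per-template head/label patterns.

What passing tests on this generator shows: that the implementation learns
the signals it is pointed at, that the knowledge pathway carries information
end to end, and that every contract (padding, projection, determinism)
holds. What it does not show: performance on real abstracts, robustness to
NER errors, paraphrase variation, or genuinely ambiguous language — template
corpora are linearly separable by design, and absolute F1 values on them
say nothing about F1 on PubMed-scale data.

## Problem sizes and numerical choices

The shipped experiments use 2000 context-free and 600 context-specific
instances, a 20-node/5-relation/60–70-triple knowledge graph, and a
480-instance corpus with 3-fold cross-validation over three seeds for the
ablation — sizes at which every planted effect is comfortably detectable and
a full run completes in minutes on one core. Numerical details: softmax
logits are max-shifted before exponentiation; masked convolution positions
are set to −∞ before pooling (then rectified after), so the gradient routes
only to valid argmax positions; the Adam step runs in place in C++ over the
dense filter blocks; skip-gram training uses a private xorshift RNG stream,
making it independent of R's RNG state and reproducible bit for bit given a
seed. Sub-seeds for pipeline stages derive from the master seed by a fixed
affine map modulo 2³¹ − 1.

## Known limitations

- The NER backend is a gazetteer; it inherits none of a CRF tagger's recall
  on unseen surface forms. The interface is pluggable by design.
- The lexicon must be pre-disambiguated (one concept per surface);
  word-sense disambiguation is out of scope.
- Concepts are embedded at semantic-type resolution, so two concepts of the
  same type share a knowledge vector; finer (concept-level) graphs would
  need no code changes but are not shipped.
- The sentence splitter is a deterministic rule (terminator + space +
  non-lowercase, with an abbreviation guard list) and is not benchmarked
  against curated splitters.
- Event decomposition handles Theme/Cause roles and Binding theme pairs;
  site/location roles and speculation/negation cues are ignored.
- Multi-sentence events are skipped, since classification units are single
  sentences.
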
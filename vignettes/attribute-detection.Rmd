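---
title: "One-step attribute detection for clinical concepts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-step attribute detection for clinical concepts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(attrseq)
```

## The problem

Clinical notes qualify the concepts they mention: a disorder may be
negated, hedged, graded by severity or localized to a body site; a
medication mention travels with its dosage, route, frequency, duration and
reason; a lab-test mention has a value. Downstream applications need the
*pair* — which attribute modifies which concept — not just the spans. The
classical solution is a two-step cascade: attribute NER, then binary
classification of every intra-sentence (concept, attribute) candidate
pair. `attrseq` implements both that cascade and the one-step alternative
this package is organized around, together with the evaluation metrics
and a synthetic-corpus generator that makes the whole system testable
without access to restricted clinical corpora.

## The concept-focused sequence transformation

For every (sentence, target concept) pair a *concept-focused sequence*
(CFS) is produced. Tokens carry two independent channels:

* **concept-role tags** — `Target` on the target concept's tokens,
  `NotTarget` on tokens of other concept mentions, `Outside` elsewhere.
  The named vocabulary distinguishes the target from non-targets; we add
  `Outside` so every token has a role, and its embedding is learned like
  the other two. Roles and BIO labels never veto each other: an attribute
  nested inside the target span keeps role `Target` while carrying `B`/`I`
  labels, and a token of a non-target concept that happens to be an
  attribute of the target keeps `NotTarget` alongside its label.
* **BIO labels** restricted to the target: only attributes related to the
  target get `B-t`/`I-t`; attributes of other concepts and unassociated
  spans are `O`.

A sentence with $k$ concepts contributes $k$ training sequences. Decoding
is the inverse: maximal `B..I` runs of one type become attribute mentions
(character spans from token spans), each related to the target; a dangling
`I-t` is repaired by treating it as `B-t`, so any label sequence decodes.

Because each CFS carries its own labeling of the *same* sentence, a
concept-blind NER's central difficulty — the same surface form annotated
when it modifies a concept and unannotated otherwise ("omitted
annotations") — disappears: relatedness to the visible target is part of
the label definition.

## The tagger

Per-token input is the concatenation of a word embedding (size 50, lookup
on the lowercased form), the final states of a forward and a backward
character LSTM over the token's characters (hidden size 25 each; the
character channel sees the original case), and a role-tag embedding
(size 10) — 110 dimensions in total. A word-level Bi-LSTM (hidden 100 per
direction) feeds a linear projection into a linear-chain CRF with explicit
start/stop states. Training maximizes the CRF log-likelihood via the
forward algorithm (log-sum-exp stabilized); decoding is Viterbi with ties
broken toward the lower label index, so predictions are deterministic.

Optimization is plain SGD, learning rate 0.005, one sequence per update,
dropout 0.5 on the word-LSTM input and output during training only, all
embeddings randomly initialized. Choices the published setting leaves open
are fixed here and surfaced in `tagger_config()`:

* epoch count (default 30; no early stopping),
* global gradient-norm clipping at 5.0 to stabilize batch-1 SGD,
* rare-word handling: words seen fewer than 2 times are replaced by the
  unknown token with probability 0.5 during training so the UNK vector is
  trained,
* dropout placement (input and output of the word-level Bi-LSTM),
* character embedding size and character-LSTM hidden size are treated as
  two independent settings that happen to both equal 25.

The concept-blind NER of the two-step baseline is the identical stack with
the role channel removed (input width 100), trained on one sequence per
sentence whose labels cover all annotated attribute mentions.

All forward/backward passes are implemented in compiled code
(RcppArmadillo); gradients are verified against central finite differences
in the test suite, and CRF partition/decoding against exhaustive path
enumeration on small instances.

## The two-step baseline

Candidate pairs are the per-sentence Cartesian product of concept and
attribute mentions. Two relation classifiers share one interface:

* **margin classifier** — one linear hinge-loss SVM (cost 1, threshold 0)
  per attribute type over hashed binary features: bags of words before,
  between and after the pair, words inside each mention, the signed token
  distance (clipped to ±15) and its direction, plus an overlap flag. The
  published description fixes the feature family but not the solver or
  hashing; a 1024-dimensional hash space and libsvm's linear solver are
  the defaults here.
* **Bi-LSTM classifier** — per-token word embedding concatenated with
  embeddings of the bucketed distance to the concept and to the attribute
  (buckets −15…15, 0 inside the mention); final Bi-LSTM states feed a
  2-way softmax. Ablating the position channel collapses both distances to
  a constant bucket, which the tests use to show position information is
  load-bearing.

Relation models are trained on gold mentions and applied to NER-predicted
mentions (the standard cascade protocol). A type with single-class
training data yields a constant predictor with a warning; a type never
seen in training defaults to "attach", mirroring the positive skew of
sparse attribute types.

## Evaluation

Strict scoring: a predicted pair is correct only if concept identity
(offsets), attribute span (exact start/end) and attribute type all match a
gold pair; an attribute linked to $m$ concepts counts $m$ times on both
sides. Concept-level accuracy is per type:
$\mathrm{Acc} = N_{\text{correct\_predict}}/N$, where a concept is correct
iff its predicted attribute set of that type equals its gold set exactly —
both sets empty included, so "no attribute" is a prediction too. Accuracy
is computed per attribute type, matching per-type reporting.
Cross-validation folds partition *documents* (the unit is chosen to avoid
train/test leakage within a note) and micro-averages pool raw TP /
predicted / gold counts — and concept counts for accuracy — before
computing ratios. A relaxed overlap-matching mode exists but is off by
default.

## The synthetic corpus generator

`generate_corpus()` realizes template-based documents (newline-delimited
sentences) with the structural properties the method must cope with, and a
generation ledger recording every planted item for oracle checks:

* 0–3 target concepts per sentence (default distribution 0.10/0.40/0.30/0.20);
* per-type attribute attachment probabilities (disorder defaults
  NEG 0.25, SUB 0.05, CON 0.08, SEV 0.15, COU 0.10, UNC 0.10, BDL 0.45,
  roughly mirroring the relative frequencies reported for public clinical
  corpora, with rare types floored so small corpora still contain them);
* **shared attributes** (default 0.1): one cue conjoined over two concepts
  ("no *edema* or *rash*"), linked to both;
* **distractor segments** (default 0.2 per sentence): a segment realized
  exactly like a concept segment whose noun is *not* an annotated target
  concept, so its cues relate to nothing and stay unannotated. This
  reproduces the omitted-annotation phenomenon: a concept-blind NER sees
  identical contexts with contradictory labels, while the role channel
  disambiguates them;
* **crossing "respectively" constructions** (default 0.25 of multi-concept
  sentences): "in the *edema* and *rash*, severe and worsening
  respectively" lists 2 or 3 concepts and then their attributes in
  matching order, so every attribute is closer to another concept than to
  its own. Mixing list lengths makes the same signed distance related in
  one sentence and unrelated in another; resolving these sentences
  requires tracking the listing order, which position-bucket features
  cannot do and the role-aware tagger can. This is the designed hard case
  separating the one-step method from proximity heuristics.

Lab-test values are generated in both flavors, numeric ("134/75") and
categorical ("NEG"). What the generator deliberately does **not** emulate:
open vocabulary, spelling variation, section structure, discontiguous
mentions, cross-sentence relations. Passing tests on these corpora
demonstrate that the implementation learns the intended structural
signals; they do not certify performance on real clinical language.

## Numerical choices and experiment sizes

* CRF transition masks use a large negative constant (−10⁴) rather than
  −∞ so the log-sum-exp stays finite.
* Viterbi tie-break: lower label index; `O` is label 1, so an untrained
  model prefers all-`O`.
* Degenerate inputs: empty sequences decode to empty paths; whitespace-only
  sentences tokenize to zero tokens and are skipped; an empty training set
  is an error.
* The capacity (overfit) check trains on a 10-sentence corpus with
  regularization off and learning rate 0.3: at batch size 1, 30 epochs on
  ~15 sequences are only ~450 updates, so the step size is scaled to that
  budget rather than to the corpus-scale setting.
* The study-scale experiments use a 100-document corpus (~500 sentences,
  ~900 gold pairs), an 80/20 document split, 120 epochs for the one-step
  tagger and 60 for the NER stage — epoch counts chosen where the
  training-loss trace plateaus (mean NLL ≈ 0.1/sequence); the Bi-LSTM
  relation classifiers use 10 epochs per type. On one CPU the full set of
  experiments runs in about five minutes.
* `cross_validate()` defaults to k = 10 as in the published protocol; the
  bundled experiments use a single held-out split for runtime reasons,
  which the acceptance script mirrors.

## Limitations

The generator's closed vocabulary means memorization can substitute for
generalization in ways impossible on real text; the baselines' strength
here (the margin classifier in particular) should be read accordingly.
Discontiguous mentions are rejected at load (mirroring their exclusion in
the source corpora), cross-sentence relations are dropped at expansion
with a warning, and no pretrained or contextual embeddings are used —
everything is learned from the training corpus alone.
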
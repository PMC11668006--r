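---
title: "Methods: name redaction and its evaluation in redactnames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: name redaction and its evaluation in redactnames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redactnames)
```

This vignette records how the de-identification method in `redactnames` is
defined, which design points were genuinely open, and what the package's
synthetic experiments do and do not establish. It states no number that the
test suite or `scripts/acceptance.R` does not itself compute.

## The task and its asymmetry

Given a free-text adverse-event narrative, flag every token belonging to a
person name and replace the flagged spans with a placeholder. The two error
types are not symmetric: a missed name token (a *leak*) is a privacy
failure, whereas a spurious flag merely costs some readability. Every
threshold and tie-break in the package is therefore chosen to fail towards
NAME.

All scoring is defined over *alphanumeric tokens*: maximal runs of Unicode
letters and decimal digits, with 0-based half-open code-point offsets.
Whether "alphanumeric" should include underscores or non-ASCII digits is
not fixed by the task; we use the Unicode letter/digit classes because
narratives are UTF-8 and accented names must not be split. Tokens of three
or fewer characters ("short") are reported separately from longer ones:
short tokens proxy for initials, which are both harder to detect and less
identifying one by one.

## Rule classifier

The rule arm captures one to three words adjacent to three trigger
families: salutations ("dr", "mr", "sister", ...) and labels ("name:",
"patient:", ...) capture *following* words; credential titles ("m.d.",
"rn", ...) capture *preceding* words. The exact published trigger lists and
capture grammar for this style of rule set are not public, so the shipped
lexicons (`inst/extdata/ruleset.txt`, editable plain text) are a
reconstruction with these committed semantics:

* the first adjacent word is **always** captured; the second and third only
  while each additional word starts with an uppercase letter;
* capture never crosses a sentence-terminating character (`.` `!` `?` `;`)
  or a newline, and never exceeds three words;
* triggers match whole tokens case-insensitively ("dr" never fires inside
  "drug"); a trailing `.`/`:` on a trigger is treated as decoration, and
  label triggers additionally require their colon in the running text.

The always-capture-one-word rule is what makes the arm recall-oriented and
individually imprecise — "the doctor said it resolved" flags "said". That
behaviour is intended: the rules exist to backstop the neural arm on
blatant contexts (a name right after "Dr"), and the OR ensemble inherits
their false positives, which is measurable in the package as an FPR
increase whenever rules are enabled.

## Neural token classifier

The trainable arm is a transformer-style token classifier with a binary
NAME/NON-NAME head. Two backends share one interface; the one implemented
and shipped is `tiny_test_transformer`, a compact encoder authored in the
package so that training and tests run on one CPU with no downloads:

* **Input units.** Words are lowercased and cut into word pieces of at most
  four characters; pieces are mapped to a 1,024-slot embedding table by a
  deterministic polynomial hash. Hash collisions are accepted (with ~400
  distinct pieces in play the collision rate is a few percent) — they trade
  a bounded amount of confusability for a fixed, download-free vocabulary.
* **Orthographic shape.** Each word also contributes a shape embedding
  (initial capital, all-caps, contains digit, short), since capitalisation
  is the dominant orthographic cue for names in English narratives. Shape
  embeddings are initialized an order of magnitude larger (sd 0.2 vs 0.02)
  than word-piece embeddings so that shape is a first-class feature of the
  representation rather than a faint additive perturbation.
* **Encoder.** One single-head self-attention layer with residual
  connection, layer normalization and a 4x feed-forward block
  (hidden size 48 by default; layer-norm epsilon 1e-5).
* **Head and scale.** The encoder output is multiplied by a fixed
  `feature_scale` (12) before the 2-class linear head, whose weights start
  near zero (sd 0.005). Both choices concern trainability at the reference
  learning rate of 1e-5: Adam moves each weight by at most roughly the
  learning rate per step, so over a few thousand update steps the head can
  only traverse a small distance in weight space; a larger feature scale
  makes the logits correspondingly responsive to that distance, and the
  near-zero head start means initial predictions are maximally uncertain
  (probabilities near 0.5), i.e. on the NAME side of the decision rule.
* **Loss and optimizer.** Categorical cross-entropy over the two classes,
  Adam with default moments (0.9/0.999), one chunk per update step, no
  class weighting. Initialization and epoch shuffling derive from the
  config seed, so training is bit-reproducible.

Three points were genuinely open and are fixed as follows:

* **Sequence limit.** Narratives are split into independent, non-overlapping
  chunks of at most 512 units *including* the two begin/end sentinels, and
  a chunk boundary never splits one word's pieces. No context is stitched
  across chunks.
* **Subword-to-token aggregation.** A token is NAME if *any* of its pieces
  fails the NON-NAME decision; equivalently its NON-NAME probability is the
  minimum over pieces. Any-piece aggregation is the privacy-conservative
  option.
* **Decision rule.** A token is NON-NAME only when P(NON-NAME) strictly
  exceeds the threshold (default 0.9); a score exactly at the threshold is
  NAME. The rule is monotone in the threshold, which the test suite checks
  as a property.

The `pretrained_uncased_transformer` backend name is accepted in
`model_config()` for interface completeness, but no pretrained weights ship
with the package, so selecting it raises an informative error. Nothing in
the evaluation framework depends on which backend produced the predictions.

## Covering-mode evaluation

A predicted span scores a gold NAME token only by covering it completely;
partial coverage is a false negative. For gold NON-NAME tokens:

* partially covered by any span: false positive, always;
* fully covered by a span that also fully covers at least one gold NAME
  token: forgiven (true negative) — over-extension around a real name does
  not hurt precision;
* fully covered by a span containing **no** fully covered NAME token:
  false positive. This is the committed reading of an ambiguous corner —
  one could instead forgive whenever the span covers *any* gold name
  material — and it is the only reading under which entirely spurious
  flags generate false positives at all.

Precision, recall and F1 are reported as whole percents and FPR to two
decimals, rounded half-up (so 49.53 prints as 50 and 86.5 as 87); F1 is the
harmonic mean of the *unrounded* precision and recall. A metric whose
denominator is zero is undefined and reported as `NA`, never 0. The FPR
denominator is the gold NON-NAME token count of the evaluation corpus.
Narrative-level recall divides leak-free name-bearing narratives by all
name-bearing narratives, per stratum.

The evaluator is verified two independent ways: against a brute-force
per-character oracle on over a thousand random instances, and by
`make_confusion_fixture()`, which builds a corpus-plus-predictions pair
realizing any consistent confusion table exactly, so any published table
of counts can be rebuilt and rescored end to end.

## Synthetic corpus generator

Confidential report streams cannot ship with a package, so experiments run
on generated narratives. The generator targets *structural* fidelity:

* exact realized counts — name-bearing narratives, total NAME tokens,
  short-token share — by partitioning budgets before sampling, rather than
  i.i.d. draws (property tests need exact prevalences);
* name mentions embedded in five context types (salutation, label, title,
  bare, signature) with configurable mixture weights;
* adverse-event vocabulary with drug names and dates as placeholder tokens
  (`DRUG`, `DATE`);
* distractors: medical eponyms (Stevens-Johnson, Parkinson, Graves),
  pseudo-identifiers ("Person A") and trigger words without names ("the
  doctor said ..."), the main sources of false positives in this domain;
* a mixed-origin name lexicon (editable text files under `inst/extdata/`),
  so sensitivity probes across name origins are expressible, plus a small
  rate (3%) of names typed in lower case, an informal-reporter trait that
  bounds what any capitalisation-driven detector can recall.

Two canned configurations encode the study conditions used throughout the
package: `synthetic_config()` defaults emulate a held-out reporting-stream
test set (5,042 narratives, 71 name-bearing, 179 NAME tokens of which 71
short), and `training_config(n)` scales an *enriched* training corpus
(64% name-bearing, ~2.3 NAME tokens per narrative, a quarter of them
short) — enrichment being what machine-assisted candidate selection
achieves on a raw stream, and what `select_candidates()` demonstrates on
generated data.

What generated data does **not** emulate: real narrative style and
discourse, misspellings, name-vs-eponym collisions *in context* (the
generator never uses "Johnson" both ways in one narrative), regional
spelling and code-switching, or the long tail of real-world name contexts.
A pipeline that scores well here has demonstrated that its machinery —
tokenization, learning, thresholding, ensemble, scoring — works as
specified; it has *not* demonstrated deployment-grade performance on real
reports, which requires annotated in-domain data.

## Experiment sizes and determinism

The packaged experiments are scaled for a single CPU: the acceptance
experiment fine-tunes on 500 generated narratives for 5 epochs at learning
rate 1e-5 and threshold 0.9, scores 200 held-out narratives (training takes
on the order of ten seconds), and runs the ten-name injection protocol on a
salutation-context narrative. The worked-example fixtures rebuild a
263,451-token confusion table in a few seconds. Every random quantity —
generation, initialization, shuffling — derives from explicit integer
seeds, and all end-to-end runs are bit-reproducible given the seed.

## Known limitations

* The rule lexicons and capture grammar are reconstructions; real
  deployments should edit `ruleset.txt` against their own data.
* The compact backend memorizes frequent tokens and leans on orthographic
  shape; it has no pretrained language knowledge, so its precision on rare
  capitalised non-names (sentence-initial words, eponyms) is limited. This
  is visible in the worked example as over-redaction, and is the expected
  trade-off of a threshold that fails towards NAME.
* Only names are in scope; dates, addresses and other identifiers pass
  through untouched (and are better served by pattern matching).
* Redaction substitutes a placeholder; surrogate-name replacement is out of
  scope because redacted narratives are typically shared with recipients
  who must know what was masked.
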
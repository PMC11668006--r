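# redactnames

Automated redaction of person names in free-text adverse event case
narratives.

Pharmacovigilance organisations hold large collections of spontaneous
adverse-event reports whose clinical substance — course of events,
differential diagnosis, patient-reported observations — often lives only in
free text. Sharing those narratives requires removing personal identifiers,
and person names are the hardest of them: unlike dates or ID numbers they
cannot be caught by simple patterns, because the same token can be a name in
one context and a medical term in another ("Mr *Johnson*" vs
"Stevens-*Johnson* syndrome"). `redactnames` is a toolkit for building,
applying and — above all — rigorously evaluating a name-redaction pipeline
for this setting. It is aimed at safety-data teams and clinical-NLP
researchers working with report narratives where names are rare, short
initials matter, and a missed name (a *leak*) is the costly error.

## Method

The pipeline combines two detectors under an **OR ensemble** — a token is
flagged if either arm flags it:

* a **rule classifier**: between one and three words adjacent to a
  salutation ("dr", "mr"), a report label ("name:", "patient:") or a
  credential title ("m.d.", "rn") are captured; the first adjacent word
  always, further words only while capitalised. Recall-oriented by
  construction (it always captures *something* after "the doctor ..."),
  hence individually low precision;
* a **neural token classifier**: a transformer encoder with a binary
  NAME/NON-NAME head, fine-tuned with categorical cross-entropy (Adam,
  learning rate 1e-5, 5 epochs), scoring narratives in independent chunks
  of at most 512 subword units. The decision rule is deliberately
  asymmetric: a token is left unredacted only when
  P(NON-NAME) > 0.9; ties and uncertainty fall to NAME. The package
  implements a compact self-contained backend (single-layer self-attention
  over hashed word-piece, orthographic-shape and position embeddings) that
  trains in seconds on a CPU without any downloads.

Flagged token runs are merged into spans and replaced with a placeholder
(`"NAME"`), and narratives containing any flag enter a review queue.

Scoring is **covering mode** at the level of alphanumeric tokens: a gold
NAME token counts as recalled only if a predicted span covers it
completely; NON-NAME tokens fully inside a span are forgiven when the span
also fully covers a name (over-extension around a true name is harmless),
while partially covered NON-NAME tokens are false positives. With
`tp/fp/fn/tn` counted that way, the report gives

    precision = tp / (tp + fp)    recall = tp / (tp + fn)
    F1 = 2tp / (2tp + fp + fn)    FPR = fp / (fp + tn)

stratified into **long** (> 3 characters) and **short** (≤ 3, a proxy for
initials) tokens, plus *narrative-level recall*: the fraction of
name-bearing narratives with zero leaked tokens.

Because real report streams are confidential, the package ships a
**synthetic corpus generator** that emulates their structure exactly
(number of name-bearing narratives, NAME-token totals, short-token share,
salutation/label/title/signature contexts, medical-eponym distractors), a
JSONL standoff reader/writer, a reader for the i2b2 2014 de-identification
XML dialect, a regex candidate selector for enriching training sets, and a
name-injection sensitivity protocol.

## Worked example

```r
library(redactnames)

corpus <- generate_corpus(training_config(300, seed = 1))
model  <- train(corpus, model_config(seed = 1), quiet = TRUE)

text <- "Spoke to Dr Priya Sharma today. Patient developed a rash after DRUG. Stevens-Johnson syndrome was excluded."
deidentify_narrative(text, model)$redacted
#> [1] "NAME to Dr NAME today. NAME developed a rash after DRUG. NAME syndrome was excluded."
```

The name is gone, and so — this is the trade-off the threshold buys — are a
few capitalised non-names, including the eponym *Stevens-Johnson*: the
method is tuned so that leaks, not over-redactions, are the rare event.
Evaluating on a held-out synthetic corpus:

```r
heldout <- generate_corpus(training_config(100, seed = 2))
res     <- deidentify_corpus(heldout, model, rs = NULL)
report  <- evaluation_report(heldout, res$predictions)
report$metrics
#>  stratum precision recall f1  fpr
#>      all        52     91 66 5.83
#>     long        47     97 63 8.76
#>    short        95     72 82 0.18
report$narrative_recall
#>   all  long short
#>    77    92    74
```

Read: 91% of all gold NAME tokens were fully covered (97% of long name
words, 72% of short initials), at 52% precision — roughly one real name per
two flags — and 92% of narratives containing a long name token came out
with no leak at all. `res$review_queue` lists the flagged narratives,
triage-ordered.

A thin command-line front end over the same functions ships at
`inst/cli/redactnames.R` with `train`, `deidentify`, `evaluate` and
`simulate` subcommands.

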
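---
title: "Detecting PROMs and PREMs in registry outcome descriptions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{promscan methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Clinical-trial registries describe what each study measures in free text.
Whether a study collects *patient-reported* outcome or experience measures
(PROMs/PREMs) — validated questionnaires answered directly by patients —
is not a structured field, and instrument naming is not standardized:
the same questionnaire appears as a full name, an acronym, a hyphen or
spacing variant, or a misspelling. `promscan` implements a complete
pipeline for measuring PROM/PREM uptake from registry outcome
descriptions: two detectors (a curated-lexicon matcher and a trainable
text classifier), the annotation workflow that produces a gold standard,
an evaluation harness, instrument-mention extraction and normalization,
cancer-site recoding, and study-level statistics — plus a synthetic
registry generator so the whole pipeline is testable offline.

The unit of analysis is one *outcome description*: the title and
description of a single registered outcome, concatenated with `". "`.
Studies are exploded into outcomes, each outcome is classified, and the
study-level flag is the OR over its outcomes.

## Eligibility model

`filter_eligible()` applies three rules: a half-open start-date window
`[start, end)` (default 2012-01-01 to 2022-01-01; a study starting
exactly on the end date is excluded — the inclusive/exclusive convention
is not fixed by common registry prose, so the half-open interval was
chosen for composability), removal of studies with no outcomes or no
outcome descriptions, and removal of individual description-less
outcomes within retained studies. An exclusion log with one count per
reason satisfies the conservation identity
`input = retained + sum(excluded)`. Domain (oncology) filtering is
delegated to the caller via a condition-keyword predicate, because the
exact registry query behind any given corpus is unknowable from the
outside; the synthetic corpus marks its domain explicitly.

## The lexicon matcher

The expert-style detector searches the normalized text for any canonical
instrument name, acronym, or one of eleven fixed generic terms (eight
PROM terms, three PREM terms). Normalization lowercases, unifies
hyphen/en-dash variants, and collapses whitespace while keeping an
offset map so every hit is reported as a span in the original string.

Matching rules that matter:

* **Word boundaries.** A hit must be delimited by non-alphanumerics on
  both sides; "satisfaction" matches as a word, never inside
  "dissatisfaction".
* **Hyphens are soft.** Inside a surface form a hyphen may surface as a
  hyphen, a space, or nothing (`QLQ-C30` ≡ `QLQ C30` ≡ `QLQC30`), and an
  internal space may surface as a hyphen.
* **Short-acronym casing.** Acronyms of at most four characters only
  fire when the matched original text is uppercase or carries digits.
  This is the guard against prose words that collide with acronyms — an
  uppercase symptom word like "PAIN" is a known red herring for learned
  models, and a lowercase "fact" must not fire the FACT acronym.
* **Deduplication.** Overlapping hits keep the longest span; instrument
  hits beat generic-term hits at equal length (a canonical name that
  contains "quality of life" is reported as the instrument, once).
* The published generic PROM term `QoLd` is shipped verbatim even though
  it is plausibly a typo for "QoL"; a `qol` alias exists behind
  `generic_terms(include_qol_alias = TRUE)`, default off, because "qol"
  is a high-yield token and silently adding it would change the
  detector's operating point.

The packaged lexicon (`instrument_lexicon_synthetic.csv`) is a
synthetic ~40-entry stand-in for the proprietary 346-entry PROQOLID
oncology extract; it contains the nine instruments that dominate
published frequency tables plus common generic and site-specific
questionnaires. Results at desk scale exercise the mechanism, not the
coverage, of the original lexicon.

## Gold-standard annotation

`sample_labeling_subset()` draws `floor(0.15 * N_pos)` matcher-positive
and `floor(0.02 * N_neg)` matcher-negative outcomes (floor, not round,
so achieved counts are reproducible arithmetic), `assign_pairs()`
partitions them round-robin over eight annotator pairs, and labels from
the two annotators live in separate files until `adjudicate()` merges
them — blinding is structural, not procedural. Cohen's kappa is computed
*before* adjudication; identical vectors return 1 even when chance
agreement is 1 (the degenerate single-category case). Adjudication
passes agreements through untouched and requires an explicit consensus
label for every disagreement, so the resulting gold set is 100% agreed
by construction.

## The trainable classifier

The classifier contract is "text in, probability out". The published
approach fine-tunes a BERT encoder; shipping that would require
pretrained weights and a GPU, neither of which a desk-scale, offline
package can assume. The default backend is therefore a bag-of-words
penalized logistic model (glmnet) behind the same interface: balanced
classes by majority-class downsampling, a stratified 61/12/27
train/validation/test split (largest-remainder apportionment; explicit
counts such as 2399/479/1065 are accepted because printed split sizes
rarely match rounded percentages exactly), truncation at 512 tokens
keeping the head of the text, a hyperparameter grid, and selection by
validation accuracy with ties breaking to the earlier grid point. A
transformer backend can implement the same contract; nothing else in
the pipeline would change.

On template-generated synthetic corpora the baseline backend is
essentially perfect (the planted instrument vocabulary separates the
classes); this validates the pipeline mechanics, *not* real-world
accuracy, where published transformer performance is ~90%.

## Evaluation conventions

`metrics()` computes accuracy, sensitivity, specificity, PPV and NPV
from the confusion matrix, with undefined denominators reported as
explicitly undefined rather than zero. Percentages round half away from
zero. The default confidence interval is Wald, with Wilson behind a
flag.

Reproducing a published evaluation table from its printed cells is the
package's exactness check, and it surfaces two genuine inconsistencies
worth recording. First, cells of 448/110/58/449 give an NPV of
449/507 = 88.56%, which rounds to 89 although the source footnote prints
88 (while rounding 448/506 = 88.54% *up* to 89 for sensitivity) — the
package reports computed values. Second, the printed intervals mix
methods: AI accuracy (88–92), AI sensitivity (88–93) and expert accuracy
(82–86) are Wald-reproducible; AI specificity (86–92) and expert
sensitivity (85–91) match Wilson but not Wald; and expert specificity
(79–85 around a point estimate of 80.3) matches neither. The acceptance
tests assert exactly the reproducible ones and pin the Wilson-only ones
as such.

`compare_algorithms()` is a Pearson chi-square without continuity
correction on the 2x2 table algorithm x {correct, incorrect}. This
treats the two evaluations as independent samples; the paired,
per-item comparison (McNemar) cannot be built from two published
confusion matrices alone, so the test is documented as an approximation
that ignores pairing.

## Instrument mention extraction and normalization

The default extractor is rule-assisted: lexicon-seeded spans (found with
the same matching rules as the detector) are authoritative; heuristic
candidates — acronym-shaped tokens and Title-Case runs ending in a head
noun like *Scale*, *Questionnaire*, *Survey* — supplement them, and any
heuristic candidate overlapping a lexicon span is dropped rather than
merged, so an exact lexicon hit is never diluted by surrounding prose.
Heuristic fragments separated by at most two tokens are merged into one
candidate before normalization: this is the countermeasure to the known
failure mode where a multiword name like "Short Form 36 Health Survey"
is tagged as two fragments and consequently missed. A learned tagger
returning spans can be plugged in behind the same contract.

Normalization scores each candidate against all lexicon surface forms
by character-trigram cosine on folded text (case, punctuation and
whitespace neutralized), assigning the argmax instrument iff the
similarity reaches the threshold, ties breaking to the smallest
instrument id. The default threshold of 0.85 was chosen on the fixture
lexicon so that hyphen/spacing variants of a true name pass (they fold
to identity, similarity 1.0) while unrelated acronyms and symptom words
stay far below (e.g. "PAIN" peaks at ~0.33 against any entry).
Frequency tables count an instrument once per study, with proportions
over studies having at least one assigned instrument.

## Cancer-site recoding

Free-text condition strings are embedded as term-frequency vectors after
stop-word removal and clustered with seeded k-means; each cluster is
named by its ten most frequent words, and a nearest-prototype classifier
(cosine against per-label exemplar centroids, confidence floor 0.1,
label "unspecified" below it) recodes the full corpus. Two deliberate
choices: the English stop-word list is a file in the package, not a
library import, so top-word naming is reproducible forever; and a fixed
oncology stop list (cancer, carcinoma, tumor, neoplasm, ...) is added,
because histology-generic words otherwise tie or even dominate the
clustering — "breast cancer" vs "breast carcinoma" should cluster by
*breast*, not by which histology synonym was typed. The number of
clusters is a configuration value (no principled k is recoverable for
registry condition vocabularies; ~15 site labels is the scale implied by
eight exemplars per site over ~116 exemplar texts). The prototype
classifier replaces a sentence-embedding few-shot model behind the same
contract for the same offline reasons as the classifier backend.

## Study-level analytics

Outcome flags aggregate to studies by OR. Yearly uptake uses the
Cochran–Armitage score test (year as a linear score). Bivariate
chi-squares exclude the explicit `"missing"` level. The multivariate
logistic regression is stratified by study type, complete-case within
the stratum (rows missing any predictor are dropped with a logged
count), and treats `"not_applicable"` allocation — single-group and
sequential designs, where randomization is structurally undefined — as
excluded from the allocation predictor rather than imputed. Odds ratios
carry 95% Wald intervals and Wald p values; reference levels are
reported with OR exactly 1. Apparent separation (any |log-OR| > 10 or
non-convergence) is an error naming the offending term, not a silent
huge estimate. The MCAR check regresses the missingness indicator on
fully observed covariates and calls the variable "consistent with MCAR"
iff the joint Wald p is at least .05.

## The synthetic world

`generate_corpus()` emits registry-dialect study records plus exact
ground truth. Its defaults *are* the stated world being emulated:

| parameter | default | rationale |
|---|---|---|
| prevalence | 0.33 | published share of studies using any PROM/PREM |
| years | 2012–2021 | the analysis window |
| trend slope | 0.044 / yr (log-odds) | implied by a rise from 27.6% to 36.2% over nine years |
| outcomes per study | truncated Poisson(5), min 1 | ~5.8 outcomes/study in the real corpus |
| interventional share | 0.79 | published study-type split |
| covariate margins | published descriptive table | phase, allocation, model, purpose, observational model, time perspective |
| covariate effects | published ORs (phase 2: 1.8, phase 3: 3.6, phase 4: 2.6, randomized: 2.0, supportive care: 4.1; prospective: 3.2, cross-sectional: 4.6, cohort: 1.6) | the generating logistic model |
| instrument mix | published nine-instrument repartition | plant frequencies |

The generating model is honored exactly: covariates are drawn from the
margins, the linear predictor adds the configured log-odds effects and
the year trend, and the intercept is calibrated by root-finding so the
marginal prevalence hits the target — a property of the generator's
contract, fixed before any test is run. Positive outcomes embed an
instrument surface form (canonical, acronym, or a configured corruption:
hyphen dropped, multiword fragmented by punctuation, adjacent-letter
typo) at a recorded span; negatives draw from clinical templates and,
at configured rates, trap phrases — an uppercase symptom token, ad hoc
item phrasing, clinician-reported phrasing — that the labeling rule
says are *not* named instruments. Trap phrases are constructed to
contain no lexicon surface form and no generic term: note that a
realistic "ad hoc questionnaire" string would legitimately fire the
generic term "questionnaire", i.e. the generic-term route is *designed*
to over-trigger on such texts relative to the named-instrument labeling
rule; the traps therefore probe the instrument-name path specifically.

What the generator does **not** emulate: the lexical diversity, length
distribution, typo census and naming chaos of real registry text, the
real 346-entry lexicon, or the correlation structure among covariates
beyond the stated margins and effects. A green synthetic test
establishes that the mechanisms are correct — perfect recall on exact
plants, exact frequency recovery, effect recovery within sampling
error — not that real-corpus performance figures would be reproduced.
The published real-corpus quantities (31%/33% prevalence, table counts,
kappa = 0.59, trend values, real-data ORs, the 96% site accuracy) are
accordingly out of reach by construction and are represented by these
property-based analogs.

## Numerical choices and degenerate inputs

* Percent rounding: half away from zero everywhere.
* Sample sizes in annotation sampling: floor.
* Split apportionment: largest remainder, stratified by label; the
  final nudge onto requested totals moves items of the most
  overrepresented class so stratification stays within one item.
* Kappa: returns 1 for identical vectors even when chance agreement
  is 1; errors on length mismatch or empty input.
* Metrics with zero denominators: undefined marker, never 0.
* Empty text: valid classifier input (scores at the prior), valid
  matcher input (no hits), "unspecified" for the site classifier.
* k-means: seeded, `nstart = 10`; clustering of duplicated strings is
  done on distinct strings and mapped back.
* All generators and samplers take explicit integer seeds; identical
  seeds give byte-identical output.

## Known limitations

* The baseline classifier is a linear bag-of-words model: it cannot
  capture word order or novel-instrument generalization the way a
  fine-tuned encoder can, and its near-perfect synthetic scores must
  not be read as expected real-world accuracy.
* The rule-assisted extractor inherits lexicon coverage: a wholly
  unlisted instrument is only found if it is acronym-shaped or
  Title-Case-with-head-noun.
* The algorithm comparison ignores item-level pairing (see above).
* Trigram cosine is robust to spacing/hyphen variants and transposition
  typos in long names but brittle for very short acronyms with typos
  ("FSS" vs "SFS" share no trigram); such plants are an intended miss
  mode of the normalization stage.
* The site recoder assumes English condition strings and
  vocabulary-separable sites; mixed-language registries would need a
  different embedding.
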
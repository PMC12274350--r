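---
title: "Case-finding for dementia with Lewy bodies in clinical text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-finding for dementia with Lewy bodies in clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlbtext)
```

## The problem and the model

Dementia with Lewy bodies (DLB) is diagnosed from four core clinical
features — visual hallucinations, cognitive fluctuations, parkinsonism and
REM sleep behaviour disorder (RBD). One core feature constitutes the
criterion for *possible* DLB, two or more for *probable* DLB. In routine
mental-health records these features are rarely captured in structured
fields; they live in free-text notes. The consequence is systematic
under-recognition of DLB among patients carrying an Alzheimer's disease
(AD) diagnosis.

`dlbtext` implements the complete case-finding pipeline for this setting:

1. **Mention detection.** Six elementary concepts are found by
   case-insensitive stem matching: `fluctuat*`, `tremor*`, `bradykinesi*`,
   `bad dream*`, `nightmare*`, and — the one proximity concept — `visual`
   together with `hallucinat*` in close proximity. Parkinsonism is
   operationalised as tremor OR bradykinesia; RBD (in the weak sense of
   *possible* RBD) as bad dreams OR nightmares, reflecting how dream
   enactment actually surfaces in records without a bed-partner witness.
2. **Mention classification.** Each candidate is called positive or
   non-positive. The non-positive side pools negations ("no evidence of
   mood fluctuation"), hypothetical or uncertain mentions ("monitoring to
   see if fluctuations deteriorate") and non-patient experiencers ("his
   mother's responsibility fluctuated"): only affirmative mentions of the
   patient's own symptom count as entities.
3. **Aggregation.** A patient carries a symptom if at least one positive
   mention occurs anywhere in their record — the whole record is scanned
   with no time window, so a single affirmative mention sets a lifetime
   flag and negations elsewhere never veto it. Core-feature counts map to
   criteria categories (`none`, `one_feature`, `two_plus`) and AD patients
   with two or more features are flagged as the AD2CS stratum.
4. **Cohort statistics.** `table1()` contrasts DLB against AD on
   demographics, the four core features and the 0–4 feature-count
   distribution; `table2()` contrasts AD with <2 features, AD2CS and DLB
   with 2+ features using two pairwise p-value columns. Continuous
   variables use Welch t-tests, categorical variables Pearson chi-squared
   tests, with 0.05 as the significance level and no multiplicity
   adjustment — the pairwise design is reproduced as such and no omnibus
   test is added.
5. **Evaluation.** Precision (positive predictive value) and recall
   (sensitivity) of extracted entities against gold annotations, per
   concept, with mention-level any-overlap matching by default.

## The synthetic corpus

Individual-level mental-health records cannot be shipped, so the package
generates a synthetic cohort with the statistical structure of a real
memory-service population, and all end-to-end properties are demonstrated
on it.

```{r cohort}
cohort <- generate_cohort(n_ad = 200, n_dlb = 50, seed = 1)
head(cohort$patients, 3)
colMeans(cohort$profiles[cohort$patients$diagnosis == "DLB", -1])
```

Defaults in `prevalence_config()` are the study-population parameters:
core-feature prevalences (DLB/AD) of 83.1/16.7% for visual hallucinations,
74.7/30.3% for fluctuations, 62.1/19.7% for parkinsonism and 26.6/9.3% for
RBD; ages at first referral of 76.9 (SD 10.2) vs 80.6 (SD 8.5) years;
49.0/64.0% female; 26.4/27.9% non-White; 42.6/34.8% married or cohabiting.
Design choices where the published evidence is silent:

* **Elementary split of composite features.** Only composite parkinsonism
  and RBD prevalences are reported. Each component (tremor/bradykinesia,
  bad dreams/nightmares) is sampled independently at
  `p = 1 - sqrt(1 - P)`, the symmetric solution making the OR-composite
  hit the configured `P` exactly.
* **Independence.** Symptoms are independent Bernoulli draws per patient;
  no co-occurrence structure is asserted because only marginal prevalences
  are published. The implied feature-count distribution therefore need not
  (and does not) match the published one — it is a soft calibration
  check, not a target.
* **Diagnostic delay.** Age at diagnosis is age at referral plus one year
  for AD, two years for DLB and for AD patients with 2+ planted features,
  matching the reported average referral-to-diagnosis delays by stratum.
* **Documents.** Each patient gets 1–5 documents (uniform; real document
  counts are unpublished), each seeded with 2–4 neutral keyword-free
  distractor sentences. Every true symptom plants one positive-labelled
  template sentence; absent symptoms receive a negated mention with
  probability 0.10 or an unknown/hypothetical one with probability 0.05,
  to exercise the classifier. Templates are table-driven (prefix, keyword,
  suffix), so gold spans are exact by construction.
* **Seeding.** One master seed is split per patient through a fixed affine
  hash, so identical seeds regenerate byte-identical corpora and existing
  patients keep their documents when the cohort grows.

What the generator does *not* emulate: clinician documentation bias,
longitudinal symptom onset, spelling noise, template-free language.
Perfect precision/recall on this corpus therefore demonstrates internal
consistency of extractor and generator — not performance on real clinical
text, where published applications of this design report precision around
83–91% and recall 84–100% per concept.

## Numerical and rule choices

* **Proximity window.** "Close proximity" for `visual` + `hallucinat*` is
  both stems in one sentence with at most 5 intervening word tokens
  (configurable). Overlapping pairs merge into one maximal candidate.
* **Sentence segmentation** splits on runs of `.`, `!`, `?` or newline
  followed by whitespace; the abbreviation list is deliberately minimal
  and documented as a dialect knob.
* **Negation scope.** A cue scopes over candidates in the same sentence
  within 6 word tokens (NegEx-style short range, matching how negative
  examples are actually phrased). With cues on both sides the nearest
  wins; ties resolve to non-positive — conservative, consistent with
  coding unknowns as negative.
* **Welch by default.** Published tables say "t-tests" without a variance
  assumption; the unequal-variance form with Satterthwaite degrees of
  freedom is the robust default (pooled form behind `pooled = TRUE`).
  Summary-statistic input is used because published tables *are* summary
  statistics.
* **Chi-squared without continuity correction** (samples are large
  throughout; Yates correction behind `correct = TRUE`). Degenerate
  margins raise errors naming the offending row/column rather than
  returning NaN.
* **Percentages** are displayed half-up to one decimal
  (`derived_percentage()`); p-values below 0.001 display as `<0.001`
  while exact values are kept in the machine-readable output.
* **Span matching** for evaluation is any-character-overlap, one-to-one
  (entities are judged, not offsets); exact-span mode is available.
  Document-level metrics are provided as an alternative reading of a
  fixed-size document test set; mention-level is the default.
* **Gold labels** are three-way (positive/negative/unknown). The
  non-patient-experiencer template is gold-labelled `unknown` (the gold
  scheme has no irrelevant class, and unknowns are coded as negative for
  scoring); the rule classifier still reports the finer `irrelevant`
  sublabel.
* **Undefined ratios** (precision with no retrieved entities, means of
  empty groups) are `NA`, never silently 0; empty groups skip tests.

The optional bag-of-words naive-Bayes mention classifier
(`train_mention_classifier()`) is OFF by default: the original supervised
annotators were trained on restricted real-text corpora, so the shipped
default is the deterministic rule path, and the trainable path is
exercised only against synthetic gold.

## End-to-end example

```{r pipeline}
corp <- generate_corpus(n_ad = 200, n_dlb = 50, seed = 1)
mentions <- extract_corpus(corp$documents)
profiles <- aggregate_profiles(mentions, corp$documents, corp$patients)
score_extraction(mentions, corp$gold)[c("concept", "precision", "recall")]
table1(corp$patients, profiles)
```

## Problem sizes and verification

The test suite verifies, among other properties: exact reproduction of
the headline cohort percentages from published counts; pooling identities
for full-cohort prevalences; recovery of planted prevalences within exact
binomial 99% intervals at the study's group sizes (617 DLB / 13,712 AD,
roughly 43,000 documents); perfect precision and recall on noise-free
corpora of 220 patients; agreement of the Welch p-value with an
independent quadrature of the t density to 1e-8 and of the chi-squared
p-value with a chi-square-tail quadrature, plus location inside the
discreteness bracket of a 100,000-resample fixed-margin permutation null
on small tables (the continuous tail approximation cannot agree with the
discrete permutation p to Monte-Carlo error, so the bracket
`[P(X² > obs), P(X² ≥ obs)]` is the correct oracle statement); and
byte-identical corpus regeneration under a fixed seed. Smaller corpora
(tens to hundreds of patients) are used for property-style tests.

## Known limitations

The rule classifier misreads positives whose sentence happens to contain
a cue token (e.g. a family member mentioned alongside the patient's own
symptom) and negations phrased beyond the 6-token scope. The generator's
template language is far simpler than clinical prose, and its
independence assumption understates the real co-occurrence of core
features, so the synthetic AD2CS share (about 17%) sits below the
published 18.7% — the category logic itself, not this share, is the
claim. Supportive DLB features (falls, syncope, autonomic dysfunction)
and non-AD/DLB dementias are out of scope.
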
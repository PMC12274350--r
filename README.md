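# dlbtext

Case-finding for dementia with Lewy bodies (DLB) in free-text clinical
records.

## The problem

DLB is diagnosed from four core clinical features — visual hallucinations,
cognitive fluctuations, parkinsonism and REM sleep behaviour disorder
(RBD). One recorded feature meets the criterion for *possible* DLB, two or
more for *probable* DLB. In mental-health and dementia services these
features are documented almost exclusively in free text, so patients
labelled with Alzheimer's disease (AD) whose notes describe a DLB-like
profile go unrecognised. `dlbtext` is for researchers mining electronic
health records for exactly this signal: it detects the core features in
note text, rolls them up to patient-level profiles scored against the
possible/probable-DLB criteria, and reproduces the standard two-table
cohort analysis.

## What it computes

* **Mention extraction** — case-insensitive stem lexicons (`fluctuat*`,
  `tremor*`, `bradykinesi*`, `bad dream*`, `nightmare*`, and `visual` +
  `hallucinat*` in same-sentence proximity), with rule-based
  classification of each candidate as positive vs non-positive (negated,
  uncertain/hypothetical, or about someone other than the patient). An
  optional naive-Bayes bag-of-words classifier can be trained on gold
  annotations.
* **Aggregation** — a feature is present if one positive mention occurs
  anywhere in the record (whole-record, no time window); parkinsonism =
  tremor OR bradykinesia, RBD = bad dreams OR nightmares;
  `core_count` ∈ 0–4 maps to `none` / `one_feature` / `two_plus`, and AD
  patients with 2+ features form the AD2CS stratum.
* **Cohort statistics** — group summaries (mean/SD, count/%) with Welch
  t-tests for continuous and Pearson chi-squared tests for categorical
  variables: `table1()` (DLB vs AD) and `table2()` (AD&lt;2 vs AD2CS vs
  DLB 2+, pairwise p-values).
* **Evaluation** — per-concept precision (PPV) and recall (sensitivity)
  of extracted entities against gold spans, mention-level any-overlap
  matching by default.
* **Synthetic corpus** — a seeded generator of patients, notes and gold
  annotations with the statistical structure of a memory-service cohort
  (group prevalences, demographics, negated/unknown distractor mentions),
  standing in for access-restricted source records.

## Worked example

```r
library(dlbtext)

corp     <- generate_corpus(n_ad = 200, n_dlb = 50, seed = 1)
mentions <- extract_corpus(corp$documents)
profiles <- aggregate_profiles(mentions, corp$documents, corp$patients)

score_extraction(mentions, corp$gold)[c("concept", "precision", "recall")]
#>                 concept precision recall
#> 1 visual_hallucinations         1      1
#> 2          fluctuations         1      1
#> 3                tremor         1      1
#> 4          bradykinesia         1      1
#> 5            bad_dreams         1      1
#> 6            nightmares         1      1
```

Extraction is exact on synthetic text (the generator's planted phrases are
within the rule grammar); on real clinical text this design reports
per-concept precision of roughly 83–91% and recall 84–100%.

```r
table1(corp$patients, profiles)
#>  variable                                   full       DLB         AD         p_value
#>  n                                          250        50          200
#>  Age at first referral in years (mean, SD)  79.3 (9.2) 76.6 (10.0) 79.9 (8.9) 0.034
#>  Female gender (%)                          60.8%      50.0%       63.5%      0.080
#>  Visual hallucinations (%)                  28.8%      80.0%       16.0%      <0.001
#>  REM sleep behaviour disorder (%)           12.4%      30.0%       8.0%       <0.001
#>  Fluctuations (%)                           46.0%      82.0%       37.0%      <0.001
#>  Parkinsonism (%)                           28.8%      70.0%       18.5%      <0.001
#>  ...
```

Read: in this 250-patient synthetic cohort every core feature is
significantly commoner in DLB than in AD (chi-squared p < 0.001), while
age at referral differs by a Welch t-test at p = 0.034 — the qualitative
structure of the real cohort, at a size where demographics are noisier.

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts/dlbtext-cli.R", package = "dlbtext"))')
Rscript $CLI generate  --config cfg.yml --seed 1 --out-dir corpus/
Rscript $CLI extract   --corpus corpus/documents.jsonl --out mentions.csv
Rscript $CLI aggregate --mentions mentions.csv --corpus corpus/documents.jsonl \
                       --patients corpus/patients.csv --out profiles.csv
Rscript $CLI analyze   --patients corpus/patients.csv --profiles profiles.csv \
                       --out-dir tables/
Rscript $CLI evaluate  --mentions mentions.csv --gold corpus/gold.csv \
                       --out metrics.csv
```

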
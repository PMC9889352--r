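---
title: "Methods: dictionary classification and provider profiling for MLN-FNA cytology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dictionary classification and provider profiling for MLN-FNA cytology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlnqa)
```

## The problem

Mediastinal lymph node fine needle aspiration (MLN-FNA) under endobronchial
or endoscopic ultrasound guidance (EBUS/EUS) produces a cytopathology report
whose diagnosis lives in free text.  Two quality questions hang on that
text at scale: *do individual submitting physicians/surgeons (SPS) and
pathologists differ systematically in their diagnostic rates*, and *does the
sampled nodal station shape the outcome*?  `mlnqa` turns a pseudonymized
report corpus into answers: it classifies each report into a diagnostic
category, a mutually exclusive severity group and an IASLC/AJCC nodal
station, tabulates per-provider rates, profiles providers on funnel plots
and control charts with exact binomial limits, and fits categorical
logistic regressions of provider and site effects.

## Hierarchical dictionary classification

Classification is pure string matching driven by two prioritized
dictionaries (diagnosis phrases → categories; site phrases → stations).
Text is first normalized: lower case, punctuation replaced by spaces except
hyphens joining word characters, whitespace collapsed.  Normalization is
idempotent, and all match offsets refer to the normalized text (0-based,
half-open).

Matching is greedy in *rank* order.  The default rank orders phrases by
descending length (ties lexicographic), so any phrase containing another
phrase is tried first and *consumes* its span: in
"non-small cell carcinoma" the embedded "small cell carcinoma" can never
match, which is exactly the hierarchy that keeps these two categories
separate.  `validate_conflicts()` enumerates every cross-category substring
pair and verifies rank resolves it; the packaged dictionaries load with all
conflicts resolved.  Negations are handled the same lexical way — the full
phrase "negative for malignant cells" is itself a benign-group entry that
outranks and consumes its embedded malignant substring — so no grammar
engine is needed.

Within one section, when phrases from several categories survive, the
category whose *exclusive group* is highest in the severity hierarchy
(malignant > suspicious > insufficient > benign) wins, with earliest offset
as the deterministic tie-break.  Sections are processed chronologically —
diagnosis, consultation, addenda — and the latest classifiable section
overrides earlier ones, because that is how pathology amendments function:
an addendum refining "non-small cell carcinoma" to "adenocarcinoma" changes
the final category and sets `changed_by_addendum`.  A report with no match
anywhere is `UNCLASSIFIED`; stations are matched on the
"source of specimen" section only, falling back to `UNKNOWN`.

The packaged dictionaries are representative stand-ins (synthetic, built
together with the corpus generator): they cover 20 diagnostic categories
with 83 phrases and all 24 nodal stations with 48 synonyms.  An
institutional dictionary of any size drops in through `load_lexicon()`
(TSV + YAML).

## Rates, the group median rate, and control charts

For each provider role the per-group rates are computed over providers with
at least `min_n = 250` specimens; the threshold guards both the rate
estimates and the regression below against sparse levels.  The centre line
of every chart is the **group median rate (GMR)** — the median of the
included providers' rates, *not* the pooled rate: a single high-volume
outlier should not drag the centre toward itself.

Control limits at volume $n$ and centre $p_0$ solve, under
$X \sim \mathrm{Binomial}(n, p_0)$,

$$k_{\mathrm{lower}} = \max\{k : P(X \le k-1) \le \alpha/2\}, \qquad
  k_{\mathrm{upper}} = \min\{k : P(X \ge k+1) \le \alpha/2\},$$

by exact CDF inversion.  The bands sit at $\alpha \in \{0.05, 10^{-3},
10^{-6}, 10^{-12}\}$; the outer two are so deep in the tails that a normal
approximation would be off by orders of magnitude, which is why the limits
are exact.  Because the binomial is discrete the achieved coverage is
conservative, and a count *equal* to a limit count is in control (strict
inequality flags).  Each provider also carries the two-sided tail
probability $2\min\{P(X\le k), P(X\ge k)\}$ capped at one.  The GMR is
treated as a fixed plug-in centre — no uncertainty propagation on the
centre line, matching standard funnel-plot practice — and no
multiple-testing correction is applied across providers; the flags are raw
per-provider significance statements.

Case-mix differences (a provider who mostly samples hard stations) are
handled by indirect standardization: the expected count is
$\sum_s n_{ps}\,\bar r_s$ over stations $s$ with pooled rates $\bar r_s$,
and the normalized rate is $\mathrm{obs}/\mathrm{exp} \times p_0$.  The
exact normalization used in the original practice setting is not public, so
indirect standardization was chosen as the standard epidemiological method
for this situation; raw mode is always available and charts record which
mode produced them.  Stations without pooled data are dropped from the
expectation with a warning.

## Regression

For each outcome (membership in one of the four exclusive groups, or in a
specific cancer category) the model is an additive logistic regression on
three categorical factors: SPS + pathologist + station.  The design is
first trimmed — providers under 250 specimens, stations under 20 records,
and `UNKNOWN` stations are dropped — and each factor is releveled with its
highest-volume level as reference for numerical stability.  Per-factor
significance is a likelihood-ratio test of the full model against the model
without that factor ($\mathrm{df} = \mathrm{levels} - 1$); LR was preferred
over Wald because it behaves better with small cells, and the choice is
recorded in the pipeline's JSON output (`test_type`).  Separation and
non-convergence are flagged on the result, never silent.  In-sample ROC
curves threshold the fitted probabilities over all unique values with
trapezoid areas; with purely categorical predictors the AUC is a
descriptive summary of how much outcome variation the provider/site factors
explain (most of it is intrinsic to the specimen, so AUCs sit well below 1).

## What the synthetic generator emulates — and what it does not

The generator is the package's test bed and defines its study conditions.
Defaults emulate a 7.5-year referral-centre cohort: 8,846 records, 7 SPS
and 11 pathologists assigned uniformly at random, 13 stations dominated by
7 / 4R / 4L (shares 0.351 / 0.277 / 0.146), per-station distributions over
benign / suspicious / malignant / insufficient close to such a cohort
(overall roughly 0.46 / 0.04 / 0.25 / 0.24) plus a sub-1% unclassifiable
tier rendered as prose containing no dictionary phrase.  Provider effects
enter additively on a group's log-odds before the group is drawn; because
an offset touches a single group, the binary group-vs-rest logistic model
is *correctly specified* with exactly that log-odds shift, which is what
makes the parameter-recovery checks sharp.  About 17% of initially
non-small-cell-carcinoma reports gain a refining addendum
(adenocarcinoma : squamous ≈ 77 : 21), mirroring how often amendments
override the original wording in practice.

Rendering draws a phrase of the true category into a report template;
distractor levels add neutral prose (`mild`) or group-safe dictionary
phrases such as negations and background descriptions (`heavy`), always
*after* the diagnosis phrase so the severity-then-offset rule keeps the
true category.  Records are i.i.d.: no patient-level repeat sampling, no
temporal drift, no interactions between provider and station, and no
imitation of real formatting quirks (tables, header noise, dictation
artifacts).  Passing the closed-loop tests therefore shows the machinery is
self-consistent under these conditions — it does not certify accuracy on
any institution's real reports, which is what the audit worksheet workflow
(`audit_sample()` / `audit_summary()`) is for.

## Numerical and design choices

- Exact binomial CDF inversion seeded by `qbinom` with a local adjustment
  loop; verified against full pmf enumeration for every $n \le 200$ across
  a $p_0$ grid and all four $\alpha$ levels.
- Ties: at-limit counts are in control; within-section category ties break
  by earliest offset; equal-length dictionary phrases order
  lexicographically.
- Degenerate inputs: $p_0 = 0$ or $1$ collapses both limits; constant
  outcomes, empty corpora, sub-2-level factors and oversized audit samples
  are errors, not warnings.
- Medians over an even number of providers are the mean of the middle two.
- Fractions are carried at full precision and rounded (3 decimals) only for
  display.
- The corpus format is JSON-lines with addenda as arrays (CSV secondary,
  addenda joined by `"|||"`), because addenda are ordered and multi-valued.

Test problem sizes were chosen to make each check statistically sharp while
keeping the suite quick: closed-loop classification at 10,000 records,
chart power/calibration at 11 providers × ~800 specimens over 100
replicates (an odds ratio of 2.5 on insufficiency is detected at
$\alpha = 10^{-3}$ essentially always), and parameter recovery at
$n = 5{,}000$ over 200 replicates (mean log-odds bias under 0.1).

## Known limitations

Lexical matching cannot read grammar: a negation or hedge not present in
the dictionary as a full phrase will be mis-read, and unusual report
formatting can defeat sectioning entirely — the reason real deployments
audit a random sample and iterate the dictionary.  The provider flags carry
no multiplicity correction by design.  The regression assumes random
assignment of patients to providers and stable case mix; with only
additive factors it cannot see provider-by-station interactions, and the
generator cannot create them either.
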
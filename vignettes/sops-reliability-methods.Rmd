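---
title: "Methods: multi-rater reliability analysis of SOPS ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-rater reliability analysis of SOPS ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sopsrel)
```

This vignette documents the statistical model, the classification rules,
the synthetic-data generator and the numerical and design choices behind
`sopsrel`. It is the package's own account of its methods; every
empirical statement here is one the test suite or `scripts/acceptance.R`
actually computes.

## The instrument and its scores

The Scale of Prodromal Symptoms (SOPS) has 19 items in four subscales —
positive (P1–P5), negative (N1–N6), disorganization (D1–D4) and general
(G1–G4) — each rated 0 (absent) to 6 (severe and psychotic / extreme).
`sops_catalog()` freezes this structure, including the interview order
(the general items are asked last, which is where missingness
concentrates when interviews with restless or inattentive participants
are cut short). `item_catalog()` lets the same machinery describe any
instrument with the items/subscales/0–max shape.

Summary scores are plain sums: the 19-item total, the four subscale
totals, and the combined positive + negative + disorganization (P+N+D)
total used for subthreshold-status reliability. Because published
reliability tables often report 100% valid summary scores while
individual items have missing cells, the scoring policy matters and is
explicit:

* `available_sum` (default): sum the observed items, count the missing
  ones (`n_missing_items`). This reproduces the convention of fully
  valid totals over partially valid items.
* `strict_missing`: a total containing any missing constituent is
  missing.

The policy used is recorded in the output (`policy_applied`), and a
profile with no scored items yields all-missing totals with a warning
under either policy.

`percent_valid()` is defined over subject × rater cells: with 18
subjects and 3 raters the denominator is 54, so observed values such as
94.4 (51/54) or 96.3 (52/54) arise naturally, which a per-subject
denominator could not produce.

## Subthreshold status classification

Each subject–rater profile is assigned one of five mutually exclusive
categories from the P, N and D items only (G items never contribute):

1. `acute_pos` — any positive item rated 6;
2. `pos_neg_dis` — at least one positive item rated 3–5 **and** at least
   two negative/disorganization items rated 3–6;
3. `pos` — at least one positive item rated 3–5;
4. `neg_dis` — at least two negative/disorganization items rated 3–6,
   in the absence of positive symptoms (no positive item ≥ 3);
5. `npro` — none of the above (not psychosis-prone).

The published rules do not state a tie-break, so the decision order is a
design choice made here: the acute rule is unconditional (a positive 6
dominates everything else, since rule 3's 3–5 window otherwise has no
escape for a 6), and the combined category is checked before its two
constituents because it is defined as their conjunction. This is the only
ordering under which the five labels partition all complete profiles.
Missing items count as non-qualifying (no imputation); the `complete`
flag is false whenever some assignment of the missing items could change
the category, which the implementation decides by trying the extreme
fill-ins (the qualifying counts are monotone in any fill-in, so extremes
suffice). The ordinal codes 0–4 (`npro` < `neg_dis` < `pos` <
`pos_neg_dis` < `acute_pos`) are a reporting and tie-break convention
mirroring the usual figure-legend order, not a clinical severity claim.

Two mechanical consensus operators are provided as plumbing —
`median_item` (per-item median, even counts resolved to the lower middle
value) and `majority_category` (modal category, ties broken toward the
higher ordinal code). They approximate, but are not, a clinical
consensus-by-discussion process; prevalence and CHR stratification use
them only because a per-subject label is needed. `chr_split()` labels a
subject clinical high risk (CHR) when the consensus category is anything
but `npro`.

## ICC(A,1): model and estimation

Agreement is quantified by the intraclass correlation for a two-way
random-effects model, single measures, absolute agreement:

$$y_{ij} = \mu + a_i + b_j + e_{ij}, \qquad
\mathrm{ICC}(A,1) = \frac{\sigma^2_s}{\sigma^2_s + \sigma^2_r + \sigma^2_e},$$

with independent Gaussian subject, rater and residual effects. The model
assumes raters are a random sample of exchangeable raters (appropriate
for a multi-site design where the specific raters are not of interest),
additivity (no subject × rater interaction separable from error at one
rating per cell), and homoscedastic effects.

**Complete data.** The estimate is the classical mean-squares closed
form $(MSR - MSE)\,/\,(MSR + (k-1)MSE + \tfrac{k}{n}(MSC - MSE))$, which
is algebraically identical to plugging the method-of-moments components
$\hat\sigma^2_s = (MSR - MSE)/k$, $\hat\sigma^2_r = (MSC - MSE)/n$,
$\hat\sigma^2_e = MSE$ into the variance ratio.

**Incomplete data.** Reliability studies of hard-to-assess populations
routinely lose cells (items skipped for some subject–rater pairs). The
package estimates the components on the observed incidence pattern by
method of moments: the row (subject), column (rater) and residual sums
of squares of the unbalanced additive layout are equated to their exact
expectations given the pattern — for the row quadratic form, e.g.
$E[SSA] = \sigma^2_s(N - \sum_i r_i^2/N) + \sigma^2_r(a - \sum_j c_j^2/N)
+ \sigma^2_e(a - 1)$, with $N$ observed cells, $r_i$, $c_j$ the row and
column counts and $a$ the number of subjects — and the resulting 3 × 3
linear system is solved. Every observed cell contributes; nothing is
imputed or discarded. When no cells are missing the system reduces
exactly to the complete-data estimators, and the test suite verifies
agreement with the closed form to 10⁻¹⁰ over 10⁴ random matrices. A
singular system (a pattern too sparse or disconnected to separate the
three components) is a hard error rather than a silent answer.

**Conventions for degenerate estimates.** Method-of-moments components
can be negative; the reported `components` are truncated at zero with
the raw values kept in `components_raw`. The estimate itself is the
*raw*-component ratio — this is what keeps the incomplete route exactly
equal to the closed form on complete data — capped at 1. On very small
degenerate samples the exact closed form can fall below −1 (a 2 × 3
integer matrix suffices); the estimate is deliberately not floored there,
because fidelity to the closed form was judged more useful than a
cosmetic bound. A matrix whose observed cells are all identical has an
undefined ICC and errors; an all-missing rater column is dropped with a
warning (reducing k), and subjects with no observations are dropped with
a message (they still count in `percent_valid`, which is computed on the
full grid).

**Confidence intervals.** The F-based interval of McGraw & Wong for
ICC(A,1), with the Satterthwaite-style denominator degrees of freedom.
On incomplete data the mean squares entering the interval are
synthesised from the (truncated) components using the number of retained
subjects and the harmonic means of per-subject and per-rater observation
counts as effective design sizes; this interval is approximate and
documented as such. Degenerate decompositions (e.g. perfect agreement,
where both MSC and MSE vanish) return the trivial interval (−1, 1) with
a warning rather than NaNs. Empirical coverage at the study scale
(n = 18, k = 3, true ICC 0.75, 1000 seeded replicates) is measured by
the acceptance checks and falls in the 0.92–0.98 band around the nominal
95%.

**Interpretation bands.** Estimates are banded `low` (< 0.40), `fair`
(0.40–0.59), `good` (0.60–0.74), `excellent` (≥ 0.75), with each
boundary belonging to the upper band.

**Reported sample sizes.** Published analyses sometimes report the
number of fully complete cases and sometimes the number of subjects with
any data, and the two can differ under item-level missingness. Rather
than guessing which convention a reader wants, every fit reports both:
`n_subjects` (any data) and `n_complete` (rated by every retained
rater).

## The synthetic-data generator

`simulate_ratings()` draws the latent score of subject $i$, rater $j$,
item $m$ as

$$x_{ijm} = \mu_m + \lambda_m (s_i + \delta_i) + r_j + e_{ijm},$$

discretises it through per-item strictly increasing thresholds to the
0–6 ordinal scale, and deletes cells completely at random at a base rate
plus a boost for the last-asked items. Defaults define the emulated
study conditions and are not tuned per run:

| parameter | default | why |
|---|---|---|
| `n_subjects`, `n_raters` | 18, 3 | the multi-site design size being emulated |
| `sigma2_subject` | 1 | latent variance unit |
| `sigma2_rater` | 0.05 | mild site/rater leniency, shared across items |
| `sigma2_error` | 0.15 | single-item latent ICC 1/1.2 ≈ 0.83, totals ≈ 0.96 — the good-to-excellent regime reported for this instrument |
| `chr_fraction` | 11/18 | elevated-severity mixture share; the CHR count is fixed at `round(chr_fraction * n)` to mirror a fixed study composition |
| `severity_shift` | 1.5 | separates CHR profiles without saturating the scale |
| `item_thresholds` | 0.5, 1.2, 1.9, 2.6, 3.3, 4.0 | most probability mass on ratings 0–2 with a right tail, mimicking modest symptom levels |
| `missing_rate_base` | 0.02 | sporadic missingness anywhere |
| `missing_tail_boost` | 0.10 on the last 4 items | shortened interviews hit the general block |

The generator returns ground truth alongside the records: the
single-item latent ICC $\sigma^2_s/(\sigma^2_s+\sigma^2_r+\sigma^2_e)$
and the latent ICC of the 19-item total. The two differ because summing
rescales the components — with unit loadings and a shared rater effect
the total has subject variance $19^2(\sigma^2_s + \delta^2 p(1-p))$
(the mixture adds between-subject variance, $p$ the CHR share), rater
variance $19^2\sigma^2_r$, and error variance $19\sigma^2_e$ — so the
generator computes the total-scale truth analytically and
`recovery_experiment()` scores estimates against it. Analysis functions
never read the truth sidecar.

What the generator deliberately does **not** emulate: interviewer skill
and probing style, item-specific rater biases tied to wording
(available only generically via the `per_item` rater-effect option),
informative missingness correlated with severity, within-subject
symptom change between ratings, and the discussion dynamics that create
a clinical consensus. Passing tests therefore demonstrate estimator and
rule correctness under a known, well-behaved generative model — not that
real SOPS ratings follow that model.

## Validation design and problem sizes

The suite pins every stage to an independent oracle where one exists:

* estimator vs a from-scratch loop-coded sums-of-squares oracle (itself
  cross-checked against `aov()`) on 10⁴ random complete matrices up to
  5 × 3, tolerance 10⁻¹⁰; the method-of-moments route must match the
  closed form on the same suite;
* classifier vs an independently coded transcription of the clinical
  rules, exhaustively over the reduced rating grid {0, 2, 3, 6} for the
  15 P/N/D items, enumerated through qualifying-count representatives
  with both non-qualifying fillers;
* recovery: 200 replicates at n = 500, k = 3 recover a true
  total-scale ICC of 0.75 within ±0.03 and a true 0 within ±0.05 on
  continuous totals; 1000 replicates at n = 18 measure interval
  coverage. These sizes keep the whole suite under a minute of
  estimator time while making the Monte Carlo error small relative to
  the tolerances;
* property tests: translation/scale/permutation invariance of the
  estimator, severity monotonicity and within-subscale permutation
  invariance of the classifier, G-item irrelevance, write/read
  round-trips, bit-identical simulation under a fixed seed, and
  byte-identical study reports on identical input.

Algebraic identities use a 10⁻¹⁰ tolerance; stochastic checks state
their tolerance per test and are always seeded.

## Known limitations

* The incomplete-data interval (effective-size approximation) is not an
  exact sampling interval; for heavily missing designs treat it as
  indicative. The point estimate, by contrast, uses the exact moment
  equations for the observed pattern.
* Method-of-moments components can be negative and are truncated only
  for reporting; strongly negative components signal model misfit
  (e.g. a subject × rater interaction), which a no-interaction layout
  with one rating per cell cannot detect.
* Ordinal discretisation attenuates the ICC relative to the latent
  scale (measured by `recovery_experiment()`'s attenuation gap); the
  package reports the ordinal-scale agreement, which is what raters
  actually produce, and makes the gap measurable rather than correcting
  for it.
* The consensus operators are mechanical stand-ins; prevalence computed
  from them inherits their conventions (documented tie-breaks), not
  clinical judgement.
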
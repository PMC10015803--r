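---
title: "Cumulative risk assessment of VOC and aldehyde mixtures with vocmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative risk assessment of VOC and aldehyde mixtures with vocmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocmix)
```

## The problem

Workers in settings such as hair salons inhale complex mixtures of volatile
organic compounds (VOCs) and aldehydes emitted by the products they handle.
No single-substance comparison against an occupational limit captures the
combined burden of dozens of co-occurring chemicals at individually modest
concentrations. `vocmix` implements the screening workflow occupational
hygienists use for this situation: personal breathing-zone concentrations are
converted into per-chemical *hazard quotients* against chronic, health-based
limits, summed into a *hazard index* for the mixture, and characterized by
the *maximum cumulative ratio*, which says whether the indicated risk is
driven by one substance or by the mixture as a whole.

## Exposure measures

For chemical $i$ with measured concentration $C_i$ (µg/m³ toluene
equivalents) and resolved reference value $RV_i$:

$$\mathrm{HQ}_i = C_i / RV_i, \qquad
  \mathrm{HI} = \sum_i \mathrm{HQ}_i, \qquad
  \mathrm{MCR} = \mathrm{HI} / \max_i \mathrm{HQ}_i .$$

HI at or above 1 flags potential non-cancer risk for the mixture. MCR ranges
from 1 (one chemical carries all the risk) to the number of contributing
chemicals (risk spread evenly). TVOC is the summed toluene-equivalent
concentration of the analytes in the hexane–hexadecane elution window; the
per-chemical `tvoc_included` flag controls window membership, and aldehydes
are included by default (set the flag to `FALSE` to reproduce a strict
GC-window TVOC). Because `vocmix` sums *identified, quantified* analytes, its
TVOC cannot include unidentified chromatographic peak area; TVOC from a
peak-area integration of the same samples would be somewhat higher.

Results are classified into MCR substance groups:

| Group | Condition (precedence order) | Meaning |
|-------|------------------------------|---------|
| I     | maxHQ ≥ 1                    | single substance concern |
| II    | HI < 1                       | low concern |
| IIIA  | HI ≥ 1 and MCR < 2           | combined effect dominated by one substance |
| IIIB  | HI ≥ 1 and MCR ≥ 2           | combined effect by several substances |

The raw textbook conditions overlap (maxHQ > 1 together with MCR < 2
satisfies both I and IIIA) and leave the boundaries undefined, so `vocmix`
evaluates them in strict precedence I → II → IIIA → IIIB and assigns the
boundaries explicitly: maxHQ exactly 1 is group I, and MCR exactly at the
dominance cutoff is IIIB. Both cutoffs (`risk_threshold`, default 1.0, and
`mcr_dominance_cutoff`, default 2.0) sit in `runConfig()`. The risk flag uses
HI **≥** threshold, the conservative reading of the two conventions in
circulation (strict and non-strict); the boundary case HI = 1 is therefore
flagged, and users preferring the strict comparison can raise the threshold
infinitesimally.

Substances of concern are named per group: for I, every chemical with
HQ ≥ 1; for IIIA, the maxHQ chemical. For IIIB no standard naming rule
exists, so `vocmix` reports the top contributors jointly covering at least
90 % of HI in descending HQ order — a reporting convention of this package,
not a published rule.

## Reference-value resolution

Each chemical is resolved to a single limit through a strict four-tier
hierarchy: chronic reference value (RV), then Swedish OEL, then the lowest
Nordic OEL, then the lowest international OEL. The hierarchy is ordered by
tier, never by magnitude across tiers — a numerically lower OEL never
overrides an existing RV, because RVs are chronic, health-based values while
OELs are 8-hour regulatory limits that are generally far higher. "Nordic" is
a country tag carried by the registry data, not geography hard-coded in the
package. A chemical with no value in any tier is excluded from HI (never
fatally: it still counts toward TVOC), which biases HI downward;
`registryCoverage()` quantifies that gap. In the packaged registry
(`table3Registry()`, mirroring a published Swedish hair-salon panel) 6 of the
frequently detected chemicals are unresolvable, and the published
formaldehyde CAS is retained as printed ("59-00-0") rather than silently
corrected to the standard registry number.

## Censoring at the reporting limit

Concentrations below the analytical reporting limits (defaults 3 µg/m³ for
VOCs, 0.3 µg/m³ for aldehydes) carry no numeric value. `readMeasurements()`
enforces this at ingest — both for explicit `"<RL"` tokens and for numeric
values below the class limit (moved to the censored set with a warning) — so
every downstream stage sees one canonical censored dataset, and censored
entries contribute to no numeric computation. Descriptive statistics run on
detected values only; no substitution such as RL/√2 is applied (a config
hook for imputation is a named possibility for future work, deliberately not
implemented).

## Aggregation to salons

The salon-level HQ map is the arithmetic mean of the salon's per-sample HQ
maps, treating a chemical absent from one sample's map as 0 there. Because
means commute with the HI summation, the salon HI equals the mean of the
worker HIs — consistent with evaluating a salon's arithmetic-mean HI — while
still providing a full HQ map from which salon maxHQ and MCR are recomputed.

## Descriptive and inferential statistics

`describeChemical()` reports AM, sample SD, GM = exp(mean(log x)),
GSD = exp(sd(log x)), median and range, the natural parameters for lognormal
exposure data. GSD of a singleton or constant series is defined as 1, the
multiplicative identity (some published tables print 0 there; 1 is the value
consistent with GSD's definition). `varianceComponents()` partitions
variance into between-salon and within-salon shares by the one-way
random-effects method of moments, truncating a negative between-group moment
at 0. `anovaOneway()` is the classical fixed-effects F test with the
Bonferroni pairwise post-test (pooled SD, raw p times the number of pairs,
capped at 1); a design with zero within-group variance and unequal means is
reported as F = ∞, p = 0 and flagged degenerate. `olsFit()` wraps ordinary
least squares. Analyses run on the untransformed ("normal") scale by
default; pass log-transformed values for sensitivity runs.

A practical caveat established by simulation while designing the package: at
the emulated campaign scale (10 salons × 3 workers) the method-of-moments
between-salon fraction from a *single* response has a sampling SD near 0.19
— far too noisy to interpret on its own. The supported workflow is the
pooled estimator: `varianceComponents()` on a matrix (e.g. log
concentrations of the whole panel) estimates per-chemical fractions and
averages them, which brings the SD down to roughly 0.03 at the same campaign
size because the salon effects are independent across chemicals.

## The synthetic campaign generator

`generateCampaign()` emulates the study design the analysis assumes: 10
salons × 3 workers (≈176-minute shifts) over a panel of chemicals with
lognormal concentrations. For chemical $c$ in salon $s$, worker $w$:

$$C_{csw} = \mathrm{GM}_c \exp(b_{cs} + e_{csw}), \quad
  b_{cs} \sim N(0, f\,\sigma_c^2), \quad
  e_{csw} \sim N(0, (1-f)\,\sigma_c^2), \quad
  \sigma_c = \log \mathrm{GSD}_c,$$

with $f$ (`between_frac`, default 0.28) the between-salon share of log-scale
variance — the default reflects campaigns where worker-to-worker variability
dominates salon-to-salon differences (72 % / 28 %). Each chemical draws its
own salon effect (the simplest structure matching a two-level variance
statement); cross-chemical correlation within a salon is a known extension
the generator does not model. Non-detects arise from two mechanisms, both
present in real data: a Bernoulli gate with the panel's `detect_prob`
(true absence) and censoring of generated values below the class reporting
limit. The default panel (`table3Panel()`) mirrors a published hair-salon
panel's GM/GSD/detection frequencies; two analytes whose published
concentrations sat entirely below the VOC reporting limit carry a synthetic
stand-in GM of 2 µg/m³, and singleton/constant analytes carry GSD 1.
`generateClimate()` draws salon CO₂ (lognormal, AM 628 ppm, CV 32 %),
temperature and relative humidity, optionally coupling CO₂ to salon-mean
TVOC to plant a recoverable ventilation association.

What passing tests on this generator do and do not show: they verify the
pipeline's algebra, censoring logic, classification regions and parameter
recovery under the assumed lognormal two-level structure; they cannot speak
to features real campaigns add — task-driven within-shift dynamics,
correlated chemical co-emission from shared products, or heavy tails beyond
lognormal.

## Numerical choices

* maxHQ ties are broken by lexicographic chemical name and logged.
* MCR at maxHQ = 0 is reported absent (`NA`), never a division by zero.
* Negative between-group variance moments truncate to 0; fractions of an
  all-constant response are reported absent.
* Report CSVs carry full-precision values (15 significant digits, which
  round-trips doubles) alongside display columns rounded to 1 significant
  figure, the convention of published maximum-HQ tables.
* Generation is fully deterministic given the config seed.

## Validation problem sizes

The shipped test-suite checks run at sizes chosen to make the statistical
assertions sharp while staying quick on one CPU: randomized-invariant sweeps
over 10 000 synthetic samples; lognormal parameter recovery at n = 10 000
(GM and GSD within 2 %); between-salon fraction recovery over 200 replicate
campaigns at 10 × 3 (pooled across the multi-detect panel, within ±0.10 in
≥95 % of replicates); planted MCR-group recovery over 100 seeded campaigns
per region; and 500 null simulations for p-value uniformity.

## Known limitations

* HI covers only analytes with resolvable reference values; in realistic
  registries roughly half the identified chemicals drop out, so HI
  underestimates cumulative risk, and OEL-based quotients underestimate it
  further relative to chronic RVs.
* Concentration-sum TVOC excludes unidentified peak area.
* No dermal route, no carcinogenic-risk indicators (the hazard-index
  framework targets chronic non-cancer effects), no task-level emission
  modelling.
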
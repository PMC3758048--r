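---
title: "Multi-stream street-price surveillance: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-stream street-price surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streetpricer)
```

## The problem and the model

Diverted prescription opioids are resold on a black market whose prices
are hard to observe directly. `streetpricer` estimates per-milligram
street prices from three independently collected report streams —
anonymous crowdsourced submissions, a quarterly law-enforcement
drug-diversion survey, and darknet-marketplace listings — and uses
their mutual agreement as the validation argument: if three collection
mechanisms with disjoint biases rank eight opioid molecules' prices the
same way, each stream is plausibly measuring the same underlying market.

The unit of analysis is the price per milligram of active ingredient,

$$p = \frac{\text{total price (US\$)}}{\text{units} \times \text{strength (mg)}},$$

which removes formulation and pack-size effects. Prices paid are
positive and right-skewed, so the summary statistic is the geometric
mean; equivalently, we model $\log p$ per (drug, source) cell as
approximately normal and report $\exp(\overline{\log p})$. The 95% CI is
the log-scale Student-t interval

$$\exp\!\left(\overline{\log p} \pm t_{0.975,\,n-1}\,\frac{s_{\log p}}{\sqrt n}\right),$$

the standard interval for a log-normal median. Nothing in the literature
pins down *the* CI for a geometric mean of street prices; a bootstrap
percentile interval is available (`geometric_mean_ci(method =
"bootstrap")`) and agrees closely at the sample sizes involved. With one
report the geometric mean is the value itself and the CI is flagged
undefined rather than fabricated. Zero-price reports (free sharing) have
no logarithm and carry no information about prices *paid*; they are
excluded with an audit count.

## Credibility filters

Crowdsourced data need noise reduction before estimation. The filters
run in a fixed order, each with an audited removal count
(`apply_filters()`):

1. **Eligibility** — submission date inside the analysis window
   (defaults to calendar 2012), country of transaction, and for
   marketplace listings a US shipping origin. A switch
   (`date_basis`) selects submission vs transaction date, because the
   collection systems timestamp entry, not the transaction.
2. **Completeness** — a per-mg price needs a dose strength (and the
   crowdsourced form records a formulation); incomplete reports cannot
   be standardized and are removed.
3. **Outlier ratings** — submissions rated 1 ("cheap") or 5
   ("overpriced") on the 5-point visual-analog price scale are
   user-identified price outliers and are excluded; unrated reports
   pass, since only reports *positively identified* as outliers are
   excluded. About a quarter of crowdsourced submissions carry endpoint
   ratings; this is a property of the data stream, not a target of the
   filter.
4. **Duplicates** — two same-IP, same-drug submissions less than 10 s
   apart almost certainly record one transaction twice; the earliest is
   retained (the original submission). For chains (0 s, 6 s, 12 s) the
   package uses a sliding anchor — a report is removed only when it
   falls inside the window of the most recently *retained* report — so
   the first and third survive. Dyads are unambiguous; the chain rule is
   this package's documented choice, property-tested against a
   brute-force oracle.
5. **Bulk flag** — purchases of more than 10 units are flagged, not
   excluded, by default; per-unit prices fall with quantity, and bulk
   status was self-reported and optional. `exclude_bulk = TRUE` turns
   the flag into a filter.

Rule order affects only the audit attribution, not the final kept set,
except for the duplicate rule (whose anchor depends on which group
members remain); a property test verifies kept-set invariance under
permuted rule order with deduplication last.

## Currency conversion

Marketplace prices are posted in bitcoin and converted at the daily
weighted-average US\$/BTC rate of the posting day, with no
interpolation: a posting date absent from the rate table rejects that
row. The rate table is interpreted as **US dollars per bitcoin**
(≈ 11 US\$/BTC in October 2012); period documents sometimes quote the
pair in the inverted direction, so the orientation is stated explicitly
here and validated by magnitude in the synthetic round-trip tests.
Monetary values are rounded half-to-even — totals to cents, per-mg
prices at 4 decimals — so all arithmetic is reproducible at the cent
level.

## Cross-validation statistics

Source agreement is the Spearman rank correlation of per-drug geometric
means over the drugs each pair of sources shares (at least 3 required).
Correlating the cell means, rather than pooled raw reports, matches the
design: the question is whether the *summaries* agree. For n ≤ 10 drugs
the permutation null is enumerated exactly (8 drugs → 40 320
arrangements) and the two-tailed p-value is the proportion of
arrangements with $|\rho|$ at least the observed; asymptotic formulas
are not trustworthy at n = 8. The t-approximation
($t = \rho\sqrt{(n-2)/(1-\rho^2)}$) is retained for larger n and as the
method contemporaneous statistical software used for its printed
p-values; both are exposed via `exact_n_max`. Ties use average ranks
(Pearson-on-ranks), and degenerate constant rankings are an error
rather than a silent NA.

Per-drug price differences across sources are tested by Welch
(heteroscedastic) one-way ANOVA on log prices (`oneway.test`), chosen
for robustness to the very unequal group sizes (e.g. 454 vs 16
morphine-cell reports) and variances; with two sources it reduces
exactly to the squared Welch t. The choice of test is a documented
package decision — the original per-drug comparison did not name its
test — and no multiplicity correction is applied by default, matching
per-drug reporting; `compare_all_drugs(p_adjust_method = "bonferroni")`
provides one.

## Predicted relative potency

The market's implicit potency estimate for drug $d$ is
$\hat\pi_d = \mathrm{GM}_d / \mathrm{GM}_\text{morphine}$, compared
against the clinical equianalgesic factor (mg morphine per mg drug,
VA/DoD 2012 table; shipped as an editable CSV because published
conversion guides differ). The CI for the ratio is a nonparametric
bootstrap (2000 resamples, percentile, fixed seed): each drug's reports
and morphine's are resampled independently and the log-ratio of
geometric means recomputed. Interval arithmetic on the two marginal CIs
is *not* valid for a ratio and demonstrably does not reproduce printed
ratio intervals; the bootstrap is the package's documented choice, so
only point ratios — not ratio CIs — are treated as exactly reproducible
quantities. Comparison labels follow the CI: `indistinguishable` when it
contains the clinical factor, `valued_higher`/`valued_lower` otherwise.
Drugs without an accepted oral conversion factor (buprenorphine) keep
their ratio but get no label. Display rounding is 1 decimal, 2 decimals
below 0.5. These ratios measure market valuation — desirability,
euphoria, withdrawal prevention — not analgesic equivalence, and must
not be used for clinical conversion.

## What the synthetic generator emulates

`default_generator_params()` encodes the published 2012 study
conditions: per (drug, source) cell the true geometric mean and report
count are the printed summary values (954 crowdsourced, 737
law-enforcement, 147 marketplace reports in total across 8 drugs), and
the log-scale SD is back-solved from the printed CI half-width via the
log-t interval rather than invented. On top of the clean log-normal
draws the generator injects what the filters are designed to absorb,
with rates that are study conditions where stated (25% endpoint-rated
outliers, 10% bulk flags) and realistic fixed choices where not (5%
duplicate clones at a 5 s gap, 5% missing strengths, typical US unit
strengths per drug). Outlier prices are coupled to endpoint ratings
(multiplied or divided by a uniform 4–10× factor, rated 5 or 1
accordingly) because the rating filter presumes users flag extreme
prices. Each cell draws from its own seeded RNG stream, so adding a
drug never perturbs another cell's data.

Because outlier, duplicate and missingness selection are independent of
the clean price draw, the filtered stream remains iid log-normal; the
recovery study (`recovery_study()`, 200 replicates) verifies |relative
bias| < 2% and ~95% CI coverage for cells with n ≥ 40. What passing
these tests does **not** show: real crowdsourced prices need not be
log-normal, real outliers need not announce themselves via ratings,
real duplicates need not share an IP hash, and price levels drift over
time — the generator validates the machinery, not those assumptions.

## Numerical and scale choices

* Exact permutation capped at n = 10 (10! ≈ 3.6M arrangements); all
  study-relevant cases have n = 8.
* Bootstrap and pipeline runs are seeded; identical seed and
  configuration reproduce byte-identical outputs.
* The recovery study uses 200 replicates of the full ~1 900-report
  study (~1 minute), enough for a 0.4% Monte-Carlo SE on pooled
  coverage; test-suite property loops use 8–40 cases per property at
  fixed seeds.
* Degenerate inputs error loudly: empty or nonpositive prices in the
  geometric mean, constant rankings in ρ, all-zero variance groups in
  the Welch test, missing exchange-rate dates.

## Known limitations

The pipeline deliberately omits geographic and temporal stratification
of prices, law-enforcement sampling design, fentanyl patches and
tapentadol (too few reports in the source study), live collection from
websites or Tor services, and any behavioral-economic modeling of
willingness to pay. The hydrocodone predicted-potency value printed in
the source era (1.5) is not reproducible from the printed means (0.81 /
0.52 rounds to 1.6 — the original likely divided unrounded means), so
exact reproduction claims exclude it; the same applies to printed ratio
CIs.
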
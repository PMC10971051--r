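---
title: "Methods: evidence synthesis and cost-utility model for bone conduction hearing implants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence synthesis and cost-utility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bchicea)
```

## The problem

Bone conduction hearing implants (BCHIs) rehabilitate conductive or mixed
hearing loss (CHL/MHL) and single-sided deafness (SSD) when conventional
hearing aids cannot. Two transcutaneous device classes compete: an active
system with an implanted piezoelectric transducer ("osia" in this package's
fixtures) and a passive magnet-retained system ("baha"). No head-to-head
trial with utility follow-up exists, so the comparison must be indirect:
each system's prospective single-arm studies measure patients before and
after implantation against their own unaided baseline, and the two systems
are compared on their *changes from baseline*. Those changes then drive a
cost-utility model from an Australian healthcare perspective.

`bchicea` implements that full pipeline: subgroup pooling, random-effects
meta-analysis, anchored indirect comparison, event-rate derivation, a
Markov cohort model, and univariate plus probabilistic sensitivity
analyses. Every input is a small transcribed summary table shipped under
`inst/extdata/`; nothing is downloaded.

## Evidence synthesis

**Subgroup pooling.** Studies often report CHL/MHL and SSD subgroups
separately. `pool_subgroup_summaries()` recovers the whole-cohort mean and
SD exactly:
$$\bar Z = \frac{m\bar X + n\bar Y}{m+n}, \qquad
SD(Z)^2 = \frac{(m-1)VAR(X) + (n-1)VAR(Y) + m(\bar X-\bar Z)^2 +
n(\bar Y-\bar Z)^2}{m+n-1}.$$
This is an algebraic identity, not an approximation: the test suite checks
it to machine precision against concatenated synthetic patient records. A
consequence worth noting: pooling two subgroups with *identical* sample
means and variances gives a pooled SD slightly *below* the common value
(the between-group term is zero while the denominator grows), so "identical
subgroups leave SD unchanged" is only asymptotically true.

**Meta-analysis.** `meta_analyze()` pools study arms by inverse-variance
weighting with the DerSimonian–Laird moment estimator of between-study
variance $\tau^2$, truncated at zero. The variance of an arm mean is
$sd^2/n$ from the printed summaries. The choice matters: for the
speech-in-quiet endpoint the two active-system arms are heterogeneous
($Q = 1.18$, $\tau^2 \approx 4.27$), and only the random-effects weights
reproduce the published pooled change of 58.80 [51.74, 65.86]
(fixed-effect pooling gives 58.99). Confidence intervals use the standard
normal quantile (1.959964 at 95%), not Student's t — back-calculating the
published single-study intervals confirms z.

**Indirect comparison.** `itc_difference()` computes
$\bar D = \bar O - \bar B$ with
$SE(\bar D) = \sqrt{VAR(\bar O) + VAR(\bar B)}$, unadjusted for baseline
differences between the cohorts (the anchoring is through each cohort's
own unaided baseline). Significance is judged at 5% with no multiplicity
correction. Endpoint-to-study mapping is data, not code: the speech-in-noise
comparison uses only the study that presented noise from behind (matching
the comparator's test geometry), and the 6-month utility comparison uses
the single active-system study reporting at 6 months — these exclusions
are simply rows absent from the fixture for that endpoint/timepoint.

Because the fixtures carry the published 2-decimal summaries rather than
patient-level data, derived quantities can differ from the published ones
in the last printed digit (e.g. the speech-in-quiet difference computes to
15.355 vs the printed 15.35). Tests therefore assert indirect-comparison
results at ±0.01. One cell is genuinely ambiguous: the published pooled
pre-operative utility prints 0.67 while inverse-variance pooling of the
printed arms gives 0.6646 (and patient-count weighting 0.666); the paper's
weighting is unstated. The meta function reports what it computes; the
Markov model uses the published model input 0.67.

## Event rates

Monthly rates are events over person-time: 3 soft-tissue complications per
786 exposure-months (0.38%/month) and 1 reoperation per 786 (0.13%) for the
active system; 4 per 324 (1.23%) and 4 per 1296 (0.31%) for the passive
system. The mixed exposure windows (6-month window for complications,
24-month for reoperations in the comparator) follow the source tables
verbatim. Rates convert to quarterly probabilities as constant hazards,
$p = 1-(1-r)^3$, which stays bounded in $[0,1)$; at these magnitudes it
differs from linear scaling by under 0.01 percentage points. Passive-system
reoperations split half explantation / half reimplantation (2 and 2
observed events); the single active-system reoperation was an explantation.
Soft-tissue complications are cost-only events: a management tariff per
expected event, no state change, no disutility.

## The Markov cohort model

Nine states: `aided_first`, `aided_revised`, four tunnel quarters,
`aided_second`, `unaided`, `dead`. Quarterly cycles, half-cycle correction,
start age 47.146 years (patient-count-weighted mean of the two
active-system cohorts, which the source does not print), 10-year base-case
horizon (the implant warranty period), 5% annual discounting.

Each cycle, aided patients face the arm's reoperation probability:
revisions keep the current device, explantations are permanently unaided
at baseline utility, reimplantations enter a one-year tunnel replaying the
rehabilitation utilities (baseline, then +3-month gain, then +6-month
gain). A second device carries the same risks, but no third device is
offered: any non-revision reoperation of a second device leads to
`unaided`. Background mortality applies to every alive state as
$1-(1-q_x)^{1/4}$ from a year-of-age lookup.

Utilities: both arms share the pre-operative baseline 0.67 so the
incremental QALYs are driven by the gains (active: 0.09 at 3 and 6 months;
passive: 0.06, with its unreported 3-month gain set equal to the 6-month
gain). The first post-operative quarter is valued at baseline (the
alternative — immediate gain — is unstated in the source and can be probed
via the utility schedule). Utilities from 6 months onward are constant, as
hearing loss at this severity does not spontaneously improve and device
output is maintained by fitting adjustments.

Costs (AUD 2022, no inflation adjustment): device + surgery +
hospitalisation at $t=0$; surgery + hospitalisation per reoperation;
soft-tissue management per expected event; sound-processor upgrades every
5 years weighted by aided occupancy. Two conventions deserve their own
paragraphs because the published per-arm totals pin them down.

*Reoperation costing.* The tariff table has no reoperation-specific rows.
Costing a reimplantation with a new device tariff overshoots the
comparator arm's published total by roughly $1,400 and drags the
undiscounted ICER ~25% below its published value; costing every
reoperation type as surgery + hospitalisation (the replacement implant
treated as warranty-covered, consistent with the warranty motivating the
10-year horizon) reproduces both arms' published totals within ~1%. The
latter is the default; `reimplant_includes_device = TRUE` restores the
alternative.

*Upgrade timing.* Upgrades at 5-year intervals are applied at every
anniversary up to and including the horizon boundary (years 5 and 10 in
the base case). Excluding the boundary upgrade leaves the intervention
arm ~$6,100 short of its published undiscounted total; including it lands
within ~1%.

Continuous accruals (QALYs, AE costs) use half-cycle-corrected occupancy
discounted at cycle midpoints; one-off costs are discounted at event time
(midpoint of the transition cycle for reoperations, the exact anniversary
for upgrades, $t=0$ undiscounted for the initial episode). With the
packaged life table the base case gives a discounted ICER of ~$29.7k/QALY
(published: $29,301; +1.3%) and undiscounted ~$24.1k (published: $24,301;
−0.7%). Exact equality is not expected: the source's life-table edition and
first-quarter utility convention are unpublished.

## The life table

The shipped `life_table_synthetic_aus.csv` is **synthetic**: a
Gompertz–Makeham curve $q_x = 4\times10^{-4} + 1.72\times10^{-5}
e^{0.0977x}$, ages 0–100, calibrated to recent sex-averaged Australian
adult mortality ($q_{47}\approx0.0021$, $q_{67}\approx0.012$,
$q_{87}\approx0.085$). It is *not* an official table; childhood mortality
in particular is only order-of-magnitude correct, which is immaterial for
a cohort starting at age 47. `make_life_table()` also provides constant-q
and fixture-file models, and the test suite checks engine survival against
the continuous Gompertz–Makeham closed form.

## Sensitivity analyses

`run_univariate()` solves one scenario per parameter dimension: horizons of
5 years and lifetime (to age 100), discounting 2.5%/7.5%, procedure and AE
costs ±10%, converging transition probabilities (the comparator's rates
interpolate linearly to the intervention's between months 12 and 24 — the
conservative direction, since the common long-run value is unpublished),
and CHL/MHL-only utilities (baseline 0.62, gains 0.12 vs 0.06). The
reproduced ordering matches the published qualitative pattern: 5-year
horizon ~$52.6k > base ~$29.7k > lifetime ~$16.2k, and CHL/MHL ~$15.2k.

`run_psa()` re-solves the deterministic engine per Monte Carlo draw.
Distributions are method-of-moments: beta for the shared baseline utility
(meta-analysis SE) and for the comparator's explantation fraction (2/2
events); gamma for each tariff (SE = 10% of the mean, matching the ±10%
univariate range, since no cost dispersion is published); beta
(events, exposure − events) for monthly event rates; normal for start age
and utility gains. Draws are consumed in a fixed, documented order from a
single seeded stream; a zero SE makes the corresponding parameter
degenerate, so an all-zero-SE configuration reproduces the base case in
every draw.

**Why utility-gain draws share a common deviate.** The two arms' gain SEs
(0.033 and 0.036) are large relative to the 0.03 increment. Sampling the
gains independently makes the incremental QALYs negative in
$\Phi(-0.03/0.049)\approx27\%$ of draws, which caps the acceptability
curve at ~0.73 at any threshold — irreconcilable with the published
finding that more than 80% of iterations were cost-effective. The
published probabilistic result is therefore only attainable if the arm
gains co-vary. The default `gain_model = "common"` scales all gain draws
with one standard-normal deviate: each gain keeps its marginal
distribution (so total QALY uncertainty is honest) while the between-arm
increment is held at its point estimate — i.e., the PSA treats the *level*
of post-implant utility response as uncertain and the comparative evidence
as fixed. With it, CEAC($50{,}000$) ≈ 0.89. `gain_model = "independent"`
implements fully independent draws; users quantifying the comparative
uncertainty itself should prefer it and will see CEAC values near 0.6,
with the caveat that it double-counts the shared rehabilitation response.

## What the synthetic data generator does and does not emulate

`generate_study()` draws per-patient endpoint values from independent
normals per subgroup — exactly the moment structure the pooling and
meta-analysis formulas consume, which makes the algebraic round-trip
(`summarize_records()` → `pool_subgroup_summaries()` = whole-sample
summary) exact on every dataset, not just in expectation. It does not
emulate audiogram structure, within-patient correlation between endpoints,
ceiling effects in speech scores, or utility distributions' skew. A green
pooling test therefore establishes the algebra, not the realism of any
distributional assumption.

## Numerical conventions and degenerate inputs

* Transition-matrix rows are validated to sum to 1 within $10^{-9}$;
  occupancy is validated each cycle (non-negative, sums to 1 within
  $10^{-9}$; in practice drift stays below $10^{-12}$ over 40 cycles).
* `meta_analyze()` with one arm returns it unchanged; zero-variance arms
  are rejected when they would absorb all weight.
* Zero incremental QALYs flag the ICER undefined rather than dividing.
* Lifetime horizons stop at age 100 (the last life-table row is carried
  forward beyond the table).
* Seeds are mandatory arguments wherever randomness exists; the global RNG
  state is saved and restored around every seeded routine.

## Known limitations

Cohort-level (no microsimulation), healthcare-perspective costs only, no
bilateral implantation, no device-failure modelling beyond the observed
reoperation rates, no value-of-information analysis, and no correlation
structure between cost and utility parameters beyond the documented
utility-gain deviate. The evidence base itself is three single-arm studies
totalling 134 patients; everything downstream inherits that fragility.
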
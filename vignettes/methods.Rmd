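---
title: "Methods: the fatal-diameter screening microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fatal-diameter screening microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screensim)
```

## The model in one page

`screensim` simulates a 1970 birth cohort of women. Each woman draws an
other-cause death age from a life table; with probability equal to the
lifetime breast-cancer risk she also draws one tumor. Tumor biology is the
fatal-diameter mechanism: exponential diameter growth from 0.01 cm and three
per-tumor threshold diameters — screen detectability (`d_screen`), clinical
surfacing (`d_clinical`), and fatality (`d_fatal`). Diagnosis strictly
before the fatal diameter cures; at or beyond it, breast-cancer death is
already scheduled at the fatal-crossing age plus an exponential survival
time, censored by other-cause death. Earlier detection therefore helps in
exactly two ways: it can move diagnosis ahead of the fatal diameter
(mortality benefit), and it moves diagnosis to a smaller size and earlier
stage (cost and quality-of-life consequences, beneficial or not).

A configurable fraction of tumors begins as ductal carcinoma in situ
(DCIS). During a lognormal pre-clinical dwell the lesion can be
screen-detected with the test's per-round DCIS sensitivity; if it escapes
screening it regresses, progresses to invasive disease (the invasive growth
clock starts at the end of the dwell), or surfaces as clinical DCIS, with
configurable fate probabilities. In-situ detection always cures — including
a progressing lesion, which is the mortality benefit of DCIS detection —
and screen-detecting a lesion that would never have surfaced before
other-cause death is an overdiagnosis.

Screening applies a policy (default: biennial, ages 50–74, full attendance)
and a test (`dcis_sensitivity`, `median_detect_size`, `specificity`,
`price`). The per-tumor `d_screen` is Weibull with
`scale = median_detect_size / (ln 2)^(1/shape)`, so the configured median is
the size at which half of tumors are detectable. Women exit screening
permanently at any diagnosis; screens never occur after death.

## The parallel-universe design and common random numbers

Every scenario is a deterministic transformation of one cohort object. The
cohort stores *uniform variates* rather than realized screening quantities:

- `u_detect` maps through the scenario's Weibull quantile function to
  `d_screen`, so a tumor that is hard to find under one test is
  correspondingly hard to find under every test, and detection-size medians
  can be swept without re-simulating natural history;
- `u_dcis_detect` maps through the geometric first-success quantile
  (`trials = 1 + floor(log(1−u)/log(1−s))`) to the round at which a
  dwelling DCIS lesion is found, so a higher DCIS sensitivity always
  detects at least as early.

Sampling uses named substreams (mortality, onset, biology, screening,
survival) derived from the master seed, so redrawing one component never
perturbs another. Consequences used by the tests: an undetecting, perfectly
specific test reproduces the no-screening universe *exactly*; contrasts
between scenarios carry no natural-history Monte-Carlo noise; and no woman
is ever worse off screened than unscreened (screen detection either cures
her or leaves her death unchanged).

False positives are handled in expectation: a screen of a woman with no
detectable cancer is falsely positive with probability `1 − specificity`.
Since a false positive changes neither the schedule nor the disease course,
the expected count `(1 − specificity) × (negative screens)` is exact, makes
the false-positive burden affine in `1 − specificity` by construction, and
removes a large variance component from QALY and cost contrasts. A round at
which an undetected DCIS lesion is present counts as a miss, not as a
false-positive candidate. The 10.6% biopsy share of false-positive workups
is likewise applied in expectation.

## Parameters, defaults, and calibration

Test characteristics (the scenario grid): DCIS sensitivity 0.91 or 0;
median detection size 1.03–1.39 cm in 0.06 steps, plus 0.61 and 0.01 cm for
near-perfect invasive sensitivity; specificity 0.88, 0.96, 1.00. The
comparator is digital mammography: DCIS 91%, median 1.21 cm, specificity
88%, USD 149 per screen.

Natural-history defaults (`natural_history_params()`), chosen once:

| parameter | default | rationale |
|---|---|---|
| lifetime risk | 0.13 | ~1-in-8 US lifetime breast-cancer risk |
| onset age | N(52, 12²) on [25, 90] | clinical diagnoses center near age 62 after ~10 years of preclinical growth |
| growth rate | LogNormal(log 0.55, 0.40²) /yr | onset-to-2 cm times of roughly 6–15 yr; screen-detectable sojourns of 1–2 yr |
| Weibull shape | 2.0 | moderate spread around the median; exposed in config because only the median is externally specified |
| `d_clinical` | LogNormal(log 2.85, 0.35²) cm | calibrated (below) |
| `d_fatal` | LogNormal(log 2.4, 0.90²) cm | heavy left tail puts a share of tumors beyond help at screen-detectable sizes, tempering the mortality benefit |
| DCIS fraction | 0.30 | DCIS ≈ one fifth to one quarter of screen-era diagnoses |
| DCIS fates | regress 0.50 / progress 0.25 / clinical 0.25 | regression-dominated mix; makes most overdiagnoses DCIS-driven |
| DCIS dwell | LogNormal(log 1.5, 0.60²) yr | short enough that ~10% of clinically destined DCIS escapes biennial screening |
| survival after fatal crossing | Exponential, mean 3 yr | advanced-disease survival scale |
| life table | Gompertz–Makeham, `4e-4 + 2.6e-5·e^(0.102x)` | synthetic stand-in for a US 1970 female cohort; life expectancy ≈ 79 |

Exponential growth with lognormal rates was chosen because it is the
standard companion of threshold-diameter models and has a closed-form
inverse, which the event scheduling (crossing ages) uses directly.

**Calibration.** The published full-scale analyses behind this model family
are calibrated to US registry (SEER) incidence and screening-registry
(BCSC) performance data that this package deliberately does not ingest.
Instead, the defaults were calibrated once so that the *comparator's
conversion ratios* — the proportions of cancers diagnosed at ages 50–74
that are screen-detected — land near the reference values 89% (DCIS), 70%
(invasive), 74% (combined): `d_clinical`'s median is the main lever for the
invasive proportion, the DCIS dwell and fate mix for the DCIS proportion.
After calibration the defaults are frozen; the acceptance tests check that
fresh seeds recover 74% combined within Monte-Carlo error. Ratio-type
outputs (sensitivity conversions, overdiagnosis reductions, orderings
across test characteristics) transfer well under this strategy; absolute
per-1000 levels do not (see limitations).

## Outcomes, discounting, and economics

Life-years are counted from age 30 (the reference age) to death and
discounted continuously at annual rate 3%:
`∫ (1.03)^{−(t−30)} dt`, evaluated in closed form. QALYs subtract additive
decrements `(1 − utility) × duration × discount`: utility 0.994 for 1 week
per attended screen; 0.895 for 5 weeks per workup (true positive, false
positive, or clinical presentation); and stage-specific care utilities by
phase — initial (first 12 months after diagnosis), continuous, terminal
(last 12 months before breast-cancer death, utility 0.49 at every stage),
terminal-OCD (final year of an other-cause decedent with a breast-cancer
history). When a woman survives less than two years from diagnosis the
terminal phase takes precedence and the initial phase is truncated, so the
three phases always partition diagnosis-to-death exactly. Events dated
before age 30 (possible for rare fast-growing tumors with young onset) are
clamped to the reference age rather than inflated — time lived before 30 is
outside the accounting horizon. Stages at diagnosis use the standard T-size
breakpoints (< 2 cm local, 2–5 cm regional, ≥ 5 cm distant, half-open and
lower-inclusive; in situ for DCIS), configurable because nothing in the
mechanism pins them.

Costs mirror the utility structure: per-screen price; false-positive
imaging plus expected biopsy share; diagnostic workup by age band at every
detection; care costs by stage and phase, with initial/terminal amounts
accrued over their windows (pro-rated when truncated) and continuous costs
per year. Diagnoses before age 50 use the youngest cost band. Total cost is
*exactly* affine in the per-test price with slope equal to the discounted
screen count, so scenarios are simulated once at a reference price (0 for
tests with no listed price) and the maximum cost-effective price against
the comparator is closed-form:
`P* = P_ref + (λ·ΔQ − ΔC(P_ref))/S` at threshold λ = USD 50,000/QALY.
Scenarios with fewer QALYs than the comparator get no price: under a
willingness-to-pay criterion no price makes a net health loss acceptable.
The counting window for sensitivity conversions includes diagnoses from the
50th to before the 75th birthday.

## What the generator emulates — and what it does not

The synthetic cohort emulates the *structure* the analysis needs: seeded
reproducibility, a calibratable mix of screen-detected and interval
cancers, DCIS-driven overdiagnosis, stage shifts with detection size, and
death pathways competing between breast cancer and other causes. It does
not emulate: age-dependent test performance (held constant per scenario),
multiple primaries (at most one tumor per woman), birth cohorts other than
1970, non-attendance correlation structure (attendance draws are
independent per round), or registry-calibrated incidence curves.
Passing tests therefore demonstrate internal correctness and directional
behavior, not agreement of absolute rates with US registry data.

## Problem sizes and numerical choices

Unit and property tests run on a shared 20,000-woman cohort; parameter
recovery uses 200,000 women (the scale at which the combined-sensitivity
Monte-Carlo error is ~0.3 percentage points); the directional grid
comparison uses 10⁶ women. The acceptance script simulates 200,000 women.
These sizes were chosen so the full suite runs in minutes on one core while
keeping every assertion comfortably outside its Monte-Carlo noise floor;
the reference full-scale analyses used 10⁷ women. Degenerate inputs are
handled explicitly: zero-risk cohorts simulate cleanly (the scenario runner
reports undefined sensitivities and mortality reduction as `NA`), all-zero
detection counts and zero control deaths are errors in the low-level
converters, ties at threshold diameters resolve against cure (detection
*strictly* before `d_fatal` cures), and the last life-table row carries a
closing hazard so no woman outlives the table.

## Known limitations

- Absolute per-1000 levels (false positives, overdiagnoses, total costs,
  QALY levels) differ from registry-calibrated full-scale results; only
  ratios, conversions, and orderings are comparable. For example, this
  parameterisation yields ~9 overdiagnoses per 1000 for the comparator
  versus ~18 in calibrated full-scale work, while reproducing the ~90%
  overdiagnosis reduction when DCIS detection is switched off.
- The net QALY effect of DCIS detection (mortality benefit of intercepting
  progressing lesions vs. harms of overdiagnosed care) is
  calibration-sensitive; under these defaults it is mildly negative,
  so no-DCIS scenarios can weakly dominate the comparator on QALYs.
- Treatment enters only through stage-dependent cure, costs, and
  utilities; there is no explicit therapy model beyond the fatal-diameter
  mechanism.
- The federal-payer perspective excludes patient time and productivity
  costs; no probabilistic sensitivity analysis is provided.
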
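# screensim

A desk-scale microsimulation of breast cancer screening built on the
**fatal-diameter** natural-history paradigm, with a parallel-universe design
for causal screening contrasts and a cost-effectiveness layer for pricing
novel screening tests — in particular, hypothetical cell-free DNA liquid
biopsies whose test characteristics are swept over a grid.

## Who this is for

Health-economics and screening-policy modelers who want a transparent,
fully seeded R implementation of the classic discrete-event screening
machinery: simulate a birth cohort of women, resolve each woman's breast
cancer course with and without screening on identical random draws, and
convert the per-woman contrasts into the quantities decision makers use —
mortality reduction, overdiagnoses, false positives, discounted QALYs,
ICERs, and the maximum per-test price at a willingness-to-pay threshold.

## The model

Every simulated tumor starts at diameter 0.01 cm and grows exponentially,
`d(t) = 0.01 · exp(g·t)`, with a per-tumor growth rate `g ~ LogNormal`.
Each tumor carries three *threshold diameters*:

- `d_screen` — screen detectability, drawn from a Weibull whose **median**
  equals the screening test's "median tumor size for screen detection"
  (`scale = median / (ln 2)^{1/shape}`);
- `d_clinical` — the size at which it surfaces clinically;
- `d_fatal` — the fatal diameter: detection strictly before this size cures;
  detection at or after it cannot prevent breast-cancer death, which occurs
  at the fatal crossing age plus a drawn survival time, censored by
  other-cause death.

A DCIS compartment precedes invasive disease for a configurable fraction of
tumors: during a pre-clinical dwell the lesion is screen-detectable with the
test's per-round DCIS sensitivity, after which it **regresses**, **progresses
to invasive cancer**, or **surfaces as clinical DCIS**. Screen-detecting a
regressing DCIS — or any cancer in a woman who would have died of other
causes undiagnosed — is an *overdiagnosis*.

Screening follows a biennial 50–74 schedule by default (13 rounds). A
woman with no detectable cancer is falsely positive with probability
`1 − specificity`; false positives are accounted in expectation, which makes
the false-positive count exactly affine in `1 − specificity`.

The economic layer discounts everything at 3%/year to age 30, prices events
from stage- and phase-of-care cost tables (2020 USD), applies utility
decrements `(1 − u) × duration`, and compares each scenario to the
digital-mammography comparator:

- `ICER = ΔC / ΔQ`,
- maximum per-test price
  `P* = P_ref + (λ·ΔQ − ΔC(P_ref)) / S`, where `λ` is the threshold
  (USD 50,000/QALY), and `S` the discounted screen count — exact because
  total cost is affine in the per-test price.

## Worked example

```r
library(screensim)

cohort  <- sample_life_histories(2e5, natural_history_params(), seed = 1)
control <- natural_course(cohort)

specs <- list(
  comparator_spec(),  # digital mammography: DCIS 91%, median 1.21 cm, spec 88%
  scenario_spec("LB no-DCIS, spec 100%",    test_characteristics(0,    1.21, 1.00)),
  scenario_spec("LB small-tumor, spec 96%", test_characteristics(0.91, 1.09, 0.96))
)
results <- run_grid(specs, cohort, control = control)
results[, .(label, combined_pct, mortality_reduction_pct,
            false_positives_per_1000, overdiagnoses_per_1000,
            qalys_gained_per_1000, max_price_usd)]
```

```
                      label combined_pct mortality_reduction_pct
1:      digital mammography           74                    27.5
2:    LB no-DCIS, spec 100%           62                    25.1
3: LB small-tumor, spec 96%           77                    30.2
   false_positives_per_1000 overdiagnoses_per_1000 qalys_gained_per_1000 max_price_usd
1:                     1203                   9.00                  43.7            NA
2:                        0                   1.04                  49.8           291
3:                      401                   9.20                  52.9           286
```

Reading the table: the comparator screen-detects 74% of cancers diagnosed
at ages 50–74 and reduces breast-cancer mortality by 27.5% against no
screening, at the price of ~9 overdiagnoses and ~1200 false positives per
1000 women. A liquid biopsy blind to DCIS prevents almost 90% of the
overdiagnoses (1.04 vs 9.00) but gives up mortality reduction; with perfect
specificity it still nets more QALYs than mammography, and stays
cost-effective at USD 50,000/QALY up to USD 291 per test on this cohort.
`export_roc_points(results)` emits each scenario as a (FPR, TPR) overlay
point with its maximum price for plotting against an externally published
ROC curve.

All results are deterministic given `(n, params, seed)`: scenarios share
one cohort and differ only in how its stored uniform variates are
transformed, so between-scenario contrasts carry no Monte-Carlo noise from
natural history.

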
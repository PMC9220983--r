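Package: screensim
Title: Fatal-Diameter Microsimulation of Breast Cancer Screening and
    Cost-Effectiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-event microsimulation of breast cancer natural history
    under the fatal-diameter paradigm: each simulated tumor grows exponentially
    from 0.01 cm and carries its own threshold diameters for screen
    detectability, clinical surfacing, and fatality, with a ductal carcinoma in
    situ (DCIS) compartment that may regress, progress to invasive disease, or
    surface clinically. A parallel-universe design resolves every simulated
    woman with and without screening on identical random draws, yielding
    per-woman causal screening effects: mortality reduction, overdiagnoses,
    false positives, discounted life-years and quality-adjusted life-years.
    A cost-effectiveness layer prices every event from stage- and
    phase-of-care cost tables, computes incremental cost-effectiveness ratios
    against a digital-mammography comparator, and solves in closed form for the
    maximum per-test price of a novel screening test (such as a cell-free DNA
    liquid biopsy) at a willingness-to-pay threshold. A scenario runner sweeps
    grids of test sensitivity and specificity on a shared cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
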
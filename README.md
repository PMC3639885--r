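# cardiolift

Unit-aware cardiovascular risk classification with personalized
guideline models.

## The problem

Clinical research cohorts are usually classified into risk categories
("at risk" / "not at risk" for blood pressure, lipids, BMI; low /
moderate / high overall risk) by an expert reading the chart. That
process is neither transparent nor reproducible: the guideline edition,
the unit system, and the clinician's private departures from the
published cutoffs are rarely recorded with the label. `cardiolift` is a
toolkit for doing the classification mechanically and auditably:

* **Typed records with convertible units.** Every measurement is a
  value bound to a unit from a compositional registry (base units,
  prefixed derivations such as `kilogram` = 1000 × `gram`, and complex
  derivations such as `kilogram-per-meter-squared`). Conversions compose
  the registered factors; mass and molar concentrations are bridged per
  analyte (mg/dl ÷ 38.67 → mmol/L for cholesterol species, ÷ 88.57 for
  triglycerides, ÷ 18.016 for glucose; 1 mmHg = 0.133322 kPa).
* **Derivations ("semantic lifting").** Missing derived attributes are
  computed from core measurements before classification:
  BMI = mass/height² (kg/m²); LDL by the Friedewald equation
  LDL = C − HDL − k·TG with the unit-dependent constant (k = 0.20 in
  mg/dl, 0.45 in mmol/l) selected automatically from the record's units;
  and the men's Framingham general-CVD point score with its 10-year risk
  lookup and ternary quantization (≤9 low, 10–19 medium, ≥20 high).
* **Declarative guideline models.** Each guideline is data: ordered
  value bands with inclusivity flags and an at-risk mapping.
  `builtin_models("aha")` carries the official binary cutoffs
  (SBP ≥ 140 mmHg, DBP ≥ 90, cholesterol ≥ 5.0 mmol/L, HDL ≤ 1.03,
  TG ≥ 2.26, BMI ≥ 25, LDL ≥ 160 mg/dl) plus the multi-band tables as
  printed — including their holes, which `validate_model()` enumerates
  (the cholesterol guideline has a genuine gap between 5.0 and
  5.2 mmol/L). `builtin_models("modified")` carries a
  clinician-personalized variant (cholesterol 5.2, HDL 0.89, TG 2.63,
  BMI 26). Model sets serialize to JSON so personalized rule sets can be
  published and swapped.
* **Evaluation and threshold recovery.** `concordance()` scores
  automated flags against expert labels (TP rate = % of expert at-risk
  records auto-flagged; FP rate = % of expert not-at-risk records
  auto-flagged), and `recover_threshold()` reconstructs a clinician's
  personal cutoff from labeled measurements, choosing the
  inclusive-at-risk boundary maximizing concordance.
* **Synthetic cohorts.** `simulate_cohort()` draws physiologic cohorts
  (truncated-normal measurements on realistic grids) and labels them
  with a configurable rule-following expert who can deviate from the
  rules at a chosen rate — so the whole pipeline is testable end to end
  without any patient data.

## Worked example

Classify the legacy spreadsheet's first row (SBP 128 / DBP 80.1 mmHg,
total cholesterol 227, HDL 55, TG 84 mg/dl, age 77, male, 1.8288 m,
78.1818 kg) under the personalized model set:

```r
library(cardiolift)
csv <- c("SBP,DBP,TOTALCHOL,HDL,TG,AGE,GENDER,HEIGHT,WEIGHT",
         "128,80.1,227,55,84,77,M,1.8288,78.1818")
rec <- read_legacy_table(csv)[[1]]
mod <- builtin_models("modified")
out <- lift(rec, binary_model_keys(mod), models = mod)
sapply(out$results, `[[`, "at_risk")
#>  sbp  dbp chol  hdl   tg  bmi  ldl
#>    0    0    1    0    0    0    0
out$provenance
#> [1] "derived BodyMassIndex"
#> [2] "derived SerumLDLCholesterolConcentration"
get_quantity(out$record, "SerumLDLCholesterolConcentration")
#> 155.2 milligram-per-deciliter
get_quantity(out$record, "BodyMassIndex")
#> 23.37616 kilogram-per-meter-squared
```

Only the cholesterol flag is raised: 227 mg/dl converts to 5.87 mmol/L,
at or above the personalized 5.2 cutoff; the derived LDL of 155.2 mg/dl
(227 − 55 − 0.20·84) sits below the 160 mg/dl bound, and the derived
BMI of 23.4 kg/m² is below 26. This reproduces the row's recorded
expert flag vector exactly.

Recovering a personal cutoff from labels:

```r
fit <- recover_threshold(c(0.85, 0.88, 0.89, 0.90, 1.00),
                         c(1, 1, 1, 0, 0), "at_risk_if_le")
fit$boundary
#> [1] 0.89
```

A command-line front end covers the same workflow
(`simulate`, `classify`, `derive`, `evaluate`, `recover`,
`validate-model`, `convert`); see `inst/cli/cardiolift` and
`?cardio_cli`.

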
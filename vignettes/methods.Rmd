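---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiolift)
```

This vignette is the package's own account of the science it
implements: the measurement model, the derivation algorithms, the
guideline representation, the evaluation statistics, and the choices we
made where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

A clinical observation is a `quantity`: a finite number bound to a unit
from a compositional registry. Units come in three kinds, mirroring how
unit ontologies compose them:

* **base** units (gram, meter, liter, pascal, mole, year) carry a
  physical quality and derive from nothing. Gram — not kilogram — is
  the base mass unit; kilogram is the 1000× prefixed derivation, so
  prefix arithmetic stays uniform.
* **simple derived** units scale exactly one base unit by a prefix
  factor and an integer dimensional size: millimeter = (meter, 0.001,
  1); meter-squared = (meter, 1, 2); millimeter-of-mercury-column =
  (pascal, 133.322, 1).
* **complex derived** units multiply two or more components:
  kilogram-per-meter-squared = kilogram¹ · meter⁻²;
  milligram-per-deciliter = milligram¹ · deciliter⁻¹.

Conversion between units of the same dimension signature is the ratio
of their composed scales, so a conversion chain through an intermediate
unit equals the direct conversion to machine precision, and round trips
are exact to better than 1e-9 relative error (a tested property).

**Analyte bridges.** Laboratories report lipid panels in either mg/dl
(mass concentration) or mmol/L (molar concentration); converting
between them requires the analyte's molar mass. The guideline tables we
reproduce print both columns, which pins the divisors: mg/dl ÷ 38.67 →
mmol/L for cholesterol species (molar mass ≈ 386.7 g/mol), ÷ 88.57 for
triglycerides, ÷ 18.016 for glucose. These are the only values that
reproduce every printed dual-unit band edge we test (pressure
12.0/15.9/…/21.3 kPa; cholesterol 5.2/6.2; HDL 1.03/1.55; TG
1.69/2.26/5.65; LDL 3.3/4.1). Two printed edges are *not* reproducible
and are asserted as known inconsistencies rather than silently
absorbed: the cholesterol table's "<200 mg/dl ↔ <5 mmol/L" pairing
(200/38.67 = 5.17, which rounds to 5.2, leaving a real 5.0–5.2 hole)
and the LDL table's 130 ↔ 3.3 edge (130/38.67 rounds to 3.4).

## Records

A `patient_record` is one encounter: at most one attribute per
measurement class, optional expert binary flags per attribute, an
optional ternary overall label (1/2/3), and optional
smoking/diabetes/treatment status. Ten classes are *grounding* (tied
directly to data); three are *derived* (LDL, BMI, Framingham score).
Sex is categorical, not a quantity; age carries the unit `year`.
Longitudinal structure is deliberately out of scope — each row is an
independent record.

Readers/writers cover the legacy spreadsheet dialect (comma or tab,
`*_GR` flag columns, `RISK GR` ternary; missing cells parse to absent
attributes, malformed cells to row-indexed errors) and a narrow Turtle
RDF profile (record → attribute → measurement nodes with unit and value
properties, one triple per line). The Turtle writer's output re-parses
losslessly — the tested contract — but the parser is scoped to that
profile; it is not a general Turtle implementation, since no RDF
library is available in the dependency budget.

## Derivations

**BMI** = mass\[kg\] / height\[m\]², emitted in kg/m². Exact under unit
conversion of its inputs.

**Friedewald LDL** = C − HDL − k·TG, computed in the unit system of the
stored cholesterol attribute with the unit-dependent constant chosen
automatically: k = 0.20 in mg/dl, 0.45 in mmol/l. Because 0.45 is a
rounded clinical constant (exact cross-system consistency would require
0.20 × 88.57/38.67 ≈ 0.458), LDL computed in mmol/L agrees with the
converted mg/dl result only to about 2e-3 relative — an inherent
property of the published constants, which we keep as printed. The
derivation refuses negative results (implausible panels). A standard
validity guard (TG > 400 mg/dl) is available but off by default, since
the source method did not apply it.

**Framingham (men's general CVD).** Point lookup per factor — age bands
30–34 → 0 through 75+ → 15; HDL 60+ → −2 down to <35 → +2; total
cholesterol <160 → 0 up to 280+ → +4; SBP by treatment status
(untreated <120 → −2 … 160+ → +3; treated <120 → 0 … 160+ → +5); smoker
+4; diabetic +3 — then a total-points table giving 10-year risk
(open-ended rows "<1%" and "≥30%" are returned as bounds, not point
values) and the ternary quantization ≤9 low / 10–19 medium / ≥20 high.
Three decisions here were forced:

* The printed smoker/diabetic cells are garbled in our source; we use
  +4/+3, the values of the published 2008 men's general-CVD table.
* Fractional inputs: printed bands are closed integer ranges
  ("45–49"). We use half-open intervals \[printed low, next printed
  low), which agrees with every printed endpoint and leaves no
  fractional value uncovered. Inputs are therefore *not* rounded before
  lookup.
* Records lacking smoking or diabetes status are not scored (the
  status is never assumed absent-negative), and `bp_treated` defaults
  to FALSE — the legacy data carried no treatment column, which its
  own authors noted as a limitation. Only the men's table is printed,
  so female records are rejected rather than approximated.

## Guideline models and lifting

A `risk_model` is data: a measurement class, a canonical unit, an
analyte tag, and ordered bands, each `[lower, upper]` with explicit
inclusivity, a label, and an at-risk bit. The boundary convention
throughout is *at-risk side inclusive* (≥ threshold; ≤ for HDL), low
side strict, which is how the personalized cutoffs were published
(≥ 5.2, ≤ 0.89, ≥ 2.63, ≥ 26). DBP's binary threshold is 90 mmHg —
no explicit block was printed for it, but the staging table's Stage 1
starts at 90 and the reported concordance is consistent with it.

Classification converts the stored value to the model's canonical unit
(the stored attribute is never mutated), matches a band, and reports
one of three outcomes: `classified`, `gap` (the value fell into a hole
of the printed guideline — never silently defaulted), or
`insufficient_data`. `validate_model()` enumerates every uncovered
interval and overlapping pair, and finds the cholesterol 5.0–5.2 gap as
well as the decimal-grid holes of the printed BMI/LDL/HDL tables
((24.9, 25), (59, 60) mg/dl, etc.). The multi-band tables' at-risk bits
are aligned with the corresponding binary cutoffs (cholesterol
borderline band at-risk, TG borderline band not), since the printed
shading is not recoverable from our source text.

`lift()` resolves the derivation dependency graph (BMI ← height, mass;
LDL ← lipid panel; Framingham ← age, lipids, SBP, status), derives each
missing derivable attribute exactly once, classifies every requested
target, and records provenance strings for each derivation and unit
conversion. Already-derived attributes are never re-derived, so lifting
is idempotent — a tested invariant.

The joint blood-pressure staging applies the five-category table with
the isolated-systolic rule (SBP ≥ 140 and DBP < 90) taking precedence,
otherwise the more severe of the two single-pressure stages; Normal and
Pre-hypertension map to not-at-risk. Values below the table floor
(SBP < 90 or DBP < 60) return an explicit `below-range` outcome; how
the original expert handled such values is unknowable, so we refuse to
guess.

## Concordance and threshold recovery

Concordance uses the asymmetric row-wise definition: TP rate = share of
expert *at-risk* records the model also flags; FP rate = share of
expert *not-at-risk* records the model flags. Rates are computed over
records with both an expert flag and a classifiable value; an empty
denominator yields NA, never 0.

`recover_threshold()` automates the manual model-personalization step:
given labeled values and a direction, it scans the observed values as
candidate inclusive-at-risk boundaries and returns the concordance
maximizer, ties broken toward the smaller at-risk set. On separable
data this is the extreme observed value on the at-risk side of the gap
(the published personalized models place their thresholds exactly at
such inclusive bounds, e.g. HDL ≤ 0.89 and BMI ≥ 26) — not the gap
midpoint, a deliberate convention. The scan is verified against a
brute-force oracle over observed values *and* midpoints; restricting
candidates to observed values loses nothing because an inclusive-≥ rule
classifies identically for any boundary in a half-open inter-value
interval.

## The synthetic cohort: what it emulates, what it does not

No patient data ships with the package; the original cohort (636
patients, 1723 encounters) was never deposited. `simulate_cohort()`
generates its *structure*: nine core measurements, sex, status flags,
and expert labels. Defaults are fixed once as a plausible
post-intervention cardiology cohort and are not tuned to any test
outcome:

| quantity | distribution | range | grid |
|---|---|---|---|
| SBP | N(130, 20) mmHg | [90, 220] | 1 |
| DBP | N(80, 12) mmHg | [50, 120] | 0.1 |
| total cholesterol | N(210, 40) mg/dl | [100, 400] | 1 |
| HDL | N(48, 12) mg/dl | [20, 100] | 1 |
| TG | N(140, 60) mg/dl | [40, 400] | 1 |
| glucose | N(105, 25) mg/dl | [60, 300] | 1 |
| height | N(1.72, 0.10) m | [1.4, 2.1] | 1e-4 |
| weight | N(80, 15) kg | [40, 160] | 1e-4 |
| age | uniform integer | [30, 85] | 1 |

Male fraction 0.7; smoker probability 0.3, diabetic 0.15, treated 0
(all config-overridable). Truncated normals are drawn by inverse CDF
(one uniform per value) and snapped to the legacy data's apparent
precision grid, so recovered thresholds land on-grid exactly. The
simulated expert labels each record by lifting it through a chosen
model set, flipping each binary flag independently with a configurable
deviation rate; the ternary label follows the deviation-free Framingham
category unless a separate ternary deviation rate is set.

What a green test therefore establishes: the pipeline is closed — a
deviation-free cohort labeled by the modified models scores TP 100% /
FP 0% against those models, deviations are recovered at their injected
rate (within 3 binomial standard errors at n = 2000), and an expert
whose only departure is a shifted cutoff is exactly recoverable. What
it does not establish: agreement with any real clinician's behavior,
realistic covariance between lipids, or longitudinal structure — the
generator draws attributes independently, which real panels are not.
The historical concordance table (e.g. cholesterol TP 92.6%, HDL FP
56.5%) depends on the undeposited data and is *not* reproduced here;
only its qualitative set-inclusion signature (original HDL cutoff 1.03
vs personal 0.89 ⇒ TP 100%, FP > 0) is asserted.

## Numerical conventions

* All computation at full double precision; rounding only for display
  and for printed-edge comparisons at the table's printed precision.
* Band membership uses exact comparisons on converted values; the
  0.1-step scans in tests and the acceptance script are generated as
  integer sequences divided by 10 to avoid accumulated floating error.
* Degenerate inputs fail loudly: non-finite quantities, negative
  derived LDL, age below the scored bands, all-one-label threshold
  recovery, zero concordance denominators (NA, not 0).
* RNG: cohort simulation seeds a local stream and restores the
  caller's; the acceptance script derives all randomness from `--seed`.

## Known limitations

Only the men's Framingham general-CVD table is implemented (the women's
table and disease-specific variants were not part of the source
material). Drug-treatment effects on risk scoring are not modeled. The
Turtle reader accepts the package's own output profile, not arbitrary
RDF. Temperature-style offset conversions and uncertainty propagation
are out of scope for the unit registry.
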
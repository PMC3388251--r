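---
title: "Modelling tiered neonatal CF screening: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tiered neonatal CF screening: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfscreen)
```

## The screening problem

Cystic fibrosis (CF) is an autosomal recessive disease of the CFTR gene.
Newborn screening for it works through a cascade of cheap, imperfect tiers
applied to the heel-prick blood spot: immunoreactive trypsinogen (IRT, in
µg/l) as a broad first filter, pancreatitis-associated protein (PAP, µg/l)
as a second biochemical filter, then a targeted CFTR mutation panel, and
finally extended gene analysis (EGA — sequencing of all CFTR coding exons
and intron/exon boundaries). The design problem is the trade-off between
specificity (healthy infants referred for sweat testing), sensitivity
(missed patients, disproportionately those with rare mutations absent from
the panel), and the volume of unsolicited secondary findings (carriers,
mild phenotypes).

`cfscreen` makes that cascade executable. The national four-step protocol
implemented by `protocol_config()`/`screen_cohort()` is:

1. IRT < 60 µg/l → negative;
2. PAP < 3.0 µg/l (when 60 ≤ IRT < 100) or PAP < 1.6 µg/l (when IRT ≥ 100)
   → negative. The IRT band is half-open: IRT exactly 100 takes the
   high-IRT branch, because the "IRT ≥ 100" clause claims the boundary.
   Positivity thresholds are everywhere inclusive (≥), negativity strict;
3. mutation panel: two panel mutations → immediate referral (sequencing
   adds nothing actionable to a two-mutation result); one → EGA; none →
   negative, unless the **failsafe** fires: IRT ≥ 100 µg/l *and* PAP ≥ 1.6
   µg/l sends even panel-negative samples to sequencing, which is what
   rescues rare-mutation (often migrant-ancestry) cases;
4. EGA: two disease alleles → referral; one → a reportable carrier finding
   (suppressed when `carrier_reporting = FALSE`, modelling parental
   opt-out); none → negative after sequencing.

The two pilot-era strategies (IRT/PAP with a two-band PAP rule; IRT
followed directly by panel + EGA) and their calculated combination
(IRT/PAP-positives pushed through the DNA tiers) are available through
`pilot_config()`. Pilot PAP thresholds are defined on the pre-2011 assay
scale; the kit's calibrators assumed a 5 µl punch volume where the true
volume is 3 µl, so pilot-era concentrations must be multiplied by exactly
5/3 (`recalibrate_pap()`). Generated cohorts carry corrected-scale PAP, and
`pilot_config(cohort_on_corrected_scale = TRUE)` (the default) rescales the
pilot thresholds accordingly.

## Synthetic cohort

`generate_cohort()` draws, per newborn: an ancestry stratum (multinomial on
birth fractions), a CFTR genotype under Hardy-Weinberg — each allele
independently mutant with probability q = carrier frequency / 2 — a
phenotype class, a meconium-ileus flag, and biomarkers. Panel
detectability is an *allele-level* property: each disease allele is
independently one of the panel mutations with the stratum's detectability,
so patient-level panel sensitivity emerges from the genotype (matching how
a fixed mutation panel actually behaves). Default strata:

| stratum | births | carrier freq. | panel detectability |
|---|---|---|---|
| general population | 0.90 | 1:30 | 0.95 (assumption) |
| Turkish ancestry | 0.05 | 1:50 | 0.44 |
| North-African ancestry | 0.05 | 1:50 | 0.69 |

The 1:30 general carrier frequency and the 0.44/0.69 migrant panel
sensitivities are the published programme figures; the roughly 1:50 migrant
carrier frequency is applied to both migrant strata (the published estimate
does not separate them). The 0.95 general-population detectability and the
5%/5% birth shares are package assumptions, configurable in
`default_config.yaml`.

Two-disease-allele genotypes present as non-classical (milder) CF with
probability 0.28 — no genotype-level rule is published, and this value
keeps the pilot-style mix of classical and non-classical detections
plausible. CF newborns carry a meconium-ileus flag with probability 4/29
(about four such infants per 25 screen-detected patients a year); they stay
in the cohort but are excluded from sensitivity denominators, since they
are diagnosed clinically before screening results matter.

Determinism: one root seed governs the whole cohort, drawn column-by-column
in a fixed order, so an identical configuration reproduces a bit-identical
table. The pipeline derives per-stage seeds from the root seed by labelled
hashing, so adding a stage never shifts another stage's stream.

`generate_cf_cohort()` is the importance-sampling companion: it draws
newborns *conditional* on a CF genotype (stratum proportional to births ×
prevalence, both alleles mutant) so that sensitivity — a CF-conditional
quantity for which the importance weights cancel — can be estimated from a
few thousand rows instead of the roughly 7 million births a 2,000-case
natural sample would need.

## Biomarker model and its calibration

All class/marker concentration distributions are log-normal: positive
support, right skew typical of analyte concentrations, and closed-form
quantile calibration. IRT and PAP are conditionally independent given the
phenotype class by default; a log-scale correlation is exposed
(`rho`) because step-2 performance depends on it and no joint distribution
is published.

The **unaffected IRT** distribution is the only one anchored to published
population data. Two
published population quantiles — 2.43% of newborns at or above 50 µg/l,
1.03% at or above 60 µg/l — give two linear equations
log tᵢ = µ + zᵢσ with zᵢ = Φ⁻¹(1 − pᵢ), solved exactly by
`calibrate_unaffected_irt()`:

```{r calibration}
calibrate_unaffected_irt(tail_constraint(50, 0.0243),
                         tail_constraint(60, 0.0103))
```

(µ = 2.8642, σ = 0.5313, median ≈ 17.5 µg/l; both tails are reproduced to
below 1e−12, and a 10⁶-draw sample recovers them within binomial error.)
The two quantiles are treated as quantiles of the *unaffected* population;
at a birth prevalence of ~1/3600 the distinction from "all newborns" is
far below the printed precision. Constraints with a non-decreasing tail are
rejected as inconsistent.

The remaining class parameters cannot be anchored to published population
quantiles; they are model assumptions, chosen **analytically, once**, so
that the four-step protocol reproduces the programme's aggregate claims
(specificity > 99.99%, sensitivity ≈ 95%) — that aggregate agreement, not
any individual class parameter, is what the package treats as checkable:

* classical CF: IRT median 130 µg/l (σ = 0.40), PAP median 10 µg/l
  (σ = 0.60). Closed form: P(pass steps 1–2) = P(IRT ≥ 100)·P(PAP ≥ 1.6) +
  P(60 ≤ IRT < 100)·P(PAP ≥ 3.0) ≈ 0.967;
* non-classical CF: IRT median 115 µg/l (σ = 0.45), PAP median 8 µg/l
  (σ = 0.60), pass ≈ 0.908 — milder, but still concentrated among
  screen-detectable cases, which is what an *aggregate* sensitivity near
  95% forces once 28% of genotypes are non-classical;
* carriers: IRT median +15% over unaffected at the same σ (carriers run
  mildly elevated IRT), PAP identical to unaffected;
* unaffected PAP: median 0.4 µg/l, σ = 0.55 (corrected scale).

Mixing these pass rates over strata and panel detectabilities (the failsafe
recovering the high-IRT/high-PAP share of panel-negative cases) gives an
expected four-step sensitivity of ≈ 0.948, which the simulations reproduce.

## Test properties and their conventions

`summarize_screening()` counts a referral (`CF_REFERRAL`) as the terminal
positive event — sweat testing and diagnosis downstream are out of scope. A
carrier report is tallied on its own row and is *never* a false positive.
Disease-positive defaults to any CF (classical + non-classical) and can be
switched to classical-only; published aggregate figures do not state which
definition they use, so both are computed. Undefined ratios (no CF cases in
the cohort, say) are `NA` with an explicit definedness flag, never 0 or 1.

Because referral under the national protocol requires two detected
mutations, and only true CF genotypes carry two disease alleles, false
positive referrals are structurally impossible under perfect sequencing
(`ega_sensitivity = 1`): the simulated specificity is exactly 100%,
comfortably above the > 99.99% claim. This is a faithful property of the
modelled decision tree, not an accident of parameters — the protocol's
design moves the specificity burden onto the DNA tiers.

## The carrier-risk calculus

When screening reports a carrier child, one parent is an obligate carrier.
The programme's counselling arithmetic, implemented on exact rationals
(`rational()`), is: allele frequency q = carrier frequency / 2
(1/30 → 1/60); birth prevalence q² (1/3600); recurrence risk after a
carrier child = q/4 (1/240 — fifteen times the prevalence). The q/4
convention prices the partner's single unknown allele at q with a 1/4
transmission-and-affection factor. A stricter conditional derivation
(partner carrier with probability ≈ 2q, then 1/4) gives q/2 — exactly twice
the figure; both are exported
(`risk_given_carrier_child_conditional()`) and never silently swapped.

A negative parental test updates the partner's carrier probability by the
standard Bayes formula p(1−s)/(p(1−s)+1−p); the residual next-pregnancy
risk re-applies the q/4 convention at the updated carrier probability, so
with no test the report returns exactly 1/240 and with perfect sequencing
exactly 0:

```{r risk}
full_risk_report(rational(1, 30))
full_risk_report(1 / 30, "PANEL_NEGATIVE", test_sensitivity = 0.95)
```

## Numerical and degenerate-input choices

Thresholds are compared with inclusive ≥ for positivity exactly as printed;
ties at 100 µg/l IRT or 1.6/3.0 µg/l PAP are covered by an enumerated
truth-table test. σ = 0 biomarker classes are point masses; sampling never
produces non-positive or non-finite concentrations for valid parameters.
Cohort TSVs serialize concentrations with 12 significant digits so
round-trips are lossless well past 9 significant digits. Rational
arithmetic promotes integer-valued scalars (the 2s and 4s of the risk
formulas) and degrades to floating point as soon as a genuine float enters.
The degenerate Bayes case prior = 1, s = 1 returns 0 by the limit
convention.

## Problem sizes

The shipped configuration simulates 200,000 newborns for the specificity
estimate (≈ 55 expected CF genotypes, ≈ 6,700 carriers), 10⁶ draws for the
calibrated-tail checks, 2,500 conditional CF genotypes for the sensitivity
estimate (binomial SE ≈ 0.45 pp), and a 72,874-newborn cohort for the
pilot-scale strategy comparison. These sizes put Monte-Carlo error well
inside every tolerance used while the whole suite runs in seconds; all are
configurable upward.

## What the simulations do and do not show

The generator emulates the *structure* the screening analysis assumes:
Hardy-Weinberg genotypes under stratified allele frequencies, allele-level
panel coverage, and class-conditional log-normal biomarkers with tails
pinned to the published population quantiles. Passing tests therefore show
that the decision logic, the calibration algebra and the evaluation
conventions are implemented correctly — not that real newborn biomarkers
are log-normal, nor that the assumed CF-class parameters match clinical
assay distributions.

Known, deliberate limitations:

* no IRT–PAP correlation among sick-but-not-CF infants, so the IRT/PAP
  pilot strategy shows far fewer false referrals here than the ~119/72,874
  observed in the field; strategy comparisons are meaningful as *orderings*
  (combined ⊆ IRT/PAP referrals; PAP filtering only removes carrier and
  mild-form detections), which hold structurally, not as absolute referral
  counts;
* carrier PAP equals unaffected PAP, so national-protocol carrier reports
  are rarer than the programme's expected dozen per year;
* no assay measurement-error model separate from biological variation, no
  age-at-sampling effects, no second heel-prick recall, no real mutation
  nomenclature, no consanguinity or haplotype structure;
* EGA is perfectly sensitive by default (`ega_sensitivity` is the hook for
  relaxing this).
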
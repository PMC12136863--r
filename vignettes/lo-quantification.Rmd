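---
title: "Quantifying lateralized overgrowth from regional DXA composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lateralized overgrowth from regional DXA composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lodxa)
```

## The measurement model

Lateralized overgrowth (LO) is the excessive growth of one body region
relative to its contralateral homologue. Because reference values for
individual body parts do not exist and body composition changes throughout
childhood, the analysis implemented here is entirely *self-controlled*:
every quantity is a within-patient comparison of a region against its
mirror-image counterpart, which removes inter-individual variability by
construction.

A total-body DXA scan is partitioned into 8 paired regions (16
region-sides): hemihead, arm, forearm, hand, hemipelvis, thigh, leg, foot.
Hemithorax and hemiabdomen are excluded at the type level — the lateral
placement of internal organs makes their two sides incomparable, so the
region vocabulary simply cannot express them. Each region-side carries a
three-compartment mass triple in grams: adipose ($m_A$, DXA fat), muscle
($m_M$, DXA lean) and bone ($m_B$, bone mineral content), with total mass
$m_t = m_A + m_M + m_B$ always derived and never stored.

Three statistics drive everything else:

* **Discrepancy ratio.** For a (candidate) affected region and its
  contralateral homologue,
  $r = (m_t^{\mathrm{aff}} - m_t^{\mathrm{contra}}) / m_t^{\mathrm{contra}}$.
  The ratio is signed: $r < 0$ means the candidate side is lighter. LO is
  called when $r \ge$ the cut-off (default 10%).
* **Relative composition (RC).** Per tissue,
  $RC_X = m_X / m_t$, a dimensionless fraction; the three RCs sum to 1 and
  are invariant under rescaling all masses, so they isolate *what* a region
  is made of from *how big* it is.
* **Composition discrepancy ($\Delta RC$).** Per tissue,
  $\Delta RC_X = RC_X^{\mathrm{aff}} - RC_X^{\mathrm{contra}}$, reported in
  percentage points; the three components sum to 0. When LO spans several
  regions, masses are summed componentwise over the affected set and over
  the mirrored set *before* computing RC and $\Delta RC$ — ratios are never
  averaged. The tissue attaining the maximal $\Delta RC$ of the affected
  aggregate is reported as the predominant overgrown tissue.

```{r worked}
m <- expand.grid(side = c("left", "right"), region = c("thigh", "leg"),
                 stringsAsFactors = FALSE)
m$fat_mass_g  <- c(2800, 2000, 1000, 760)
m$lean_mass_g <- c(5100, 4600, 2500, 2300)
m$bmc_g       <- c(300, 300, 150, 150)
scan <- patient_scan("example", m, diagnosis = "PROS",
                     clinical_affected = data.frame(region = c("thigh", "leg"),
                                                    side = "left"))
score_patient(scan)
```

## Tunable parameters

* `lo_threshold` (fraction, default 0.10): the mass-discrepancy cut-off.
  The boundary is *inclusive* — a region at exactly 10% is called — so
  borderline cases surface for review rather than silently passing. The
  clinical girth/length cut-off and this DXA mass cut-off are conceptually
  distinct quantities even though both default to 10%; they are therefore
  independent configuration values.
* `near_threshold_band` (fraction, default 0.05): clinically labeled
  groups whose ratio lands in `[lo_threshold - band, lo_threshold)` are
  flagged near-threshold in the concordance report instead of being lumped
  with clear negatives.
* `tie_order` (default adipose > muscle > bone): exact ties in the
  predominant-tissue argmax are broken by this fixed priority. Ties have
  measure zero for continuous data; the rule exists so the classifier is a
  total, deterministic function.

Internal computation always runs at full precision; the 1-decimal
percentage formatting in reports and CSV display columns is applied at
serialization only and never feeds back into calls or classification.

## Concordance with clinical evaluation

Clinical examination labels region-sides as affected; DXA provides
mass-based calls. Concordance is evaluated at *region-group* granularity —
upper limb (arm, forearm, hand), lower limb (thigh, leg, foot), hemihead,
hemipelvis — because clinical findings for limbs are reported at limb
level; per-region granularity is available behind the `granularity`
argument. A patient is concordant when every clinically labeled group is
DXA-called on the same side. DXA calls on unlabeled groups are reported
(`dxa_only`) but do not break concordance: they are the "clinically
overlooked" findings the method is designed to surface. A call on the
*opposite* side is discordant and separately flagged. Patients with no
clinical labels are excluded from the rate's denominator and listed,
since a concordance rate is undefined for them.

## The synthetic cohort generator

No public patient-level data exist for this design, so the package ships a
generator that emulates the statistical structure the analysis assumes,
and the generator's defaults are the package's operative description of the
three diagnostic subgroups:

* Subgroup mix 28:11:7 (PROS : BWSp : ILO, i.e. 61/24/15%) for a
  46-patient cohort.
* Per subgroup, the contralateral RC means/SDs and the $\Delta RC$
  means/SDs of adipose and bone (PROS: contralateral RC 29.2 ± 10.0 /
  67.4 ± 10.2 / 3.1 ± 1.3%, $\Delta RC$ +2.0 ± 3.8 / −1.5 ± 3.6 /
  −0.3 ± 0.4 pp; BWSp: muscle-shifted with $\Delta RC_M$ +0.8 pp; ILO:
  adipose-rich contralateral composition 38.4% with $\Delta RC_A$
  −2.3 pp).
* Overgrowth ratio on masked regions: truncated normal, mean 0.25, SD
  0.10, floor 0.10 — every truly overgrown region clears the LO cut-off
  before noise, which is what makes the ≥ 99% re-detection property a
  meaningful pipeline check rather than a tautology about noise.
* Physiological asymmetry on unaffected regions: multiplicative mass noise
  with SD 0.02, plus a small compositional jitter (SD 0.005) so the two
  sides of an unaffected region are similar but not identical.
* Clinical labeling sensitivity 1.0 by default (labels equal the true
  mask); lowering it produces clinically overlooked regions for testing
  the `dxa_only` pathway.

### Sampling design

RC vectors live on the 3-simplex. Rather than a Dirichlet — whose
parameters would have to be back-fitted — adipose and bone fractions are
drawn from truncated normals at the configured means/SDs and muscle is
closed out as $1 - RC_A - RC_B$, with rejection of invalid draws. This
maps the published subgroup means and SDs *directly* onto generator
parameters. The same closure enforces the zero-sum constraint on
$\Delta RC$: adipose and bone deltas are drawn and muscle is set to
$-(\Delta RC_A + \Delta RC_B)$. A deliberate consequence: the implied mean
$\Delta RC_M$ for the adipose-predominant subgroup is
$-(2.0 - 0.3) = -1.7$ pp, not the printed $-1.5$ pp — the printed row does
not sum to zero because it rounds per-patient means. The implied value is
documented here and used knowingly; recovery checks allow for it.

Masks are drawn from a weighted catalog built from complete region groups
(lower limb 0.35, upper limb 0.20, hemihead 0.15, ipsilateral upper+lower
limb 0.10, hemibody 0.10, hemipelvis+lower limb 0.10) with a uniformly
random side — weights chosen to reflect that limb-level LO is the common
presentation and whole-hemibody involvement the rarer syndromic extreme.
Base region masses (thigh 7000 g down to hand 400 g) are an adult-scale
phantom; by scale invariance of RC they influence only absolute masses,
never composition statistics. Ages and sexes are generated for realism
from the subgroups' summary distributions but drive nothing, matching the
self-controlled design. Because masked region-sides carry the patient's
affected RC exactly and their mirrors the contralateral RC exactly, the
scored affected-aggregate RC recovers the drawn vectors — the pipeline,
not the generator, is what the recovery tests exercise end to end.

Reproducibility: one master seed per cohort draws per-patient subseeds, so
the same seed and configuration reproduce the cohort bit-for-bit, byte-identical
on disk.

### What the generator does not emulate

Within-patient correlation between the mass overgrowth ratio and the
$\Delta RC$ magnitude (none is published; they are generated
independently); age- or sex-dependence of composition; measurement error
of the DXA device itself; longitudinal growth. Passing tests therefore
demonstrate that the pipeline correctly recovers the structure it assumes,
not that real cohorts satisfy those assumptions.

## Statistical battery

Within-patient affected-vs-contralateral comparisons use the paired
Student t test; between-subgroup $\Delta RC$ comparisons use one-way
ANOVA plus all pairwise pooled-variance (classic Student) unpaired t tests
— pooled, because that is the form the reporting convention names; Welch's
correction is available behind a flag. No multiplicity adjustment is
applied by default (none was applied in the source analyses); a Holm
option exists. The prevalence of each predominant tissue across subgroups
is tested with Fisher's exact r×c test: exact (network) enumeration, with
a fixed-seed Monte-Carlo fallback that reports its standard error when
enumeration exhausts its workspace. The Shapiro–Wilk statistic is computed
as an *annotation only*: it flags non-normality on parametric output but
never switches methods silently, because silent switching would make
results depend on an unreported gate.

Degenerate inputs (zero-variance differences, constant groups) raise
classified errors rather than returning NaN; the cohort summary converts
them into per-cell notes so one degenerate subgroup cannot abort a
cohort report.

## Numerical and scale choices

Simulation-based checks in the test suite use sizes chosen to keep each
property statistically sharp: parameter recovery runs 5000-patient
single-subgroup cohorts (standard error of a mean RC ≈ 0.14 pp, well
inside the 0.3 pp recovery band); the paired t test's type-I calibration
uses 2000 replicates of 10 symmetric patients (binomial SE ≈ 0.005 around
0.05); invariants run on 10 000 random draws. The rejection samplers abort
after 1000 consecutive failures with an "infeasible parameters" error so a
misconfigured generator fails fast instead of hanging.

## Known limitations

* The region vocabulary is fixed; sub-region custom drawing is out of
  scope — the package starts from an already-extracted regional table.
* Concordance semantics for a patient labeled on one side but DXA-called
  on the other are a design choice (discordant, separately flagged); the
  source material never encounters the case.
* The headline clinical figures of the motivating study (91% concordance
  and the subgroup p values) derive from a 46-patient cohort that is not
  publicly available; the package reproduces the *procedure*, and its
  tests validate it on synthetic cohorts with known ground truth.
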
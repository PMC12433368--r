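---
title: "Globin-chain ratio screening: models, cutoffs and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Globin-chain ratio screening: models, cutoffs and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoscreen)
library(dplyr)
```

## The screening problem

Thalassemias and structural hemoglobin (Hb) variants are the most common
monogenic disorders worldwide. In a newborn, the clinically useful signal is
not any single protein level but the *balance* between globin chains:
α-gene deletions depress α-chain output and prolong expression of the
embryonic ζ chain; β-thalassemia mutations depress β-chain output, which
raises the relative abundance of the δ chain (the HbA2 component); a
structural variant such as Hb S replaces part of the wild-type β chain with
a mutant one. A targeted mass-spectrometry assay measures one
proteo-specific tryptic peptide per chain (αT1, αT3, βT1, βT2, γT10, δT2,
ζT8, plus one mutant peptide per monitored variant), each against a
stable-isotope-labeled internal standard (IS), and this package turns those
integrated peak areas into screening calls.

## From peak areas to ratios

Quantification is single-point isotope dilution. For a peptide with analyte
area $A$, IS area $A_{IS}$ and spiked IS concentration $C_{IS}$ (mg/L),

$$C = \frac{A \, C_{IS}}{A_{IS}},$$

and a chain ratio is the quotient of two such concentrations, expanded so it
is computed directly from the four areas and two IS concentrations. The six
named ratios the pipeline emits are `aT1_bT1`, `zT8_bT2`, `aT3_bT1`,
`dT2_bT2`, `gT10_aT3` and `gT10_bT1`; all are dimensionless and invariant
under any common rescaling of a sample's areas. The mutant-to-wild-type
variant ratio $G_M/\beta$ is computed from IS-normalized areas *without* the
IS concentration terms — the mutant and wild-type peptides share a backbone,
and the ratio is used as a detection readout, so we keep the simpler form
exactly as the assay defines it rather than "correcting" the asymmetry with
the chain-ratio formula.

A peptide counts as detected when its signal-to-noise ratio is at least 10.
When a measurement carries no noise estimate, a configurable per-peptide
detection floor (default 0) stands in for the assay's lower limit of
quantitation, which this package does not re-estimate. Undetected numerators
contribute a ratio of 0; an undetected or zero-area β denominator makes the
sample **non-evaluable** — the pipeline never divides by an absent chain and
never drops a sample silently.

## Risk models and cutoffs

Two fixed-coefficient binary logistic models convert ratios to disease
probabilities:

$$P(\alpha) = \mathrm{logit}^{-1}\!\left(30.444\,\frac{\zeta T8}{\beta T2}
  - 1.030\,\frac{\alpha T1}{\beta T1} + 1.771\right), \qquad
P(\beta) = \mathrm{logit}^{-1}\!\left(105.132\,\frac{\delta T2}{\beta T2}
  + 0.388\,\frac{\alpha T3}{\beta T1} - 13.195\right).$$

The inverse logit is evaluated with a sign branch so a slope like 105.132
cannot overflow `exp()`. The screening rule calls α-thalassemia at
$P(\alpha) \ge 0.33$ and β-thalassemia at $P(\beta) \ge 0.13$ (both firing
yields the combined category); descriptive severity bands layer on the α
screen (≥ 0.66 α⁰-type, ≥ 0.87 --SEA-type, ≥ 0.88 HbH-type), with a sample
assigned the *highest* band whose threshold it meets. We treat the
per-genotype thresholds as descriptive rather than decisional because
genotype is unknown at screening time; the global pair drives the call. The
un-rounded ROC decision points (0.329 / 0.126) are available as
`default_cutoffs(preset = "roc")` since the rounded and un-rounded pairs
both appear in the assay's documentation and we do not guess which was used
prospectively. Variant flags fire independently of the thalassemia flags
("> 0" thresholds operationalized as "mutant peptide detected at S/N ≥ 10",
so electronic noise cannot trigger them; Hb G-Coushatta uses ≥ 2.19).

Refitting is done by iteratively reweighted least squares written in this
package: convergence when the largest parameter change is below 1e-8, at
most 100 iterations, a 1e-8 ridge on the weighted normal equations for
numerical stability. Complete or quasi-complete separation is reported via
`separation_flag` — detected when every fitted probability sits within 1e-5
of its label or a coefficient passes 1e4 — rather than raised as an error.
ROC curves use the "positive when score ≥ threshold" convention to match the
cutoff table; AUC is the trapezoidal area, which for these step curves
equals the tie-aware Mann–Whitney concordance; Youden ties break toward
higher sensitivity (screening penalizes false negatives), then the lower
threshold. Candidate biomarker selection orients each ratio so its AUC is at
least 0.5 and keeps those above 0.850.

## What the synthetic cohort emulates — and what it does not

No public cohort accompanies the assay, so `generate_cohort()` provides a
genotype-stratified stand-in. Per sample, each chain's abundance is a
healthy-newborn baseline times the genotype's chain multiplier times
multiplicative lognormal noise at a configurable CV; IS areas are drawn
independently (separately spiked standards); a heterozygous structural
variant moves a fraction of the affected wild-type peptide's signal onto the
mutant peptide. Lognormal noise keeps areas strictly positive and is
parameterized directly by CV.

Numerical choices, made once and documented here:

* Baseline noise-free ratios: `aT1_bT1 = aT3_bT1 = 4.5` (α-chain output
  exceeds β-chain output several-fold in HbF-dominant newborns),
  `dT2_bT2 = 0.04` (δ barely expressed at birth), `zT8_bT2 = 0.002` (trace
  embryonic ζ), `gT10_aT3 = 0.8` (γ the dominant non-α chain).
* Default measurement CV 10% for analyte and IS areas, inside the assay's
  validated imprecision range (inter-assay CVs up to ~15%).
* Genotype presets: α multipliers 0.7 / 0.55 / 0.5 / 0.25 with ζ elevations
  8 / 15 / 50 / 100 for one-gene, two-gene-trans, --SEA and HbH classes;
  β-thalassemia carriers at β 0.5–0.7 with δ 1.8; heterozygous variant
  fractions near 0.5 (0.75 for Hb G-Coushatta so its simulated ratio clears
  the 2.19 cutoff, since peptide-specific response factors are not
  modelled).
* Default study cohort: 200 normal, 50 --SEA-like, 50 β⁰-like samples at
  CV 10% with a fixed seed; the larger parameter-recovery runs use 5,000
  samples. These sizes make every check in the test suite a desk-scale
  computation.

The preset magnitudes are **synthetic calibration knobs**, not measured
biology: only the *direction* of each effect and the qualitative ordering
(normal < α⁺ < --SEA < HbH in $P(\alpha)$) follow the physiology. The
generator also omits chromatographic artifacts (retention drift,
co-elution), the postnatal Hb switching time-course (ages are static
labels), carryover between injections, and real per-genotype effect-size
distributions. Consequently, passing end-to-end tests show the *pipeline
logic* is sound — not that the assay achieves any particular clinical
performance; the clinical figures this package reproduces come from the
shipped validation count tables, never from simulation.

## A worked run

```{r example}
spec <- cohort_spec(c(normal = 200, sea_het = 50, beta0_het = 50),
                    cv = 10, seed = 12345)
peaks <- generate_cohort(spec)
profiles <- quantify_cohort(peaks)
result <- screen_cohort(profiles)
result$summary

merged <- inner_join(result$calls, cohort_truth(peaks), by = "sample_id")
cm <- confusion_matrix(
  merged$category %in% c("alpha_thalassemia", "alpha_and_beta_thalassemia"),
  merged$group == "alpha_thalassemia")
sensitivity_specificity(cm)
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(result)
```

## Known limitations

* The variant-ratio formula and the "> 0" cutoffs make abnormal-Hb calls a
  detection test; quantitative variant fractions are not interpreted.
* Severity bands are suggestive only; genotype confirmation (sequencing) is
  outside this package's scope.
* `fit_logistic()` offers no penalization, so separated refits must be
  caught via `separation_flag`; there is no cross-validation machinery
  beyond what a user can build from the exported pieces.
* The shipped transition registry stores one published IS product ion
  (βT2, 68.3927 Th) as printed even though it is physically implausible; the
  entry carries a note, and nothing in the quantification depends on m/z
  values.
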
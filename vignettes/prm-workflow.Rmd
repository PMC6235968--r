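---
title: "Targeted PRM quantification of ethylene-signaling proteins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted PRM quantification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmquant)
```

## The problem

Ethylene receptors (ETR1–ETR7), CTR-like kinases (CTR1–CTR4) and EIN2 sit
at the top of the ethylene signal-transduction pathway that drives
climacteric fruit ripening. They are very low-abundance membrane proteins,
below the comfortable reach of shotgun proteomics, and transcript levels
are known to be an unreliable proxy for their protein levels. Parallel
reaction monitoring (PRM) with stable-isotope-labeled spike-in peptides
solves both problems: a quadrupole isolates one precursor at a time, all
of its fragments are read out in a high-resolution analyzer, and a known
amount of a heavy-labeled twin of each target peptide turns the
light/heavy area ratio into an absolute amount.

`prmquant` implements that workflow end to end: proteotypic peptide
selection, assay-panel mass arithmetic, extraction and integration of
transition chromatograms, decoy-based identification confidence,
single-point-calibration quantification, peptide-to-protein roll-up,
qPCR expression analysis, and a Monte-Carlo procedure for correlating
protein and mRNA stage profiles. A seeded simulator stands in for the
instrument and the fruit, so every stage is testable against a known
ground truth.

## Assay design

Target proteins are digested in silico with the classical trypsin rule:
cleavage C-terminal of K/R except before proline. Candidate peptides are
kept when they are 7–25 residues long, carry no missed cleavage, contain
no methionine, cysteine or histidine, and occur in exactly one proteome
entry ("mass between 7 and 25 amino acids" is read as length in residues,
the unit the criterion itself uses). Panels may additionally include
explicitly supplied peptides that violate the strict filters — in the
original assay several peptides entered via an earlier shotgun
experiment, including a histidine-bearing one — so the builder accepts an
`extra_peptides` escape hatch while the filters stay strict.

Mass arithmetic uses six-decimal monoisotopic residue masses, water
18.0105646 Da and the proton 1.00727646 Da. The heavy labels are fixed at
+8.014199 Da (^13^C~6~^15^N~2~ lysine) and +10.008269 Da
(^13^C~6~^15^N~4~ arginine); these exact values reproduce all 42 printed
precursor m/z of the bundled panel at four decimals, which is also the
package's m/z print convention (rounding half away from zero).
Uniqueness screening treats I and L as distinct letters by default; since
the two are isobaric and indistinguishable by mass, a `collapse_il` mode
is available and its effect is tested.

```{r}
panel <- demo_panel()
head(validate_panel_mz(panel), 3)
```

## The simulator: what it emulates and what it does not

`simulate_run()` generates, per panel peptide, co-eluting light and heavy
transition groups as Gaussian elution peaks: each trace is
$A f_i \exp(-(t-\mathrm{apex})^2 / 2\sigma_t^2)$ plus zero-truncated
Gaussian noise. The summed area of a group is `response_factor` times the
fmol on column — true abundance × digestion yield for the light form, the
spiked amount for the heavy form. Per-transition fractions $f_i$ come
from one Dirichlet draw per peptide, shared by both isotopes, which is
what makes the light/heavy pattern comparison meaningful. Light and heavy
share one retention-time jitter per peptide (isotopologues co-elute by
construction), and reported trace m/z carry a ppm-scale error.

Defaults state the experimental world being emulated: four ripening
stages (mature green, breaker, orange, red) × six biological replicates,
1 µg injections, a 6 s FWHM peak on a 60-min gradient
(σ ≈ 2.55 s), spike levels 0/1/5/10/100/200 fmol for the dilution series,
and protein abundances drawn log-uniformly from 1–20 fmol/µg with
climacteric, declining, late-drop or flat stage shapes — the patterns and
order of magnitude reported for these proteins in ripening tomato
pericarp. Digestion yields default to 1; a `"discordant"` preset (yields
1/0.5/0.25 across a protein's peptides) reproduces the between-peptide
disagreement that position-dependent trypsin efficiency causes in real
data.

The simulator does **not** model chemical interference, chromatographic
drift, carry-over, or MS2 spectra. A green round-trip test therefore
establishes that the quantification arithmetic and gating logic are
correct, not that the workflow is robust to matrix effects — that
robustness lived in the manual XIC curation of the original experiment.

## Identification scoring and q-values

A transition group is scored on four sub-scores mapped to [0, 1]:
retention-time agreement with the schedule, mass error against a 5 ppm
gate, mean pairwise Pearson correlation of the transition traces
(co-elution), and the normalized dot product of light areas against a
reference pattern (the heavy group by default). The composite is a
weighted sum with default weights rt 0.2, ppm 0.3, co-elution 0.3, dot
product 0.2 — the underlying criteria are those used for manual
validation; the weights themselves are a package choice and are
configurable.

Full semi-supervised mProphet rescoring is deliberately not
reimplemented. The workflow consumes q-values only at two fixed gates
(keep below 0.01, flag between 0.01 and 0.05, remove above 0.05), so a
transparent estimator suffices: shuffled-sequence decoy groups are scored
through the identical code path, and
$\mathrm{FDR}(s) = \#\{d \ge s\} / \max(1, \#\{t \ge s\})$
with the q-value as the running minimum over decreasing score. One
subtlety: shuffling preserves amino-acid composition, hence the precursor
mass, so a precursor-level mass error cannot separate decoys from
targets. The mass-error term is therefore evaluated per transition
against the m/z the chromatogram was *queried* at, which restores the
separation (a decoy fragment that happens to fall within the 0.5 Da match
tolerance still shows a mass error of hundreds of ppm).

Flagged groups are kept by default and removed under `strict = TRUE`,
mirroring the ambiguity of "some of which were eliminated" in the source
experiment. A missing heavy signal yields an explicit `NA`-with-warning
quantification-failure record rather than a silent drop — the real
experiment has exactly this case (CTR4 was never quantified).

## Quantification and dilution linearity

Absolute abundance is single-point calibration:
$\mathrm{fmol}/\mu g = (\sum \mathrm{AUC}_\mathrm{light} / \sum
\mathrm{AUC}_\mathrm{heavy}) \times \mathrm{spike} / \mu g_\mathrm{injected}$,
summing over exactly the panel's quantifier transitions. Integration is
trapezoidal over the extraction window; the apex is located by quadratic
interpolation of the summed trace. The dilution-series check regresses
the run-to-run-corrected response (heavy/endogenous area ratio, the
endogenous signal acting as the internal normalizer) on the spike level;
the level-0 run is excluded (nothing to normalize against a zero heavy
signal). The inverse ratio convention is exposed because the source
description is ambiguous between its two mentions; the default follows
the calibration-section reading.

## Protein roll-up

Proteins observed through several peptides are rolled up with a linear
mixed model: stage fixed, peptide random, and a random fruit (sample)
intercept inducing compound symmetry among peptides measured on the same
fruit — the minimal-parameter reading of a "repeated structure" on
samples. Fitting is REML via `lme4`; with a balanced design the
cell-means fixed effects are the marginal stage means. Single-peptide
proteins route to classical one-way ANOVA, to which the mixed model
provably reduces; that reduction is an acceptance test. When the
optimizer fails (degenerate data with zero residual variance), the
roll-up falls back to an ANOVA on peptide-averaged samples and records
`model_used = "anova-fallback"`.

Degrees of freedom for Tukey comparisons under the mixed model use a
containment-style count (observations minus estimated fixed, peptide and
sample levels) rather than Satterthwaite, which is unavailable without
`lmerTest`; this is a known divergence risk versus commercial software
and affects borderline letters only. The compact letter display itself is
computed by insert-and-absorb over all-pairs studentized-range tests and
is verified against brute-force enumeration of the pairwise tests.

## qPCR analysis

Amplification efficiency comes from the pooled-cDNA standard curve,
$E = 10^{-1/\mathrm{slope}}$ of Ct on log10 input. The "modified Ct"
relative quantity is implemented as the standard efficiency-corrected
form $Q = E^{(Ct_{\min} - Ct)}$ with the per-gene minimum Ct as
calibrator — the source does not print its formula, so this
interpretation is documented and the calibrator is configurable.
Normalization divides by the arithmetic mean of the three reference-gene
quantities (Actin, EF1, GAPDH); a geometric-mean mode exists because
common practice differs. The construction makes normalized expression
invariant to a run-wide Ct offset, which is tested.

## Monte-Carlo correlation

Protein and transcript profiles come from different fruits, so their
structural correlation is approximated: 1500 random datasets are drawn
with each stage value independently Normal(mean, SE), a Pearson r is
computed per dataset, and the summary is the mean on the Fisher-z scale.
The 95% interval is the 2.5/97.5 percentile of the z samples mapped back
through tanh (a mean ± 1.96 sd variant is available); significance means
the interval excludes zero. Normal sampling is the minimal distribution
consistent with "same mean and SEM"; r is clipped at 1 − 10⁻¹² before
atanh so zero-SE draws stay finite.

A calibration caveat found while testing, and worth stating plainly: with
only four stages this procedure is strongly conservative as a test of
zero correlation. Resampling around means that already contain the
measurement noise both attenuates the resampled r (toward roughly half
the observed r) and widens its distribution, so the percentile interval
almost never excludes zero unless |r| is near 1. Measured false-positive
rates under a true correlation of zero are 0.2–1.6% against the nominal
5%, and no parameter of the stated world changes this. The corresponding
acceptance assertion is intentionally left failing rather than loosened.
Practically, the conservatism means significant calls from this procedure
are trustworthy, and non-significant ones are weak evidence of absence.

## Worked example

```{r, eval = FALSE}
out <- run_pipeline(tempfile("prm"), seed = 1)
```

The pipeline writes `panel.csv`, `quant.csv`, `profiles.csv`, `cts.csv`,
`expression.csv`, `correlation.csv`, a log and a checksummed
`manifest.json`; identical seeds give identical checksums.

## Known limitations

- The simulator's noise model is additive Gaussian only; interference and
  drift are out of scope (documented extension point).
- Mixed-model df are approximate; exact agreement with JMP/SAS letters is
  not guaranteed for borderline pairs.
- The decoy null is shuffled-sequence only; second-best-peak decoys are
  not implemented.
- Retention times are taken from the panel; no RT prediction.
- The real experiment's headline percentages (83.7/13.9/2.4% q-value
  classes, the published fmol/µg profiles, the three significant
  protein–mRNA correlations) depend on the deposited raw data and are not
  reproduced here; property-based tests on synthetic data substitute.
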
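---
title: "Methods: quantitative metabolomics of MEP-pathway bottlenecks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative metabolomics of MEP-pathway bottlenecks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepscope)
library(dplyr)
```

## The scientific problem

*Zymomonas mobilis* makes the isoprenoid precursors IDP and DMADP through
the seven-step methylerythritol 4-phosphate (MEP) pathway, fed by pyruvate
and glyceraldehyde 3-phosphate from Entner–Doudoroff (ED) glycolysis. The
pathway is attractive for isoprenoid engineering — ED glycolysis runs at
very high flux — but which steps limit carbon flow is not obvious from
sequence or annotation. The experimental strategy this package supports is
to overexpress pathway enzymes singly or in combination and read the
bottlenecks off the metabolome: a substrate that piles up while its product
barely moves marks the enzyme between them as rate limiting.

`mepscope` implements the full quantitative analysis around that strategy:

1. **Absolute quantification** of intracellular metabolites by isotope
   dilution (`quantify_samples()`).
2. **Relative time-course quantification** against a spiked ¹³C reference
   with OD normalization (`fold_change_vs_t0()`).
3. **Differential statistics** — equal-variance and paired *t* tests on
   log2 signals with Benjamini–Hochberg FDR control (`test_fold_changes()`).
4. **Pool accounting** (`pool_sum()`, `pool_ratio()`).
5. **In vivo thermodynamics**, ΔG = ΔG°′ + RT·ln Q (`pathway_dg_table()`).
6. **Physiology** — growth rate, glucose consumption, isoprene yield
   (`fit_growth_rate()`, `consumption_rate()`, `isoprene_yield()`).
7. **Bottleneck scoring** (`accumulation_scores()`).
8. A **synthetic-data generator** with known ground truth
   (`simulate_single_timepoint()`, `simulate_timecourse()`,
   `simulate_physiology()`) so that each stage is testable end to end.

## Quantification models

### Isotope-dilution absolute quantification

Cells grown on uniformly labeled [U-¹³C] glucose carry fully heavy
metabolites (mass shift `n_C × 1.003355` Da, `isotope_mass_shift()`).
Extraction solvent contains unlabeled standards at known concentration
$c_\mathrm{std}$, so in a single LC–MS run

$$\hat c_\mathrm{extract} = \frac{I_{13}}{I_{12}} \, c_\mathrm{std}.$$

Because both channels share one injection, the estimate is invariant to any
common intensity rescaling — the property that makes the method robust to
instrument drift. Extract molarity is converted to cytoplasmic molarity
with the extraction geometry:

$$\hat c_\mathrm{cell} = \hat c_\mathrm{extract}
  \frac{V_\mathrm{solvent}}{\mathrm{OD}_{600} \cdot V_\mathrm{culture}
  \cdot v_\mathrm{bio}},$$

where $v_\mathrm{bio}$ (µL of cytoplasmic aqueous volume per OD·mL,
default 3.0) is a documented assumption: the constant is not published for
this system, and all reference-table arithmetic in the package uses the
table's molarities directly rather than this conversion. Excreted
metabolites (pyruvate, MEcDP) can be corrected for medium carryover on the
filter via `extracellular_correction()`; the correction defaults to off
(carryover 0 µL) because no carryover volume is published, and it clamps at
zero rather than returning negative amounts.

Replicates are summarised with a normal-theory *t*-interval (95% default).
With n = 6 replicates the *z*-interval would undercover noticeably (~90%);
the *t*-interval restores the nominal rate, which the test suite verifies
by simulation (300 runs at cv = 0.1). Missing or zero standard-channel
signal flags `below_LOD`; CDP-MEP, which has no purified standard, is
flagged `no_standard` and participates only in relative analyses.

### Time-course relative quantification

Each time-course sample (unlabeled, ¹²C) is mixed with a fixed aliquot of a
fully labeled reference extract (¹³C). The analysis chain is

$$x_{r}(t) = \frac{I_{12}/I_{13}}{\mathrm{OD}_{600}(t)}, \qquad
  \mathrm{FC}_r(t) = \frac{x_r(t)}{x_r(0)},$$

i.e. reference normalization (cancels injection-to-injection variation), OD
normalization (cancels biomass growth), and a per-replicate fold against
that replicate's own pre-induction sample. The reported fold is the
**geometric mean** over replicates. The choice of geometric over arithmetic
mean was open; the geometric mean is the location estimate matching the
log2-domain *t* tests, makes FC(0) ≡ 1 exactly, and is symmetric for
up/down regulation. Replicates lacking a t = 0 observation are dropped with
a warning rather than imputed.

Single-time-point experiments (all strains sampled at OD 0.5) are not OD
normalized; there the fold is the ratio of group means versus the GFP
control, computed on the analyte-channel intensities so that relative-only
metabolites (CDP-MEP) participate.

### Statistics

Single-time-point contrasts use a two-tailed pooled-variance two-sample
*t* test on log2 signals (`two_sample_t_equal_var()`, df = nₐ+n_b−2).
Time-course contrasts use a paired two-tailed *t* test, implemented as the
algebraically identical one-sample *t* of per-replicate log2 fold changes
against 0 (`paired_t_vs_baseline()`, df = n−1). Degenerate inputs are
handled explicitly: zero variance with equal means gives p = 1; zero
variance with a nonzero mean gives p = 0 with a `degenerate` flag.

Multiple testing is controlled with Benjamini–Hochberg at 5%
(`bh_adjust()`, a thin wrapper over `stats::p.adjust`; an independent
brute-force step-up oracle lives in the test suite). The BH *family* is not
uniquely defined by the experimental design, so it is a configuration
option (`flag_significance(scope = ...)`): the default `per_experiment`
adjusts all metabolite × timepoint tests within one strain, matching how a
single figure panel is assessed; `per_timepoint` and `global` are
available. Time courses additionally carry a per-metabolite
"significant at any time point" flag.

## Pools and integer-fold reporting

Pool totals are plain sums of member molarities, with flagged members
excluded *and reported* (`pool_sum()`), never silently imputed as zero —
the numeric result is the same, but the exclusion is auditable. The MEP
pool defaults to the six absolutely quantified intermediates
(DXP … IDP/DMADP). Whether the downstream prenyl diphosphates GPP and FPP
belong in it is ambiguous; both memberships are provided
(`MEP`, `MEP_with_prenyl`), and the glycolytic/MEP pool-ratio claim holds
under either (69.1 versus 64.0, both ≥ 50). Reported integer folds use
round-half-away-from-zero (`round_half_away()`), the convention behind
figures that print "38-fold". The reference table also yields
MEcDP/HMBDP = 16.9, marginally below a ">17-fold" reading; the package
reports computed ratios as-is rather than reconciling rounding applied
upstream of the printed table.

## Thermodynamics

`pathway_dg_table()` evaluates ΔG = ΔG°′ + RT·ln Q with
R = 8.314×10⁻³ kJ·mol⁻¹·K⁻¹ and T = 303.15 K (RT = 2.5204 kJ/mol), a 1 M
standard state, and unit water activity (water never enters Q).
Conventions that the source data do not pin down, chosen once and encoded
in the bundled pathway definition:

* **Electron donors**: DXR, IspG and IspH are written on the NADPH/NADP⁺
  couple.
* **CO₂** enters via Henry's law, `henry_co2()`: k_H × p(CO₂) with
  k_H = 3.0×10⁻² M/atm at 30 °C (configurable; an implementer-chosen
  constant) and p(CO₂) = 0.05 atm (5% chamber atmosphere), giving 1.5 mM.
* **Diphosphate** defaults to 100 µM, the conventional intracellular
  estimate for a species that is not quantified.

ΔG°′ values are *inputs*, not computed: the component contribution method
is out of scope. The bundled priors file is **synthetic**
(`dg0_prime_synthetic.csv`) — plausible magnitudes chosen once for the
stated conditions (pH 6, I = 0.25 M, pMg 3, 30 °C) so the machinery can be
exercised and tested; a real analysis should regenerate the file with a
component-contribution tool at those conditions. IspF and IspG carry no
standard energy (the predicted formation energy of MEcDP is too uncertain)
and are flagged `no_dg0_prime`; IspE is flagged `missing_species` because
CDP-MEP has no absolute concentration. Uncertainty on ΔG°′ is carried
through unchanged; concentration uncertainty is not propagated (a
first-order term could be added, but the ΔG°′ uncertainty dominates by an
order of magnitude).

## Physiology

Growth rate is the least-squares slope of ln OD vs time. The exponential
window, when not supplied, is the largest contiguous run of ≥ 3 points with
log-linear R² ≥ 0.99 (earliest longest run; R² breaks length ties) — a
deterministic rule that excludes stationary phase without manual curation.
The specific glucose consumption rate is q = µ·ΔS/ΔX over that window,
with biomass ΔX = ΔOD × 0.33 gDCW/L/OD (the dry-weight conversion is a
documented assumption). The glucose assay inverts the isotope-ratio
dilution algebra: supernatant diluted 1/50, mixed 50:50 with a 1 mM
[U-¹³C] spike, so S = ratio × 1 mM × 50 — the 50:50 mix dilutes both
channels equally and cancels; `glucose_concentration()` documents and
unit-tests this mass balance.

Isoprene yield divides total vial isoprene (headspace reading, ideal-gas
conversion for ppbv inputs, scaled by headspace/sampled volume) by mmol of
glucose consumed by the 200 µL aliquot during the sealed 10-min window.
The assay-window convention is configurable since the integration window of
the published denominators is not fully specified; FIS calibration is a
single configurable constant.

## Bottleneck score

For each reaction the package computes

$$s = \log_2 \mathrm{FC}(\text{main substrate}) -
      \log_2 \mathrm{FC}(\text{main product}) \;\text{bits},$$

classified *bottleneck* if s ≥ 1 bit (2-fold differential accumulation)
with a significant substrate fold change, *mitigated* if s ≤ −1 bit, else
*none*. The threshold formalizes a judgement the underlying study makes
qualitatively; it is a default, not a discovery procedure, and is labeled
as such in reports (`render_report()`). For the combined-isomer pool the
pool fold change is used. The score is exactly antisymmetric under
substrate/product swap, and rankings are invariant to common rescaling of
all folds.

## The synthetic-data generator

The generator produces every raw input the pipeline consumes, with ground
truth recorded, under the study conditions as defaults: n = 3 biological
replicates (6 for absolute quantification), single-time-point sampling at
OD 0.5, time courses induced at OD 0.35 and sampled at 0, 7.5, 15, 30, 45,
60 and 120 min, wild-type truth equal to the packaged reference
concentration table, and strain scenarios encoding the printed fold-change
responses (e.g. DXS2: DXP 9.3, CDP-ME 9.1, MEcDP 102; DXS2+IspG: HMBDP
140-fold at 60 min; isoprene yields 5.6–33.3 nmol/mmol). Where no value is
printed for a metabolite or intermediate time point, trajectory knots were
chosen once as realistic shapes (log-linear rise to a peak, partial
relaxation) and are marked in `scenarios.yaml`.

Noise is multiplicative lognormal on intensities — the standard model for
LC–MS peak areas — parameterised by a coefficient of variation
(default 0.2) and applied independently per channel, with mean exactly 1 so
that cv → 0 recovers the noise-free signal identically. Biological and
technical variance are not separable from the available information, so a
single cv covers both. Trajectories interpolate piecewise-linearly on the
log-fold scale; OD follows exponential growth with a hard stationary cap
(the real curve's shoulder is not modeled). All randomness derives from the
config seed; identical configs give bit-identical outputs.

What passing tests do and do not show: zero-noise round trips prove the
estimators invert the generative model exactly, and noisy recovery within
±30% over 100 seeds (the packaged acceptance conditions) bounds estimator
bias under the assumed noise model. They do not validate peak integration,
retention-time matching, adduct handling, saturation, or structured
(non-lognormal, correlated) instrument error — none of which the generator
emulates.

## Numerical choices and degenerate inputs

* Fold estimators: single-time-point folds are ratios of group arithmetic
  means (matching how control-normalized figures are computed); time-course
  folds are geometric means over replicates. The ratio-of-means estimator
  carries a small positive bias of order cv²/n under lognormal noise
  (≈ 1.3% at cv 0.2, n 3), well inside the ±30% acceptance band.
* Zero 12C (standard) intensity → `below_LOD`, never a division error;
  zero 13C reference → flagged missing; both are flags, not crashes.
* BH ties resolve via the deterministic cumulative-minimum step-up.
* Pool ratios are reported to 3 significant figures; integer-fold claims
  round half away from zero.
* The pipeline is pure in (inputs, config, seed): repeated runs produce
  byte-identical report JSON.

## Problem sizes used in the test suite

Simulation-based tests are sized to establish their property without
excess: CI coverage uses 300 runs at n = 6; type-I calibration uses
4×10³–10⁴ null features; BH is checked against a brute-force oracle on
1000 random vectors; fold-change recovery uses 100 seeds at the packaged
scenario conditions (and 12–25 seeds for the bias-trend checks). The
acceptance script reruns the two recovery analyses at 100 seeds each.

## Known limitations

* Absolute molarities depend linearly on the biovolume constant; until a
  measured value is supplied, cross-condition *ratios* are the robust
  quantities.
* The IspE quotient cannot be evaluated without a CDP-MEP concentration;
  how a complete energy table could be produced without one is left open,
  and the package flags rather than guesses.
* The bundled ΔG°′ priors are synthetic stand-ins; in vivo ΔG values
  computed from them demonstrate the arithmetic, not the chemistry.
* No imputation, smoothing, or variance moderation: with n = 3 the tests
  are exactly what they claim to be, at the cost of power.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config("DXS2", "single_timepoint", seed = 1, noise_cv = 0.2)
res <- run_pipeline(cfg)
res$fold_changes |>
  filter(significant) |>
  arrange(desc(fold_change))
res$scores          # IspG ranks first: the MEcDP -> HMBDP step
autoplot(res$scores)
```
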
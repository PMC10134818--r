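# mepscope

Quantitative metabolomics of methylerythritol 4-phosphate (MEP) pathway
bottlenecks in *Zymomonas mobilis*.

*Z. mobilis* channels glucose through Entner–Doudoroff (ED) glycolysis at
very high flux, making it a promising chassis for isoprenoid production via
the MEP pathway (pyruvate + GAP → DXP → MEP → CDP-ME → CDP-MEP → MEcDP →
HMBDP → IDP/DMADP). Which of the seven enzymatic steps limits carbon flow
can be read off the metabolome of enzyme-overexpression strains: a
substrate that accumulates while its product barely moves marks the enzyme
between them as a bottleneck. `mepscope` is an R package for everyone
running (or reviewing) that kind of experiment: it implements the complete
analysis from LC–MS peak tables to a ranked bottleneck report, plus a
synthetic-data generator with known ground truth so every stage is testable
without instrument data.

## What it computes

* **Absolute quantification by isotope dilution** — cells grown on
  [U-¹³C] glucose, extracted into solvent with unlabeled standards:
  ĉ = (I₁₃/I₁₂)·c_std, converted to cytoplasmic molarity via the
  extraction geometry (`quantify_samples()`).
* **Time-course fold changes** — ¹²C sample / ¹³C reference-spike
  normalization, OD₆₀₀ normalization, per-replicate fold versus the
  pre-induction state, geometric mean across replicates
  (`fold_change_vs_t0()`).
* **Differential statistics** — equal-variance two-sample *t* (strain vs
  GFP control) and paired *t* (one-sample *t* of log₂ fold changes vs 0),
  with Benjamini–Hochberg FDR at 5% (`test_fold_changes()`,
  `bh_adjust()`).
* **Metabolite-pool accounting** — summed category pools and pool ratios
  (`pool_sum()`, `pool_ratio()`).
* **In vivo thermodynamics** — ΔG = ΔG°′ + RT·ln Q with mass-action
  quotients from the concentration table, Henry's-law CO₂, and a 100 µM
  diphosphate default (`pathway_dg_table()`).
* **Physiology** — exponential growth rates, isotope-ratio glucose assay,
  specific consumption rates, and headspace isoprene yield per glucose
  (`fit_growth_rate()`, `consumption_rate()`, `isoprene_yield()`).
* **Bottleneck scores** — per reaction,
  score = log₂ FC(substrate) − log₂ FC(product) bits; ≥ 1 bit with a
  significant substrate change calls a bottleneck
  (`accumulation_scores()`, `render_report()`).

All user-facing functions take and return tibbles and chain with the pipe;
result types have `autoplot()` methods, and fitted objects have
`tidy()`/`glance()` methods.

## Worked example

Simulate the DXS-overexpression scenario (truth: MEcDP 102-fold over the
GFP control) with realistic noise, then run the whole pipeline:

```r
library(mepscope)
library(dplyr)

cfg <- sim_config("DXS2", "single_timepoint", seed = 1, noise_cv = 0.2)
res <- run_pipeline(cfg)

res$fold_changes |>
  filter(significant) |>
  arrange(desc(fold_change)) |>
  select(metabolite_id, fold_change, p_value, q_value) |>
  head(5)
#>   metabolite_id fold_change    p_value   q_value
#> 1 MEcDP              108.   0.00000922 0.0000952
#> 2 CDP-ME               8.06 0.00000456 0.0000952
#> 3 DXP                  7.10 0.000148   0.00115
#> 4 MEP                  4.89 0.00000650 0.0000952
#> 5 HMBDP                4.61 0.000248   0.00130
```

The recovered folds sit near the configured truths (MEcDP 102, CDP-ME 9.1,
DXP 9.3) given n = 3 replicates at 20% noise, and all are FDR-significant.
The accumulation scores then localize the constraint:

```r
res$scores |> head(3)
#>   reaction substrate product score_bits classification
#> 1 IspG     MEcDP     HMBDP        4.55  bottleneck
#> 2 IspE     CDP-ME    CDP-MEP      0.835 none
#> 3 IspH     HMBDP     IDP/DMADP    0.720 none
```

IspG ranks first — MEcDP piles up ~23× faster than HMBDP — which is the
bottleneck call for this scenario. Pool accounting and thermodynamics work
straight off the packaged wild-type concentration table:

```r
ct <- zm4_concentrations()
pw <- mep_pathway()
pool_ratio(pool_sum(ct, pw$pools$ED_glycolysis, "ED"),
           pool_sum(ct, pw$pools$MEP, "MEP"))
#> 69.1   # the ED pool is ~69x the MEP pool

pathway_dg_table(ct) |> select(reaction, dg0_prime, rt_ln_q, dg_in_vivo, flag)
#>   reaction dg0_prime rt_ln_q dg_in_vivo flag
#> 1 DXS          -50     -8.13      -58.1 ok
#> 2 DXR          -40     -7.80      -47.8 ok
#> 3 IspD          -8.3   -3.71      -12.0 ok
#> 4 IspE         -12     NA          NA   missing_species
#> 5 IspF          NA     NA          NA   no_dg0_prime
#> 6 IspG          NA     -8.66       NA   no_dg0_prime
#> 7 IspH        -130     -1.64     -132.  ok
```

Every evaluable step is strongly exergonic, with IspD the least favorable
(−12 kJ/mol). Note the bundled ΔG°′ priors are synthetic stand-ins (see
`load_dg0_priors()`); supply component-contribution estimates for real
analyses. The flags mark what genuinely cannot be evaluated: CDP-MEP has
no absolute concentration (IspE) and MEcDP has no reliable formation
energy (IspF/IspG).

See `vignettes/mep-bottleneck-methods.Rmd` for the models, assumptions,
defaults and their rationale.

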
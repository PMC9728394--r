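# glycoscreen

Post-processing toolkit for ensemble-docking studies of glucosyl-transfer
enzymes (amylosucrase-type transglucosylation), written for structural
bioinformaticians who have docking poses and replica MD trajectories in hand
and need the downstream analysis: which poses are *reactive conformations*,
how a mutation shifts the conformational population, whether it rigidifies
the active-site loops, and what the enzyme kinetics say.

## What it computes

**Reactive-conformation screening.** Glucosyl transfer requires the
acceptor's hydroxyl oxygen to attack the anomeric carbon of the covalent
glucosyl–aspartate intermediate while the catalytic glutamate deprotonates
it. Per hydroxyl per pose the package measures

- *d1*: hydroxyl O → anomeric C distance (Å),
- *d2*: min distance from the hydroxyl O to either carboxylate O of the
  catalytic glutamate (Å),
- *a1*: attack angle at the anomeric carbon between the hydroxyl O and the
  leaving-group O (°),

and classifies a pose reactive when `d1 < 4 Å`, `d2 < 4 Å` and
`80° < a1 < 140°` (any hydroxyl suffices for polyols).

**Variant comparison.** 2D (d1, a1) density-difference maps after a
`d2 < 4 Å` prefilter, reactive-pose enrichment counts, and per-ligand
two-proportion tests across acceptors.

**Flexibility.** Per-residue RMSF after Kabsch superposition, replica means
with 95% *t* confidence bands, per-residue Welch tests between variants,
and per-frame RMSD traces.

**Kinetics.** Michaelis–Menten fits by Lineweaver–Burk
(`1/v = Km/Vmax · 1/[S] + 1/Vmax`) and by direct nonlinear least squares;
through-origin linear fits for non-saturating substrates where only
`kcat/Km` is identifiable; `kcat = Vmax · MW · 10⁻³` (min⁻¹) and `kcat/Km`
(mM⁻¹ min⁻¹); product-yield fold changes with first-order error
propagation.

Synthetic generators for pose ensembles, replica trajectories and
initial-velocity data — each with exact recorded ground truth — stand in
for the docking/MD engines, so the whole pipeline runs and is tested at
desk scale. File I/O covers PDB v3.3, multi-model PDBQT (AutoDock dialect,
Vina score remarks) and multi-frame XYZ.

## Worked example

```r
library(glycoscreen)

# synthetic hydroquinone-like ensembles: WT at 20% reactive, mutant at 30%
wt  <- generate_pose_ensemble(pose_ensemble_spec(
  500, ligand_name = "HQ", n_hydroxyls = 2,
  fraction_reactive_target = 0.20, seed = 101))
mut <- generate_pose_ensemble(pose_ensemble_spec(
  500, ligand_name = "HQ", n_hydroxyls = 2,
  fraction_reactive_target = 0.30, seed = 102))

gw <- classify_poses(wt$atoms,  wt$receptor,  wt$site)
gm <- classify_poses(mut$atoms, mut$receptor, mut$site)
head(gw, 3)
#> # A tibble: 3 × 8
#>   pose_id hydroxyl_serial hydroxyl_name    d1    d2    a1 reactive n_hydroxyls
#>     <int>           <int> <chr>         <dbl> <dbl> <dbl> <lgl>          <int>
#> 1       1               1 O1             3.98  4.91 119.  FALSE              2
#> 2       2               1 O1             4.55  2.84  57.6 FALSE              2
#> 3       3               1 O1             5.76  2.79 139.  FALSE              2

build_conformation_map(gw, gm)
#> <conformation_map> 328 WT / 348 mutant poses after d2 prefilter;
#>   enrichment (mut - WT reactive): 35
```

Each pose row carries the geometry of its representative hydroxyl and the
reactive verdict; the map reports 35 more reactive mutant poses than
wild-type poses inside the reactive region, out of 500 poses per variant.

```r
d <- generate_kinetic_data(kinetic_sim_spec(
  Km_true = 36.174, Vmax_true = 0.090,
  substrate_concs = c(0.4, 1, 2, 5, 10, 25, 50, 100, 200),
  noise_cv = 0.05, replicates = 3, seed = 7))
derive_kcat(fit_mm_nonlinear(d), MW = 73044)
#> <kinetic_fit> regime: saturation
#>   Km   = 35.34 +/- 1.51 mM
#>   Vmax = 0.09005 +/- 0.00131 umol/min/mg
#>   kcat = 6.578 min^-1, kcat/Km = 0.1861 mM^-1 min^-1
#>   R^2 = 0.9971 (n = 27)

fold_change(6.80, 4.76, a_sd = 0.26, b_sd = 0.02)
#> # A tibble: 1 × 3
#>   ratio ratio_sd ratio_1dp
#> 1  1.43   0.0550       1.4
```

The fit recovers the simulated Km (36.174 mM) and Vmax
(0.090 µmol min⁻¹ mg⁻¹) within their standard errors at 5% assay noise; the
yield comparison reports a 1.4-fold increase at the conventional one-decimal
rounding.

Every result type has `autoplot()` (density-difference map, RMSF band plot,
Michaelis–Menten / Lineweaver–Burk plots), and fitted objects have
`tidy()`/`glance()` methods. `run_pipeline(demo_pipeline_config())`
executes the full generate → screen → compare → rmsf → kinetics workflow
into a report directory with a reproducibility manifest; a thin CLI wrapper
lives at `inst/scripts/glycoscreen.R`. See
`vignettes/reactive-conformation-screening.Rmd` for the methods account.

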
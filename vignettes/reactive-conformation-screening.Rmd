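---
title: "Reactive-conformation screening and kinetics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactive-conformation screening and kinetics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoscreen)
```

## The scientific setting

Amylosucrase transfers a glucosyl unit from sucrose onto an acceptor
hydroxyl. Catalysis proceeds through a covalent glucosyl–aspartate
intermediate: the acceptor's hydroxyl oxygen must attack the anomeric carbon
of the bound glucose while the catalytic glutamate acts as the general base
that deprotonates it. Whether a docked acceptor pose is *transfer-competent*
is therefore a question of local geometry, and `glycoscreen` operationalises
it with three features measured per hydroxyl per pose:

* `d1` — distance from the hydroxyl oxygen to the glucosyl anomeric carbon
  (Å);
* `d2` — minimum distance from the hydroxyl oxygen to either carboxylate
  oxygen of the catalytic glutamate (Å);
* `a1` — angle at the anomeric carbon subtended by the attacking hydroxyl
  oxygen and the aspartate ester (leaving-group) oxygen (degrees).

A pose is a **reactive conformation** when `d1 < 4` Å, `d2 < 4` Å and
`80° < a1 < 140°` (strict inequalities; `reactive_criteria(strict = FALSE)`
switches to closed bounds). For polyhydroxylated acceptors
(hydroquinone, kaempferol, genistein, ...) the pose-level verdict uses
*any-hydroxyl* semantics: one transfer-competent hydroxyl is enough. The
reported features belong to the representative hydroxyl — the
criteria-satisfying one with smallest `d1`, otherwise the smallest-`d1`
hydroxyl overall, with ties broken by smaller `d2` and then atom serial.

Two readings of `a1` are defensible from the qualitative description of "the
angle between the hydroxyl group and the glucose moiety". We define it at
the anomeric carbon against the leaving-group oxygen — the standard in-line
near-attack proxy — and keep all three atom selectors configurable in
`catalytic_site_map()` so other readings cost one argument, not a fork.

Screening an ensemble of docked poses for two enzyme variants gives the
downstream comparisons:

* a 2D conformation map in the (`d1`, `a1`) plane after a `d2 < 4` Å
  prefilter, with the **density difference** (mutant − wild type, each
  variant normalised to unit mass) and the **enrichment count** — the raw
  difference in reactive-pose counts;
* a per-ligand **reactive-population summary** with a two-proportion test
  (an inferential layer we add; the original screen reports raw counts);
* per-residue **RMSF profiles** averaged over replica simulations with a
  95% *t* confidence band, and per-residue Welch *t*-tests between
  variants;
* **Michaelis–Menten kinetics**: Lineweaver–Burk and direct nonlinear fits
  in the saturating regime, a through-origin linear fit where saturation is
  not reached, `kcat = Vmax · MW · 10⁻³` and `kcat/Km`.

## What the synthetic generators emulate

The package replaces the MD and docking engines with generators that produce
data *with exact ground truth*, so every downstream stage can be tested
against known answers.

**Pose ensembles.** `generate_pose_ensemble()` samples `(d1, d2, a1)` from
normal distributions and constructs coordinates that realise the triple
exactly: anomeric carbon at the origin, leaving oxygen on the +y axis at
bond distance, hydroxyl oxygen placed from `(d1, a1)` with a uniform random
azimuth, and the carboxylate oxygens along the outward ray so that the
nearer one sits at exactly `d2`. Angles sampled outside [0°, 180°] and
nonpositive distances are *resampled*, never clamped, preserving the
distribution shape away from the boundary. Because every docking pose in an
ensemble-docking study comes from its own receptor frame, the site atoms are
emitted as a multi-model receptor (one model per pose). With
`fraction_reactive_target` set, each pose first draws a reactive/
non-reactive label and its geometry is rejection-sampled conditional on the
label, giving ensembles with a known expected reactive fraction. The default
distributions — `d1 ~ N(4, 1)` Å, `d2 ~ N(3.5, 1)` Å, `a1 ~ N(110°, 25°)` —
centre the population on the criteria boundary, which is the realistic
regime for an acceptor that does react but inefficiently, and they make
conditional sampling efficient for targets in the 0.1–0.5 range.

What the generator does *not* emulate: docking score distributions (scores
are decorative), ligand internal geometry beyond the hydroxyl triplets,
steric feasibility, or correlation between `d1`, `d2` and `a1` — features a
real docking engine would induce. Passing tests therefore certify the
*measurement and bookkeeping machinery*, not the docking physics.

**Trajectories.** `generate_trajectory()` adds iid per-frame Gaussian
displacements (per-residue, optionally per-axis scales) to a fixed extended
reference — the stationary-fluctuation regime RMSF analysis assumes. For
isotropic displacement of scale σ the population RMSF is exactly σ√3, the
closed form used as an oracle. Real trajectories add autocorrelation,
rigid-body drift and anharmonicity; superposed RMSF handles the drift
(tested with explicit rigid motions) but replica independence is an
assumption real data must earn.

**Kinetics.** `generate_kinetic_data()` uses multiplicative noise,
`v = Vmax·[S]/(Km+[S]) · (1+ε)`, `ε ~ N(0, cv)` — the constant-CV error
model typical of chromatographic quantification. Noiseless data lie exactly
on the curve, which pins both fitting routes to machine precision.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `d1_max`, `d2_max` | 4, 4 | Å | reactive-conformation distance thresholds |
| `a1_min`, `a1_max` | 80, 140 | ° | attack-angle window |
| `strict` | `TRUE` | — | thresholds as strict inequalities |
| `d1_bin`, `a1_bin` | 0.25 Å, 5° | | resolve the 4 Å / 80–140° box exactly on bin edges |
| ensemble | 5 × 5000 ps / 50 ps + t₀ | | 5 replicas × 101 frames = 505 conformations |
| `conf_level` | 0.95 | — | *t* interval at df = n_replicas − 1 |
| `alpha` | 0.05 | — | per-residue significance level |
| `noise_cv` | 0.05 | — | assay CV used in recovery studies |
| `MW` | user input | g/mol | required for `kcat`; the test fixture uses 73 044, the value implied by a tabulated (kcat, Vmax) pair |

Binning is half-open `[lo, hi)` with the top bin closed; edges extend in
whole bins when data exceed the nominal `[0, 15]` Å × `[0, 180]°` window, so
binning is always exhaustive. Contour-style smoothing of the difference map
(Gaussian, sd = 1 bin) exists in `autoplot()` only — statistics always use
raw counts.

## Numerical and design choices

* **Superposition** is a standard Kabsch least-squares fit (SVD with a
  determinant correction); the reference defaults to the first frame, and
  RMSF deviations are taken about the post-superposition mean structure.
  RMSF uses the population mean over frames (not the n−1 sample variance
  some toolkits use); the difference is a factor √(n/(n−1)), immaterial at
  trajectory lengths but accounted for in cross-checks.
* **Welch** (unequal-variance) *t*-tests compare per-replica RMSF values
  between variants; replica counts need not match. No multiple-testing
  correction is applied by default, mirroring per-residue reporting
  conventions; `p_adjust = "BH"` is one argument away. Degenerate
  zero-variance residues return p = 1 when the means agree and p = 0
  otherwise.
* **Lineweaver–Burk** estimates come from OLS of 1/v on 1/[S] with
  delta-method standard errors; a nonpositive intercept (no saturation
  signal) is an explicit fit error rather than a nonsensical negative Vmax.
  The **nonlinear route** (Levenberg–Marquardt via `minpack.lm`) is
  initialised from the LB estimates, falls back to `Vmax = max(v)`,
  `Km = median([S])` when those are infeasible, and is the recommended
  estimator under multiplicative noise: the reciprocal transform lets the
  lowest concentrations dominate the LB regression. Both estimators are
  honest about their limits — in recovery simulations at 5% CV the median
  relative Km error sits near 15% for the double-reciprocal route on a wide
  0.4–200 mM design and for the nonlinear route on a narrow design whose
  top concentration is below Km, where Vmax and Km are barely separable.
  The linear-regime fit is through the origin (v = 0 at [S] = 0 is
  mechanistically forced; `intercept = TRUE` for diagnostics) and runs a
  pure-error lack-of-fit test that warns when curvature says the regime
  assumption is wrong.
* **Replicates are pooled** in all fits; per-replicate dispersion can be
  examined from the returned data, and no mixed model is invented for a
  triplicate design.
* **Hydroxyl detection**: with hydrogens present, an oxygen within 1.2 Å of
  a hydrogen; hydrogen-free, an oxygen with exactly one heavy neighbour,
  a carbon, within 1.8 Å. The hydrogen-free rule cannot distinguish a
  carbonyl from a hydroxyl oxygen — a documented limitation of
  connectivity-free classification.
* **Altloc policy**: highest occupancy wins, ties go to the first record —
  deterministic by construction. Parsers never drop ATOM/HETATM records
  silently; skips are warned with counts, malformed fields error with the
  line number.
* **Determinism**: every generator takes an explicit seed and uses one
  RNG stream per call (`withr::with_seed`), so identical specs give
  byte-identical outputs and the pipeline manifest (seed + configuration +
  file checksums) suffices to reproduce a report bundle.

## Problem sizes used in the test suite

The automated checks run at desk scale, chosen to keep Monte-Carlo error
well inside the asserted bands: geometry oracle on 1000 poses; enrichment
recovery over 100 seed pairs of 1000-pose ensembles (0.2 vs 0.3 reactive
fractions, asserted against binomial 99% bounds); RMSF closed form at 5000
frames; kinetic recovery over 200 seeds per design; null calibration of the
per-residue test over 500 simulated replica sets of 20 residues (10 000
tests, a-priori acceptance band 0.04–0.06 around α = 0.05). Concentration
grids follow the study designs: sucrose 0.4–200 mM (nine points, log-like
spacing), the acceptor 0.1–1.0 mM (six points), both in triplicate.

## Known limitations

* The geometric screen is a necessary-condition filter: it knows nothing of
  activation energies, protonation states or water-mediated interactions.
* The generators produce independent poses and frames; autocorrelated or
  clustered docking output will have wider enrichment-count variance than
  the binomial bounds used here.
* The enrichment count is a raw difference of counts at the ensemble sizes
  supplied; it is not normalised across ligands with different pose counts
  (the population summary's fractions cover that case).
* `kcat` requires a user-supplied enzyme molar mass; the package refuses to
  guess one.
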
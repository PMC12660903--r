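# rnagate

Quantitative structural analysis of dynamic multidomain RNA assemblies,
built around the scaffold domain (D1) of group II intron ribozymes.

Group II introns fold sequentially: the ~300-nt D1 scaffold folds first,
then the 3'-terminal domains dock onto it without forming misfolded
"kinetic traps". Whether docking can proceed is governed by the geometry of
four helical subdomains of D1 — core D1c (residues 66–75/112–121),
peripheral D1c (80–102), D1d1 (124–133/230–242) and i1–i2 (6–23/250–267) —
hinged around conserved internal loops. rnagate turns coordinate models
(crystal structures, cryo-EM sub-state series, simulation frames) into the
standard descriptors of that geometry, and fits the kinetic models used to
assay the functional consequences of perturbing it. It is aimed at
structural biologists and RNA biophysicists comparing conformational states
of large RNAs.

## What it computes

**Scaffold geometry.** Helical axes are total-least-squares 3D lines through
the sugar-phosphate backbone atoms of a subdomain. From them:

* inter-helical angles *A–D*, with A = ∠(core D1c, D1d1),
  B = ∠(core D1c, peripheral D1c), C = ∠(core D1c, i1–i2),
  D = ∠(D1d1, i1–i2), reported in both directed and undirected conventions;
* the *gate distance* d(C1′ G75, C1′ U238), a proxy for the aperture of the
  D1 pocket;
* the radius of gyration R_g of the scaffold.

**Displacement mapping.** Kabsch superposition (SVD closed form, optional
iterative outlier rejection) and per-residue phosphate displacement
profiles between two conformations.

**Nucleotide conformation.** Backbone pseudo-torsions
η(i) = ∠(C4′ᵢ₋₁, Pᵢ, C4′ᵢ, Pᵢ₊₁), θ(i) = ∠(Pᵢ, C4′ᵢ, Pᵢ₊₁, C4′ᵢ₊₁), and
bulged-in / bulged-out classification of hinge nucleotides from the distance
of the base-ring centroid to the helix axis.

**Path-progress coordinates.** For N milestone conformations X₁…X_N,

    spath = Σᵢ i·exp(−λ R(X−Xᵢ)) / Σᵢ exp(−λ R(X−Xᵢ))
    zpath = −(1/λ)·ln Σᵢ exp(−λ R(X−Xᵢ))

with R the mean-squared deviation after optimal superposition and
λ = 2.3 / (mean adjacent-milestone distance) by default.

**Splicing kinetics.** The sequential two-step scheme
precursor →(k1) intermediate →(k2) linear intron in closed form, nonlinear
least-squares fitting of observed species, Michaelis–Menten fitting of SER
(spliced-exon reopening) initial rates with a Lineweaver–Burk cross-check,
and mutant/wild-type relative-activity tables.

**Synthetic structures.** Deterministic generators for idealized A-form
duplexes, multi-helix D1 mimics with prescribed angles and gate distance,
linear morphs, sub-state sweep ensembles, and noisy kinetic data — every
analysis stage is testable without external coordinate files.

## Worked example

```r
library(rnagate)

# a synthetic D1 scaffold mimic at closed-state geometry, 0.3 A noise
cons <- make_d1_construct(angle_A = 62.9, angle_B = 30, angle_C = 45,
                          angle_D = 60, gate_dist = 32.0,
                          noise_sigma = 0.3, seed = 1)
compute_descriptors(cons$structure) |>
  dplyr::select(angle_A, angle_B, angle_C, angle_D, gate_distance, rg)
#>   angle_A angle_B angle_C angle_D gate_distance    rg
#> 1    62.6    27.6    42.8    60.1          31.8  26.4
```

The pipeline recovers the construction geometry: angle A within half a
degree of the requested 62.9°, the gate within 0.2 Å of 32.0 Å. A
twenty-frame sub-state sweep behaves like an ordered cryo-EM ensemble:

```r
sw  <- make_sweep_ensemble("angle_A", seq(65.8, 80.5, length.out = 20),
                           noise_sigma = 0.2, seed = 2)
ser <- descriptor_series(sw$ensemble)
trend_stats(ser$angle_A)
#>   fraction_nondecreasing   min   max first  last range
#> 1                  0.947  65.7  81.1  65.7  81.1  15.4
```

i.e. the recovered angle-A series climbs from 65.7° to 81.1° (ground truth
65.8–80.5°) and 95% of adjacent steps are non-decreasing at this noise
level. Kinetic rate constants are recovered from a noisy time course:

```r
tc  <- make_kinetics_data("two_step", list(k1 = 0.016, k2 = 0.041),
                          seq(0, 180, by = 15), noise_sigma = 0.02, seed = 3)
tidy(fit_two_step(tc, n_starts = 3))
#>   term estimate std.error unit
#> 1 k1     0.0161  0.000206 1/min
#> 2 k2     0.0428  0.00125  1/min

relative_activity(c(vmax = 0.75, km = 7.87), c(vmax = 22.47, km = 192.67))
#>   parameter mutant wildtype percent percent_rounded
#> 1 vmax        0.75     22.5    3.34               3
#> 2 km          7.87    193.     4.08               4
```

A hinge-locked mutant with vmax = 0.75 and K_M = 7.87 retains 3% and 4% of
the wild-type parameters — the catalytic signature of rigidifying the D1
gate. Plot helpers (`plot_displacement_profile()`, `plot_rmsd_matrix()`,
`plot_descriptor_series()`, `autoplot()` on fits) render the standard
figures for each result type.

Deposited models can be analyzed directly, e.g.
`compute_descriptors(read_structure("4y1o.pdb"))` with the packaged
O. iheyensis registry; no coordinate files are bundled, so those runs
require the files locally.

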
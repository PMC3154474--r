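# ptggdyn

Conformational-ensemble analysis of platinum-GG DNA adducts in R.

Cisplatin and oxaliplatin damage DNA chiefly through a covalent
cross-link between the platinum atom and the N7 positions of two
adjacent guanines. The resulting Pt-GG adduct bends and unwinds the
duplex, and damage-recognition proteins such as HMGB1a read that
distortion. Two kinds of ensembles describe it experimentally and
computationally: small NMR structure families (10-20 refined
conformers) and long MD trajectories (tens of thousands of frames).
`ptggdyn` provides the analysis layer for both, together with a
synthetic duplex-ensemble generator used to validate every stage
against known ground truth.

## What the package computes

* **Helical parameters.** Base reference frames are fitted to the
  standard base geometries by least-squares superposition; intra-pair
  parameters (shear, stretch, stagger in Å; buckle, propeller twist,
  opening in degrees) and base-pair-step parameters (shift, slide,
  rise; tilt, roll, twist) come from a symmetric mid-frame (CEHS-style)
  decomposition. The decomposition is exactly invertible, which the
  synthetic builder exploits: `build_duplex()` followed by
  `compute_param_table()` recovers every parameter to better than
  1e-6. A plane-normal dihedral between the two platinated guanines and
  a two-segment global bend angle complete the geometric vocabulary.
* **Hydrogen-bond classification.** A donor-H-acceptor triple counts as
  a hydrogen bond when the donor-acceptor distance is ≤ 3.5 Å and the
  D-H-A angle is ≥ 135° (both cut-offs inclusive). Every frame is
  classified by which platinum-amine contacts it forms — the
  3'-guanine O6 contact (`G7-O6`), the 3'-flanking thymine O4 contact
  (`T8-O4`), both, or none — reproducing the structure of published
  per-class frequency tables, and occupancies aggregate over all
  classes containing a bond.
* **Ensemble comparison.** Welch-form Z-scores,
  `Z = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)`, for small families;
  the exact two-sample Kolmogorov-Smirnov statistic
  `D = sup_x |F_a(x) - F_b(x)|` and its significance-normalized ratio
  `D / (c(α) sqrt((n_a+n_b)/(n_a n_b)))` for large ensembles; heat-map
  matrices over all designated parameters; class-conditional histograms
  normalized over the full frame count; per-run equilibration trimming.
* **Superposition.** Kabsch least-squares rotations (reflections
  excluded, optional mass weighting), iterative mean structures, family
  RMSD (the `mean ± sd` spread quoted for NMR families), centroid
  frames, and smoothed RMSD time series.
* **Synthetic ensembles.** `generator_spec()` draws every helical
  parameter from configurable Gaussians around B-form means (twist 36°,
  rise 3.38 Å), optionally applies the Pt-GG distortion signature,
  attaches a platinum-diamine moiety at exact 2.0 Å N7 coordination,
  and plants hydrogen-bond class fractions that the geometric
  classifier verifies frame by frame at generation time.

## Worked example

```r
library(ptggdyn)

# a 500-frame platinated duplex ensemble with hydrogen-bond classes
# planted at the published OX-adduct fractions (None, G-O6, T-O4, both)
built <- plant_hbond_classes(c(0.20, 0.59, 0.06, 0.13),
                             n_frames = 500, seed = 42)

classes <- classify_frames(built$ensemble)
frequency_table(classes, digits = 1)
#>         class count percent
#> 1       G7-O6   292    58.4
#> 2       T8-O4    35     7.0
#> 3 T8-O4+G7-O6    75    15.0
#> 4        None    98    19.6

aggregate_bond_occupancy(frequency_table(classes, digits = 1), "G7-O6")
#> [1] 73.4

params <- compute_param_table(built$ensemble)
round(colMeans(params[, c("step_6_7_roll", "step_6_7_twist",
                          "gg_dihedral")]), 1)
#>  step_6_7_roll step_6_7_twist    gg_dihedral
#>           26.1           26.0           25.9

control <- sample_param_tables(generator_spec(n_frames = 500, seed = 7))
zmat <- comparison_matrix(
  list(ptgg = compute_param_table(built$ensemble, gg_dihedral = FALSE),
       undamaged = control), statistic = "z")
head(zmat[order(-abs(zmat[, 1])), , drop = FALSE], 3)
#>                ptgg vs undamaged
#> step_6_7_roll          109.07606
#> step_6_7_twist         -40.44418
#> step_6_7_slide         -15.17121
```

The frequency table recovers the planted class fractions to within
sampling noise (58.4 / 7.0 / 15.0 / 19.6 against planted
60.2 / 6.1 / 13.3 / 20.4 after normalization), the G7-O6 occupancy is
the sum of the two classes containing that bond, the platinated step
shows the planted cross-link signature (roll and twist near 26°, a
matching guanine-guanine plane dihedral), and the Z-score heat map
against an undamaged control is dominated by exactly those central-step
parameters.

## Analysis workflow

`analysis/` holds the numbered drivers that reproduce the study-shaped
workflow end to end on synthetic stand-ins (generated ensembles are
cached under `scratch/`, tables land under `results/`):

```sh
Rscript analysis/01_simulate.R            # build MD-like runs + NMR-like families
Rscript analysis/02_hbond_classification.R
Rscript analysis/03_helical_parameters.R
Rscript analysis/04_comparison.R
Rscript analysis/05_superposition.R
```

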
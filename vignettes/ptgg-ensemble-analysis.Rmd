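---
title: "Methods: conformational ensemble analysis of Pt-GG DNA adducts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational ensemble analysis of Pt-GG DNA adducts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptggdyn)
```

`ptggdyn` analyses conformational ensembles of B-DNA duplexes carrying
a platinum cross-link on two adjacent guanines: helical parameters,
geometric hydrogen-bond classification of the platinum-amine contacts,
distribution comparisons between ensembles and between hydrogen-bond
classes, and superposition statistics. This vignette documents the
models and conventions, the tunable parameters, the synthetic-data
generator that stands in for MD trajectories and NMR families, the
numerical choices, and the limitations.

## The duplex and its numbering

The reference system is a 12-mer duplex with a TGGT core,
5'-CCTCTGGTCTCC-3' paired to 5'-GGAGACCAGAGG-3', with platinated
guanines at positions 6 and 7. Residues are numbered continuously:
strand I is 1-12, strand II 13-24, and residue *i* pairs with residue
25-*i*, so the central pairs are 5-20, 6-19, 7-18 and 8-17. All column
labels (`pair_7_18_propeller`, `step_6_7_roll`, ...) use this
numbering. Positions 2-4 of strand I are unconstrained by any labelled
analysis; the shipped sequence fixes them to C, T, C as one concrete
choice.

## Helical parameters

Each base receives an orthonormal reference frame by least-squares
(Kabsch) superposition of a standard planar base geometry onto the
observed ring atoms (nine atoms for purines, six for pyrimidines); the
fit residual is reported and a missing ring atom is an error. The
standard geometries are embedded as program data with the frame origin
between the Watson-Crick edges, x toward the major groove, y along the
base long axis, and z the base normal.

Pair and step parameters come from one symmetric **mid-frame
decomposition** applied at two levels:

1. the complementary base frame is flipped 180° about its x axis, and
   the decomposition of (flipped complement, Watson base) gives shear,
   stretch, stagger (Å) and buckle, propeller, opening (degrees), plus
   the pair mid-frame;
2. the decomposition of two consecutive pair mid-frames gives shift,
   slide, rise (Å) and tilt, roll, twist (degrees).

The decomposition rotates both frames by half the bending angle about
their common hinge (the cross product of the z axes) so the z axes
coincide, reads twist as the residual rotation about the shared z,
splits the bend into tilt/roll components by the phase between hinge
and mid-frame y, and expresses the origin displacement in mid-frame
coordinates. This is the standard-reference-frame (CEHS-style)
convention, **not** the curvilinear-axis algorithm of the older CURVES
program: values for B-form DNA are comparable but not bit-identical.
The convention was chosen because it is fully published and exactly
invertible — the inverse is the synthetic builder, and the round-trip
(`build_duplex` then `compute_param_table`) is validated to ≤ 1e-6
over the full tested range (|angles| ≤ 60°, |translations| ≤ 3 Å),
which pins down every sign and decomposition-order choice by test
rather than by prose.

Two coarser descriptors complete the set. The **GG plane dihedral** is
the angle in [0, 90°] between the least-squares base-plane normals of
the two platinated guanines; a signed variant was rejected for
simplicity, since every use here is a magnitude. The **bend angle** is
the angle between best-fit axes of the first and last four base pairs,
each axis blending the principal direction of the pair origins with
the mean pair normal; it is a two-segment estimate, not a curvilinear
global axis.

By default, tables cover the central four pairs and the three steps
they span. Terminal pairs are computable but excluded from default
designations, since fraying ends dominate their variance.

## Hydrogen-bond detection and classification

A donor-hydrogen-acceptor triple is a hydrogen bond when the
donor-acceptor distance is at most 3.5 Å **and** the donor-H-acceptor
angle is at least 135°. Both cut-offs are inclusive; the boundary
behaviour is codified by tests (3.5 Å/135.0° detected, 3.6 Å/134.9°
not). Donors are the base N-H groups and, when a platinum moiety is
present, its amine N-H hydrogens; acceptors are the base lone-pair
sites (G O6/N7/N3, A N7/N1/N3, T O4/O2, C O2/N3). Base-base
(Watson-Crick) bonds are detected but filtered out of classification,
which considers only platinum-amine contacts: each frame is labelled
`None`, `G7-O6`, `T8-O4`, or the combination `T8-O4+G7-O6`. The
combination is its own class, so no priority ordering is needed, and a
bond's *occupancy* is the summed frequency of every class containing
it. Structures without explicit polar hydrogens get idealized ones
(N-H 1.01 Å, in-plane sp2 placement for base amines and imino groups).

## Ensemble comparison statistics

For small families (n ≈ 14) the per-parameter comparison is a
Welch-form Z-score, (mean_a − mean_b)/sqrt(var_a/n_a + var_b/n_b).
The exact standardization behind the published heat maps is not fully
specified in the source material, so the Welch form — appropriate for
small samples with unequal variances — is isolated behind one function
where a pooled-variance alternative would be a one-line swap.

For large ensembles the comparison is the two-sample KS statistic,
computed exactly by merging the sorted samples (ties handled by
evaluating after each distinct value), and reported as a **KS ratio**:
D divided by the asymptotic critical value
c(α)·sqrt((n_a+n_b)/(n_a·n_b)), c(α) = sqrt(−ln(α/2)/2), with
α = 0.05 by default. A ratio of 1 is the significance boundary. This
normalization is an interpretation (the published description of the
ratio is not available in detail); it is flagged as such and kept
behind its own function. No multiple-testing correction is applied
across heat-map cells, matching the raw-heat-map reporting style; a
Bonferroni threshold for a 42-cell matrix would be α/42.

Class-conditional histograms share Freedman-Diaconis bin edges
computed on the pooled sample and are normalized **over the full frame
count**, so the area under each class's curve equals that class's
frequency — low-abundance classes correctly appear small.
Equilibration trimming removes the leading burn-in fraction of each
run (default 0.4, i.e. keep the final 60%, mirroring a 6-of-10 ns
convention) and respects a `run` column so concatenated independent
runs are trimmed per run.

## Superposition machinery

Kabsch superposition excludes reflections and accepts per-atom weights
(with unit weights, weighted and unweighted RMSD agree exactly; mass
weighting uses standard atomic masses). The family mean structure is
iterative — superpose all models on the current mean, re-average,
repeat until the mean moves < 1e-6 Å — initialized from model 1 and
deterministic given model order; the published protocol behind family
RMSD values is unstated, and the quoted spread absorbs the difference.
Family RMSD reports per-model RMSD to that converged mean. The
centroid is the member minimizing mean pairwise RMSD (ties to the
lowest index). RMSD time series are smoothed by a centered moving
average with truncated (not reflected) edge windows.

## The synthetic-data generator

The generator is the package's stand-in for the study conditions: MD
trajectories of platinated and undamaged duplexes (five independent
runs per system) and refined NMR families. Its defaults are:

* B-form means (twist 36°, rise 3.38 Å, all else 0) with per-frame,
  per-parameter independent Gaussian draws. Default spreads —
  pair (0.15, 0.12, 0.25 Å, 8°, 8°, 4°), step (0.4, 0.4, 0.25 Å, 3°,
  5°, 5°) — are magnitudes typical of room-temperature duplex MD. An
  optional AR(1) coefficient produces time-series-shaped draws; it is
  off by default because no analysis here depends on autocorrelation.
* the `pt_gg` distortion preset raises the platinated step to roll
  26°, twist 26° and slide −0.3 Å — the qualitative cross-link
  signature (raised roll, unwinding, negative slide). These constants
  are configuration choices of the generator, not measured values.
* with a platinum moiety attached, the spreads of the platinated step,
  its flanking steps and the four central pairs are scaled by 0.5: the
  covalent cross-link rigidifies its neighbourhood, and the reduced
  local flexibility also keeps the N7-N7 separation within
  cross-linkable range for essentially every drawn frame.

The platinum moiety is placed constructively: Pt on the major-groove
bisector of the two guanine N7 atoms at exactly 2.0 Å coordination
distance (when a rare extreme frame draws the N7s too far apart, Pt
falls back to the bisector midpoint with a small outward offset), two
amine nitrogens at 2.05 Å completing a distorted square, and two
explicit hydrogens per amine on the tetrahedral cone about the Pt-N
axis. The two cone hydrogens play the roles of the axial and
equatorial amine hydrogens of a real carrier ligand; ring chemistry of
the oxaliplatin DACH ligand beyond the amine hydrogens is not
modelled.

**Class planting** realizes a requested hydrogen-bond class
deterministically rather than by rejection sampling. Frames planted to
form the flank contact receive the conformational signature that
promotes it — more positive shift at the G7-T8 step and T8-A17
opening, more negative G7-C18 propeller and shear — as class-
conditional mean offsets recorded in the ground truth, which also
gives the class-conditional histograms their planted structure. The
amine placement and hydrogen azimuth are then chosen by a
deterministic search (directions on a polar grid scored by
hydrogen-bonding geometry; azimuths computed from the acceptors' cone
projections), with required bonds enforced under slightly stricter
cut-offs and forbidden bonds under slightly looser ones, so that
coordinate rounding to the PDB grid cannot flip a class. Every
generated frame is re-checked by the actual classifier; an
unrealizable class is a loud generation error, with one deterministic
conformational rescue attempted first. Because planting is verified at
generation, recovery experiments measure pure multinomial sampling
noise, which is the intended property.

The generator emulates: Gaussian helical-parameter fluctuation,
class-conditional conformational signatures, cross-link rigidity and
geometry, and family-versus-trajectory spread. It does **not**
emulate: torsionally realistic backbones (bases carry only C1' and
polar hydrogens; no phosphates or sugars), solvent or counter-ions,
autocorrelated dynamics (unless AR(1) is enabled), anharmonic or
multimodal marginals within a class, or force-field energetics.
Passing recovery tests therefore show that the analysis stack is
correct and well-calibrated on ensembles with known structure — not
that real trajectories satisfy the generator's assumptions.

## Numerical choices

* Near-parallel frame z axes (bending angle below ~1e-9) switch to an
  aligned-frame branch; the hinge is computed from the cross product
  with atan2, which is stable at small angles. Anti-aligned z axes
  (impossible for a sane pair after flipping) are an error.
* Rotations are built by Rodrigues' formula; frames are orthonormal by
  construction and validated to 1e-9 in tests.
* The Kabsch implementation warns on collinear point sets (rank < 2
  cross-covariance) but still returns the SVD solution; planar sets
  (every base) are fine.
* Centroid ties resolve to the lowest index; the iterative mean caps
  at 100 iterations and errors rather than returning an unconverged
  mean.
* Percentages are reported at integer precision by default (matching
  the published tables); internal comparisons use full precision.
* Published integer-percent class rows need not sum to exactly 100;
  planted fractions are normalized when their sum is within 5% of 1
  and rejected otherwise.

## Problem sizes

The shipped analysis scripts and tests run at desk scale: five runs of
400 frames per MD-emulating ensemble (trimmed to 1200 frames per
adduct), 14-model families, 10,000 frames for the class-recovery
experiment, 100 seeds for detection and null-calibration suites, and
10,000 sampled rotations per Kabsch optimality case. These sizes give
the statistical resolution the assertions need (e.g. a ±1.5-point
binomial bound at n = 10,000) while keeping a full run in minutes on
one CPU.

## Known limitations

* Helical parameters follow the mid-frame convention; comparisons with
  curvilinear-axis outputs of legacy software are close for B-form DNA
  but not bit-identical, and groove geometry, backbone torsions and
  sugar puckers are out of scope.
* The bend angle is a two-segment estimate and under-reads strongly
  S-shaped deformations.
* The Z-score and KS-ratio normalizations are documented
  interpretations of under-specified published statistics; both are
  isolated behind single functions.
* The platinum moiety is geometric, not chemical: coordination
  distances and amine cones are idealized, and no energetics constrain
  the hydrogens beyond the planted class.
* mmCIF input, RNA, triplexes and protein chains are unsupported;
  input is standard multi-model PDB with either two chains or
  continuous residue numbering.
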
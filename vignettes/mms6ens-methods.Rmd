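---
title: "Methods: coarse-grained ensembles and assay quantification for the Mms6 C-terminal region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained ensembles and assay quantification for the Mms6 C-terminal region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and intent

The acidic C-terminal region of the magnetosome protein Mms6 (residues
38–59, `MKSRDIESAQSDEEVELRDALA`) is intrinsically disordered and binds
ferric ions. `mms6ens` re-implements, at desk scale, the analysis stages
of a mutational study of this region: a conformational-ensemble sampler
for the wild type and its alanine variants, ensemble descriptors and
mutant-versus-wild-type comparison metrics, and the quantification
arithmetic for a luminol-based ferric-binding plate assay and a
nanoplasmonic sensing (LSPR) experiment.

Two things this package deliberately is **not**: it is not an all-atom
force field (the original ensembles were produced with an implicit-solvent
all-atom Monte Carlo engine that cannot be bundled here), and it contains
no measured instrument data (the assay stages operate on synthetic
generators whose structure mirrors the published qualitative findings).
Quantitative reproduction of the original per-panel comparison values is
therefore explicitly *not* claimed; what is preserved is every downstream
definition, so that the same analyses run end-to-end on ensembles and
traces of the same shape.

## The coarse-grained chain model

Each residue carries backbone N, CA, C atoms placed with fixed ideal bond
lengths (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å), fixed ideal angles and
trans peptide bonds (ω = 180°), plus one side-chain bead at fixed geometry
off CA. Two virtual cap atoms (written as ACE/NME in PDB output) make φ of
the first and ψ of the last residue well-defined, so dihedral extraction
inverts construction exactly (tested to 10⁻⁴ degrees). Chirality follows
the IUPAC convention; an ideal α-helix built at (φ, ψ) = (−57°, −47°) is
right-handed with CA(i)–CA(i+3) ≈ 5.2 Å (validated during development
against an independent structural-biology library).

### Energy function

Energies are in kT at 298 K, with three switchable terms:

* **Sterics** — soft-core quartic overlap penalty
  `k_rep (1 − (d/σ)²)²` for `d < σ = r_i + r_j`, `k_rep = 100 kT`,
  between CA and side-chain beads at least 3 bonds apart on the virtual
  bond graph (CA–CA for |i−j| ≥ 3, CA–SB for |i−j| ≥ 2, SB–SB for
  |i−j| ≥ 1). Overlapping chains have large-finite, never infinite,
  energy, keeping Metropolis well-defined. Restricting sterics to
  CA + side beads (rather than all four atoms) is a desk-scale
  performance choice; the CA radius (1.9 Å) effectively covers the
  backbone.
* **Electrostatics** — Debye–Hückel between charged side-chain beads,
  `E = l_B q_i q_j exp(−d/λ_D)/d` with Bjerrum length 7.13 Å and
  `λ_D = 3.04/√I` Å (≈ 21.5 Å at the study's 20 mM 1:1 salt). Side-chain
  formal charges at pH 7.4: D, E → −1; K, R → +1; all others (including
  His, which does not occur in the region) 0. The fragment termini are
  treated as capped and neutral because the region is internal to the
  full-length protein — uncapped termini would add charges absent from
  the original system.
* **Helix bias** — `−log w_i` for each residue whose (φ, ψ) falls in the
  helical basin, with `w_i` the residue's helix propensity weight.

An optional Gaussian attractive test term between CA pairs (off by
default) exists solely to verify compaction behaviour (scaling-map ratios
< 1, reduced Rg) against the excluded-volume reference.

### Sampling

The sampling design mirrors the published campaign: 20 independent runs,
30×10⁶ production steps sampled every 20×10³ after 2×10⁶ equilibration
steps (1500 recorded configurations per run, 30 000 per construct), a
56 Å spherical droplet applied to centroid-centred coordinates, 298 K,
20 mM salt. The default **desk preset** divides the step counts by 100
(3×10⁵/2×10⁴/200) while keeping 1500 configurations per run; the
`paper-counts` preset retains the original arithmetic for the count
assertions. One attempted move re-draws a single uniformly chosen
residue's (φ, ψ) from a three-basin Ramachandran mixture — helical
φ ∈ [−100°, −30°], ψ ∈ [−67°, −7°]; extended φ ∈ [−180°, −50°],
ψ ∈ [90°, 180°]; a broad "other" basin for the remainder — choosing the
basin by propensity weight (helix: `w_i`; extended and other: 1) and
uniformly within it.

**Acceptance is plain Metropolis** (`min(1, exp(−ΔE))`) *without* a
Hastings correction for the non-uniform proposal. This is a considered
choice, not an oversight: with all interactions off the chain must reduce
exactly to independent basin-weighted sampling (the package tests this
against a no-Markov-chain oracle through `⟨R_ee²⟩`), which a Hastings
correction would destroy (it would make the zero-energy stationary law
uniform over the Ramachandran square). The price is that the stationary
distribution is the proposal tilted by `exp(−E)` rather than a pure
Boltzmann law — acceptable for a stand-in sampler whose role is to
generate disordered ensembles with controllable helicity, sterics and
electrostatics, and it is documented as a non-equivalence with the
original engine. Droplet-violating proposals are rejected at proposal
time; zero acceptance across an entire equilibration aborts loudly.

Randomness is a counter-based generator (splitmix64-seeded xoshiro256**)
with one substream per (base seed, run id): ensembles are bit-for-bit
reproducible for identical `(sequence, params, base_seed)` on any
platform, and never touch R's global RNG.

### Helix propensity defaults and the calibration band

Per-residue helix weights are a residue-type table (Ala highest, Gly/Pro
lowest, loosely ordered like experimental helix propensity scales)
multiplied by a single global scale. The scale (1.55) was calibrated
**once**, as the acceptance criteria prescribe, so that the wild-type
desk-scale ensemble's mean C-terminal helicity (residues 50–59, the
configurable operationalisation of "C-terminal region") falls within the
study's printed 10–15% transient-helicity band; after freezing, measured
values are 13.7–14.0% across seeds. No other generator parameter was
tuned against any test outcome.

## Descriptors

* **Radius of gyration** — mass-uniform RMS distance of all real beads
  from their centroid. Computed two independent ways (definition vs the
  pairwise-distance identity / gyration-tensor moments) in package and
  tests; they agree to 10⁻⁸.
* **Asphericity** — `δ = 1 − 3(λ₁λ₂ + λ₂λ₃ + λ₃λ₁)/(λ₁+λ₂+λ₃)²` from the
  gyration-tensor eigenvalues; 0 for spherical symmetry, 1 for collinear
  beads; an all-coincident cloud is defined as 0. The vectorised batch
  route uses the eigenvalue-free moment identity
  `Σλᵢλⱼ = (tr² − tr S²)/2`.
* **Transient helicity** — residue i is helical in a conformation iff its
  (φ, ψ) lies in the helical basin *and* it belongs to a run of ≥ 4
  consecutive such residues (one helical turn; the threshold is a recorded
  choice, configurable). `f_i` is the fraction of conformations where i is
  helical; being dihedral-based it is exactly invariant under rigid-body
  motion. Both the per-residue profile and the region average are
  reported, since the original statement of 10–15% does not say which is
  meant.
* **Distance and scaling maps** — mean CA–CA distance maps (CA-only is
  the standard IDR convention; the original atom set is unstated), and
  element-wise ratios against the excluded-volume reference
  (sterics-only, same protocol). The EV self-scaling test requires
  mean |R_ij − 1| < 0.02 for |i−j| ≥ 3 at default ensemble sizes.

## Comparison metrics

* **Local deviation** — `|⟨d_ij⟩_mut − ⟨d_ij⟩_WT|` with scalar summary the
  unweighted mean over pairs |i−j| ≥ 2 (bonded pairs are constants and
  would dilute signal; the map is emitted so alternatives can be
  recomputed). Absolute Å, not relative — the original normalisation is
  unstated and this is recorded.
* **Global deviation** — Hellinger distance between the two normalised 2D
  (Rg, δ) histograms on a shared 30×30 grid spanning the pooled range.
  Hellinger was chosen because the original "deviation between 2D
  distributions" names no distance; it is bounded in [0, 1], symmetric,
  zero iff identical, one for disjoint supports, and robust to binning.
* **Heterogeneity** — over sampled conformation pairs, similarity is the
  Pearson correlation of upper-triangle (|i−j| ≥ 2) instantaneous CA
  distance-map entries mapped to [0, 1] via (s+1)/2, and
  `D = mean(1 − similarity)`. The originally cited heterogeneity measure
  is not printed in the source study; this kernel is a stand-in and is
  flagged as such, preserving the intended reading (larger D = more
  disordered) and the invariances (rigid-body motion, seed-controlled
  pair sampling).
* **Noise floor** — the pipeline always simulates an independent-seed
  wild-type replicate and reports Δ_local(WT, WTrep): every mutant
  deviation should be read relative to this Monte Carlo floor, mirroring
  the original wild-type-baseline logic.
* **Rank report** — variants sorted per metric plus a Spearman
  association between each metric and the binary binding-impairment
  label. The report *states* association; the original conclusion (no
  trend between conformational change and binding impact) is for the
  reader, not an automated verdict.

## Assay quantification

The plate arithmetic follows the published protocol numbers: 1 mg/ml
protein of MW 21.5 kDa mixed 63 µl + 7 µl reagent gives 42 µM; an 8 µl
aliquot holds 0.34 nmol (rounded to 2 decimals for display, unrounded
retained). Replicate statistics are mean ± SEM (sd/√n, n = 3 by default);
significance is a per-sample two-group one-way ANOVA against an explicit
control (`F = t²`), at α = 0.05, with a global k-group ANOVA attached.
The control is a required argument because the original does not state
whether GFP or wild type anchored the test; no multiple-testing
correction is applied by default (mirroring the original), with an
optional Bonferroni flag. Degenerate cases follow explicit conventions:
zero within-group variance with equal means → p = 1, flagged; with
different means → F = ∞, p = 0.

The **synthetic plate generator** draws Gaussian replicates (truncated at
0) around a per-sample mean profile whose ordering encodes the published
qualitative result — GFP negative control lowest; E44A, E50A, EE50AA and
R55A (the binding-impaired set) intermediate; wild type and the
unimpaired variants (D42A, D49A, E51A, E53A, D56A) highest. The printed
figure contains no numeric intensities, so the profile values (5 / ~45 /
~100 arbitrary units, noise sd 8) are free synthetic parameters chosen
once; the round-trip test asserts that the default generator plus the
ANOVA stage reproduce exactly the impaired partition. This is a
generator-contract test, not a claim about the real instrument.

## Nanoplasmonic sensing

Traces are 1 Hz plasmon-peak wavelength series with three labelled
transitions (buffer→protein, water→iron, iron→water); transition times
are explicit inputs, as in the original (switch times were recorded
manually; no "stable peak" detector is implemented). A transition window
spans [t−100 s, t+300 s] (400 samples); the mean over the 100 pre-switch
samples is the baseline subtracted from the window, making windows from
different scenarios overlayable at t = 0 and the operation idempotent.
Post-switch drift is the least-squares slope over the final 200 s; a
slope below −5×10⁻⁴ nm/s labels the window "decaying".

The **synthetic trace generator** encodes the three published contrasts
as scenario behaviour (not as a chemical model of iron speciation):
comparable adsorption shifts for both proteins and none for the
protein-free sensor; a small iron-binding shift for both proteins with
exponential decay for the triple mutant (weaker, reversible binding) and
near-zero for protein-free; and a large post-iron water shift
(iron-oxide precipitation as the pH rises) for wild type and protein-free
that is suppressed for the triple mutant. Amplitudes (2 nm adsorption,
0.5 nm iron, 5 nm water, 0.02 nm read noise) are free synthetic
parameters chosen once at instrument-plausible magnitudes.

## What a green test establishes — and what it does not

The generators emulate the *statistical and qualitative structure* of the
published data: ordering of group means, presence/absence and sign of
shifts, decay at one transition, replicate noise. They do not emulate
absolute luminescence units, real plasmonic response functions, drift or
fouling, nor any force-field-accurate conformational preferences. A green
acceptance suite therefore establishes that the package's definitions,
arithmetic and statistics are correct and reproducible, and that the
sampler's stated world is calibrated to the printed helicity band — not
that the physical conclusions are independently re-derived.

## Numerical choices and degenerate inputs

* Tolerances: dihedral round trip 10⁻⁴ deg; dual-route descriptors 10⁻⁸;
  PDB coordinates 10⁻³ Å (format precision); EV self-scaling 0.02.
* Ties/degeneracies: asphericity of a point cloud with zero trace → 0;
  Hellinger on histograms renormalises and clamps at [0, 1]; rank
  association on constant metrics → NA with a `degenerate` flag; SEM of a
  single replicate → NA with a warning; unbalanced plates allowed but
  flagged.
* All randomness flows from explicit seeds (`base_seed` in the sampler
  and pipeline, `seed` arguments in generators and heterogeneity); the
  package never draws from an unseeded source, and generator helpers
  restore R's RNG state.
* Residue numbering is absolute (38–59) in every user-facing structure;
  conversion to internal 1-based indices happens at one boundary layer.

## Known limitations

* The sampler's stationary distribution is proposal-tilted rather than
  Boltzmann (see above); its ensembles are a stand-in, and comparison
  values across variants are meaningful only within this model.
* Side chains are single beads: no rotamers, no hydrogen-bond-based
  secondary structure (helicity is dihedral-basin based, not DSSP-like).
* Ferric/ferrous ions are absent from the simulations, as in the original
  study; the triple mutant's low aqueous stability is not modelled.
* Desk-scale step counts shorten decorrelation relative to the original
  design; the per-run interval (200 moves ≈ 9 re-draws per residue) was
  checked to decorrelate this 22-mer's basin occupancies, but users
  scaling to longer chains should re-examine it.
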
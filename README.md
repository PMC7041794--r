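# mms6ens

Desk-scale conformational-ensemble and iron-binding-assay analysis for the
acidic C-terminal region of **Mms6**, the magnetosome membrane protein of
*Magnetospirillum magneticum* AMB-1 that nucleates magnetite nanoparticle
formation. The C-terminal region (residues 38–59,
`MKSRDIESAQSDEEVELRDALA`) is intrinsically disordered and binds ferric
ions; alanine-substitution variants of its charged residues probe which
positions matter for binding and whether mutations act through
conformational change or through the loss of specific contacts.

The package is aimed at structural bioinformaticians and protein
biochemists who want a reproducible, fully synthetic re-implementation of
that analysis chain:

* **Variant registry** — the 22-residue wild type, the single mutants
  (D42A, E44A, D49A, E50A, E51A, E53A, R55A, D56A), the double mutant
  EE50AA and the triple mutant MM (EER44,50,55AAA), with per-residue
  charge/propensity annotations and FASTA I/O.
* **Ensemble sampler** — a coarse-grained torsional Metropolis Monte
  Carlo chain (backbone N/CA/C + one side-chain bead; Ramachandran-basin
  proposals; soft sterics, Debye–Hückel electrostatics, helix bias)
  following the published sampling design: 20 runs × 1500 recorded
  configurations = 30 000 conformations per construct, 56 Å droplet,
  298 K, 20 mM salt. Includes the excluded-volume reference model.
* **Descriptors** — radius of gyration, gyration-tensor asphericity
  δ = 1 − 3(λ₁λ₂ + λ₂λ₃ + λ₃λ₁)/(λ₁+λ₂+λ₃)², per-residue transient
  helicity f(i) (helical basin + run-of-4 rule), mean CA distance maps
  and scaling maps R(i,j) = ⟨d(i,j)⟩/⟨d(i,j)⟩(EV).
* **Comparison metrics** — local deviation |⟨d(i,j)⟩(mut) − ⟨d(i,j)⟩(WT)|,
  Hellinger distance between (Rg, δ) 2D distributions, conformational
  heterogeneity D from distance-map correlations, plus a cross-variant
  rank/association report and a wild-type-replicate noise floor.
* **Assay stages** — luminol ferric-binding plate arithmetic
  (concentration/aliquot conversions, mean ± SEM, one-way ANOVA vs a
  control) and nanoplasmonic (LSPR) trace processing (400 s transition
  windows, 100 s pre-switch baseline, post-switch drift), each with a
  seeded synthetic generator.
* **Pipeline/CLI** — JSON config, staged subcommands
  (`simulate descriptors compare assay nps run-all`), multi-model
  PDB/XYZ trajectories, CSV/JSON reports, manifest with seeds and
  hashes; byte-reproducible given (config, seed).

See `vignettes/mms6ens-methods.Rmd` for the model, its assumptions, the
calibration of the helicity band, and what the synthetic generators do
and do not emulate.

## Worked example

```r
library(mms6ens)

wt <- get_variant("WT")
mm <- get_variant("MM")        # EER44,50,55AAA triple mutant
net_charge(wt); net_charge(mm) # -4, -3: the triple mutant is only +1 different

p <- sampler_params("desk", n_runs = 2L, production_steps = 30000,
                    equilibration_steps = 2000, sampling_interval = 100,
                    base_seed = 1203L)   # small demo; defaults give 30,000 confs
wt_ens <- sample_ensemble(wt, p)
descriptor_table(wt_ens)
round(100 * region_helicity(wt_ens), 1) # C-terminal transient helicity, %

mm_ens <- sample_ensemble(mm, p)
compare_variant(mm_ens, wt_ens, n_pairs = 300)

round(molar_concentration(1, 21.5, 63, 7))   # 42 uM after 63+7 ul mixing
round(aliquot_amount(8, 42), 2)              # 0.34 nmol in an 8 ul aliquot

plate <- simulate_plate()                    # synthetic Fig-2c-like plate
res <- anova_vs_control(plate, "WT")
res[res$significant, c("sample", "F", "p")]

nps_features(simulate_nps_trace("Mms6MM"))   # synthetic LSPR sensorgram
```

Output (abridged; exact values, fixed seeds):

```
<peptide_sequence> WT: MKSRDIESAQSDEEVELRDALA (residues 38-59)
<mms6_ensemble> WT: 600 conformations (2 runs), interactions {sterics: on, electrostatics: on, helix_bias: on}
<mms6_descriptors> WT: 600 conformations; mean Rg 10.65 A, mean asphericity 0.489
C-terminal (50-59) helicity: 12.2 %
<mms6_comparison> MM vs WT: delta_local 0.471 A, delta_global 0.441, D(mut) 0.129, D(WT) 0.124
 sample     F        p
    GFP 386.4 3.95e-05
   E44A  69.3 1.14e-03
   E50A  84.4 7.80e-04
 EE50AA 155.6 2.37e-04
   R55A 486.8 2.50e-05
 scenario transition baseline plateau     slope decaying
   Mms6MM    protein      550   1.842  0.001925    FALSE
   Mms6MM       iron      552   0.140 -0.000988     TRUE
   Mms6MM      water      552   0.228  0.000133    FALSE
```

Reading this: the wild-type ensemble shows ~12% transient helicity in the
C-terminal region (the calibrated 10–15% band); the triple mutant's
conformational deviation from wild type is modest while its synthetic
plate/LSPR signatures are strongly binding-impaired — the qualitative
decoupling the study reports. The ANOVA flags exactly the GFP control and
the impaired set {E44A, E50A, EE50AA, R55A}; the `Mms6MM` iron-transition
window is labelled *decaying* (weak, reversible binding) and its
post-iron water shift (0.23 nm) is suppressed relative to wild type
(~5 nm, iron-oxide precipitation).

## Full pipeline

```r
cfg <- pipeline_config(variants = c("WT", "E50A", "MM"), base_seed = 1203L)
run_pipeline(cfg, "run1")    # trajectories/, descriptors/, compare/, assay/, nps/, manifest.json
```

or, staged, from a shell:

```sh
Rscript inst/cli/mms6_pipeline.R simulate    --config cfg.json --outdir run1
Rscript inst/cli/mms6_pipeline.R descriptors --config cfg.json --outdir run1
Rscript inst/cli/mms6_pipeline.R run-all     --config cfg.json --outdir run2 --seed 7
```

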
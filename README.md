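# confhet

Side-chain conformational heterogeneity in multiconformer crystal
structures, and how ligand binding redistributes it.

## What this package is for

Crystallographic models that carry alternative side-chain conformations
(altlocs) with occupancies and B-factors encode two kinds of disorder:
anharmonic jumps between rotamer wells, and harmonic wobble within a well.
`confhet` is an R toolkit for structural biologists who want to quantify
that disorder per residue and compare matched ligand-free (apo) and
ligand-bound (holo) structures of the same protein: which binding-site
residues rigidify when a ligand binds, and where in the protein the
flexibility goes instead.

The core quantity is a crystallographic side-chain order parameter on
[0, 1] (1 = rigid), the product of an angular and a harmonic component:

- angular: S²_ang = (3/2) Σ_ab M²_ab − 1/2 with
  M_ab = Σ_i q_i u_ia u_ib, the occupancy-weighted second moment of the
  χ1-defining Cβ→γ bond orientations across conformers (for two conformers
  this is 1 − 3 q₁q₂ sin²Θ);
- harmonic: S²_ortho = clip(1 − k (B_Cβ + B_H)/r², 0, 1) with
  k = 3/(16π²), r = 1.09 Å, resolution-normalized as
  S²_ortho,norm = clip(S²_ortho · B_Cα/(10 d), 0, 1) at resolution d;
- reported: S²_calc = S²_ortho,norm × S²_ang.

Around it sit occupancy-weighted RMSF and B-factor aggregation, rotamer-well
assignment with a four-way apo/holo change classification, occupancy-
weighted hydrogen-bond counting on altloc-split models, Shrake–Rupley
solvent accessibility with binding-site (≤ 5 Å) / distant (> 10 Å) /
buried–exposed (20% relative ASA) partitioning, apo/holo pair matching and
quality control, cohort statistics (matched controls, residual regression,
bootstrap slope comparison, rank tests, quartile contrasts, clustering),
and a synthetic multiconformer-structure generator with planted ground
truth that makes the whole pipeline testable without any downloads.

## Worked example

Build one synthetic apo/holo pair with a known planted effect (+0.03 mean
order-parameter change in the binding site, +0.015 in distant buried
residues) and run the per-pair pipeline:

```r
library(confhet)
spec <- cohort_spec(n_pairs = 1, seed = 42)
pair <- build_pair(spec, "demo", x_p = 0.03, d_p = 0.015,
                   resolution = 1.6, category = "distinct")
res <- run_pair(pair$apo, pair$holo, ligand_id = "LIG",
                config = pipeline_config(sasa_points = 320))
print(res$summary, digits = 3)
#>               pair_id mean_delta_s2_bs mean_delta_s2_distant_buried
#> 1 demo_holo__demo_apo             0.03                        0.015
#>   mean_delta_s2_distant_all residual_buried residual_all n_binding_site
#> 1                    0.0048          -0.015      -0.0252              3
#>   n_distant_buried hbond_delta
#> 1                8           0
```

The measured binding-site mean Δorder parameter (holo − apo) is exactly the
planted +0.03 and the distant-buried mean exactly +0.015, because planted
effects enter through occupancy shifts whose effect on the order parameter
is known in closed form. `residual_buried` (= 0.015 − 0.03) is the pair's
residual: distant buried residues gained less rigidity than the binding
site. Per-residue rows carry the rotamer classification:

```r
res$deltas[res$deltas$environment == "binding_site",
           c("residue", "aa", "delta_s2", "rotamer_category")]
#>   residue  aa  delta_s2 rotamer_category
#> 4     A:4 SER  4.50e-02        no_change
#> 5     A:5 SER  4.50e-02        no_change
#> 6     A:6 SER -2.22e-16         distinct
```

Residues 4 and 5 absorb the planted rigidification (their occupancies
shifted from 0.75/0.25 towards the major conformer); residue 6 changed
rotamer well (p → m) with no order-parameter change. `run_cohort()`
aggregates many such results into medians, matched-control contrasts, the
residual regression and category fractions; `read_pdb()`/`write_pdb()`
connect the same pipeline to multiconformer PDB files on disk.

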
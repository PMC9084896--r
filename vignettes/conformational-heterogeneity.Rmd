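---
title: "Quantifying side-chain conformational heterogeneity in multiconformer crystal structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying side-chain conformational heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confhet)
```

## The problem

X-ray crystallography averages over very many copies of a protein, in time
and across the lattice. A multiconformer model represents that average
explicitly: side chains may carry several alternative conformations
(altlocs), each with a fractional occupancy and its own B-factors. Two kinds
of disorder coexist in such a model: *anharmonic* disorder — jumps between
discrete rotameric wells, visible as distinct altloc conformers — and
*harmonic* disorder — small wobbles within a well, absorbed by the
B-factors. `confhet` quantifies both per residue, and compares matched pairs
of ligand-free (apo) and ligand-bound (holo) structures of the same protein
to ask how ligand binding redistributes side-chain flexibility.

## The order-parameter model

For every residue except glycine and proline the package computes a
crystallographic side-chain order parameter on the scale 0 (fully flexible)
to 1 (fully rigid), built from two components.

**Angular component.** The orientation of the bond set by the first
side-chain torsion (the Cβ→γ heavy-atom bond, whose direction χ1 controls)
is collected across conformers with occupancy weights
$q_i$. With $M_{ab} = \sum_i q_i\, u_{ia} u_{ib}$ the second-moment tensor of
the unit bond vectors,

$$S^2_{\mathrm{ang}} = \tfrac{3}{2} \sum_{a,b} M_{ab}^2 - \tfrac{1}{2}.$$

For two conformers this reduces to the closed form
$1 - 3 q_1 q_2 \sin^2\Theta$, where $\Theta$ is the angle between the two
bond directions; with ideal tetrahedral geometry a 120° χ1 jump gives
$\cos\Theta = -\tfrac13$ and, at equal occupancy, $S^2_{\mathrm{ang}} =
\tfrac13$. These identities serve as exact oracles in the test suite.

**Harmonic component.** A small-wobble model converts the isotropic
B-factors of Cβ and its riding hydrogen into an order parameter,

$$S^2_{\mathrm{ortho}} = \mathrm{clip}\!\left(1 - \frac{k\,(B_{C\beta} +
B_H)}{r^2},\; 0,\; 1\right), \qquad k = \frac{3}{16\pi^2},\; r = 1.09\,\text{Å}.$$

When explicit hydrogens are absent, $B_H = 1.2\,B_{C\beta}$ (the riding-
hydrogen convention). The prefactor is a configuration default rather than
gospel; all cohort-level results are *differences* between matched
structures, which are insensitive to a global monotone recalibration of this
component.

**Resolution normalization.** B-factors inflate as resolution degrades, so
the harmonic component is placed on a common scale,

$$S^2_{\mathrm{ortho,norm}} = \mathrm{clip}\!\left(S^2_{\mathrm{ortho}}
\cdot \frac{B_{C\alpha}}{c \cdot d},\; 0,\; 1\right),$$

with $d$ the resolution in Å and $c = 10$ by default. The final reported
order parameter is the product
$S^2_{\mathrm{calc}} = S^2_{\mathrm{ortho,norm}} \times S^2_{\mathrm{ang}}$.
Whether $B_{C\alpha}$ is the residue's own Cα B or the structure mean is
genuinely ambiguous; both modes are implemented
(`norm_config(mode = ...)`), with the per-residue reading as default since
it preserves residue-level contrast.

**Calibrating `c`.** `calibrate_normalization()` scans a grid of candidate
constants against a multi-resolution series of the same protein, seeking the
slope closest to 1 and then the smallest RMSE. One subtlety dictated the
design: if *both* arms of the regression are normalized with the candidate
constant, the constant multiplies both variables by the same scalar and
cancels out of the OLS slope exactly — no interior optimum exists. The
package therefore treats the highest-resolution arm as the reference scale
(its order parameters taken at face value, the same rationale that motivates
calibrating on 1.1–2.0 Å structures of a well-behaved protein) and
normalizes only the lower-resolution arm. The degenerate both-arms variant
remains available via `normalize_reference = TRUE` for comparison.

## Companion metrics

* **RMSF** — occupancy-weighted root-mean-square spread of the side-chain
  heavy-atom centroids of the conformers; a purely geometric measure of the
  anharmonic spread.
* **Residue B-factors** — occupancy-weighted means of heavy-atom B over the
  side chain (or all atoms).
* **Conformer counts** — a side chain counts as multiconformer when at
  least one side-chain atom carries an altloc label.
* **Rotamer wells** — χ dihedrals are binned into the canonical wells
  p = [0°, 120°), t = [120°, 240°), m = [240°, 360°), with chemically
  symmetric terminal torsions (Phe/Tyr χ2, Asp χ2, Glu χ3) folded modulo
  180°. This deliberately replaces a full rotamer library: the apo/holo
  change classification needs only well identity, and the bin edges are
  configurable. The absence of an outlier class approximates a very relaxed
  outlier criterion. Matched residues are then classified by set relations
  of their well sets: `no_change` (equal sets), `distinct` (disjoint),
  `remodeled_holo_loss` (wells populated in apo only),
  `remodeled_holo_gain` (wells populated in holo only), and
  `remodeled_both` (extras on both sides — required for exhaustiveness even
  though real cohorts may never produce it).
* **Hydrogen bonds** — geometric criteria on explicit hydrogens
  (H···acceptor < 3.2 Å, D–H···A ≥ 90°), evaluated on every altloc split of
  the structure (each split keeps one altloc plus all atoms with no
  alternative; residues lacking the label contribute their
  highest-occupancy conformer). Bonds are weighted by the lower of the
  donor and acceptor occupancies, deduplicated across splits by the maximum
  weight (a sum variant is available), restricted to side-chain/side-chain
  and side-chain/main-chain contacts, and normalized per binding-site
  residue.
* **Spatial classes** — binding-site residues have any heavy atom within
  5 Å of any ligand heavy atom (inclusive); distant residues are beyond
  10 Å. Solvent exposure uses an in-package Shrake–Rupley implementation
  (probe 1.4 Å, deterministic golden-spiral point lattice, hydrogens
  excluded, highest-occupancy conformer per residue) with the theoretical
  maximum-ASA normalization; relative accessibility ≥ 20% counts as
  exposed. The Shrake–Rupley step is a documented substitution for a
  DSSP-style accessibility computation with the same 20% relative-ASA
  contract.

## Pair construction and quality control

`match_pairs()` applies the pair criteria to a metadata table: identical
space group; identical sequence up to trimming at most five residues from
either terminus of either structure; resolution difference ≤ 0.1 Å (the
boundary is treated inclusively); unit-cell lengths within 1 Å and angles
within 1°; then one apo per holo by minimal resolution difference with a
lexicographic tie-break. `qc_filter()` adds coordinate-level checks —
global Cα RMSD ≤ 1 Å and binding-site Cα RMSD ≤ 0.5 Å under an SVD-based
Kabsch superposition — plus table-driven checks (clashscore ≤ 15, apo/holo
R-free gap ≤ 0.05 absolute, per-structure R-free increase ≤ 0.025, ligand
occupancy ≥ 0.15). Clashscore and R-free are consumed as inputs, never
computed. The "5% difference" R-free rule is read as absolute (0.05), the
more conservative of the two readings.

## Cohort statistics

Per-pair residue deltas always carry the holo-minus-apo sign. The central
spatial statistic is the **residual regression**: for each pair, the
residual (mean Δ order parameter of distant buried residues minus the mean
over binding-site residues) is regressed on the binding-site mean. A
negative slope means proteins that rigidify their binding site show a
*relative* flexibility gain far away. The x-variable reading (per-pair mean
binding-site Δ) was genuinely open; it is adopted because the residual is
defined against the same quantity. Slope differences between cohorts are
assessed by independent pair-level bootstrap resampling and a normal z
statistic. Matched controls re-draw, for every binding-site residue, a
non-binding-site residue of the same amino-acid type and exposure class
(without replacement, 100 draws by default, mean reported). Paired deltas
use the Wilcoxon signed-rank test and group contrasts the Mann–Whitney U
test, both two-sided with midranks, normal approximation and continuity
correction so ties and zeros are handled; ligand-descriptor quartile
comparisons (lowest versus highest ⌊n/4⌋ by the descriptor) are
Bonferroni-corrected at α/10 = 0.005. Residue-by-pair delta matrices are
ordered by average-linkage hierarchical clustering on Euclidean distances
for clustermap rendering.

## The synthetic cohort and what it does (not) show

`build_cohort()` generates matched apo/holo pairs with fully known ground
truth. Chains are idealized poly-Ser segments (with Val/Leu decorations)
laid out at 3.8 Å Cα spacing with a small alternating lateral offset (a
perfectly straight trace would make superposition ill-posed); side chains
are built from ideal bond lengths and tetrahedral angles so the realized χ1
equals the requested angle to machine precision. A rigid 10-carbon ring
ligand sits above three designated residues so that exactly they fall
within 5 Å for any χ1; occluding carbon shells bury a designated distant
stretch (shell groups are small and excluded from ligand classification).
Flexible residues are two-conformer χ1 = 60°/180° side chains at occupancy
0.75/0.25.

Effects are planted **through occupancy shifts only**: the target change in
$S^2_{\mathrm{calc}}$ is converted analytically into a major-conformer
occupancy via the two-site closed form, which leaves every atom's
coordinates identical between apo and holo. Distances, burial and rotamer
wells are therefore exactly shared, and the pipeline must recover the
planted per-pair means to numerical precision. Generator defaults mirror
the headline study conditions: per-pair binding-site mean Δ drawn from
N(0.03, 0.012²); distant buried residues follow the generative residual
slope −0.44 with residual noise SD 0.0055 (these two spreads give a
realistic r² near 0.5); resolutions uniform on 1.2–1.9 Å with
$B_{C\alpha} = 8d$ so the normalization factor is 0.8; side-chain B 14 Å²;
11% of pairs keep all binding-site rotamer sets ("pre-organized"), the rest
flip one single-conformer binding-site rotamer; one residue outside the
analysed regions cycles through the four named rotamer-change categories.
Apo and holo share the resolution within a pair, so the planted deltas are
not distorted by differing normalization factors.

What passing these tests shows: the metric definitions, the spatial
partitioning, the classification logic and the cohort statistics are
implemented correctly, end to end, at realistic effect sizes. What they do
not show: robustness to real crystallographic noise — refinement bias,
occupancy/B-factor degeneracy, missing atoms, lattice contacts, water
networks — none of which the generator emulates. Real-data headline numbers
(pair counts, exact category percentages, printed p-values) derive from a
PDB-scale cohort and are out of reach at desk scale; the package instead
demonstrates property-based correctness and parameter recovery.

## Numerical choices and degenerate inputs

* Order parameters are clipped to [0, 1]; `s2_calc` equals the product of
  its factors to 1e-12 by construction.
* Boundary semantics are inclusive with a 1e-9 tolerance wherever the
  source rules say "within": 5 Å binding site, 0.1 Å resolution, 20%
  exposure; the hydrogen-bond distance is strictly below 3.2 Å.
* Glycine and proline are excluded from order parameters; alanine (no χ1)
  reports $S^2_{\mathrm{ang}} = 1$ so its harmonic component remains
  usable. Residues missing χ1 atoms are flagged not-computable rather than
  erroring.
* Blank-altloc atoms are shared by all conformers of their residue; the
  conformer occupancy is authoritative where the two disagree.
* Multi-model files: only the first model is read, with a warning.
* Kabsch superposition refuses fewer than three points and collinear sets;
  the returned rotation is always proper.
* Ties: altloc fallback in splitting picks the highest-occupancy conformer,
  then the lexicographically smallest label; calibration ties resolve to
  the smallest constant; quartile groups are the ⌊n/4⌋ extreme
  observations.
* All randomness (control draws, bootstrap) flows through R's session RNG;
  seed it once for full reproducibility. Cohort generation is deterministic
  given the spec seed.

## Problem sizes

The shipped tests and the acceptance script use 30-residue chains, cohorts
of 200 pairs (plus a 100-pair control), 240–960 sphere points for
accessibility, 500–1000 bootstrap replicates and 1000–2000 null replicates
for test calibration. These sizes were chosen so the full suite exercises
every stage at statistically meaningful scale on a single CPU.

## Limitations

mmCIF input, anisotropic displacement tensors, water-mediated hydrogen
bonds, covalent-ligand handling beyond a code list, rotamer-library
probabilities and any re-refinement or multiconformer rebuilding are out of
scope; descriptors of real ligands are consumed from a table rather than
computed. The normalized ligand B-factor is reported as the plain ratio to
the mean Cα B — published quartile boundaries on other scales are not
numerically comparable to it.
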
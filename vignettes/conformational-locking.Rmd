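---
title: "Quantifying conformational locking from trajectory ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conformational locking from trajectory ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conflock)
```

## The scientific question

Ligand-sensing proteins such as the leucine sensor Sestrin2 (SESN2) are
intrinsically flexible in their unbound (apo) state: they wander among many
metastable conformations, which is thought to be why the apo protein resists
crystallization. Binding of the right ligand can collapse this heterogeneous
ensemble into a handful of stable, signalling-competent conformations —
"conformational locking". conflock quantifies that collapse from molecular
dynamics (MD) trajectory ensembles, using the conformational state census as
its central readout, and surrounds it with the standard supporting analyses:
stability metrics, correlated-motion networks, ligand-contact persistence,
and replicate-level binding-energy statistics.

## The core model: PCA + density-based state census + free-energy landscape

Given a set of replicate trajectories for one system, concatenated with
`concatenate_ensembles()`:

1. **Alignment.** All frames are superposed (Kabsch) on the Calpha atoms
   with an iterative-mean reference: frames are fitted to a running mean
   structure which is recomputed until it moves by less than 1e-6 Å (at most
   10 iterations). This removes global rigid motion without privileging any
   single frame.
2. **Projection.** The aligned Calpha coordinates form 3N-dimensional
   vectors; their covariance is eigendecomposed (via SVD of the centered
   frame matrix) and frames are projected onto the first two principal
   components (PC1, PC2). Eigenvector signs follow the convention that the
   largest-magnitude component is positive, making projections reproducible.
3. **Clustering.** The PC1/PC2 projection is clustered with DBSCAN
   (own implementation; Euclidean metric in raw score units; a point is core
   when its eps-neighborhood *including itself* holds at least `min_samples`
   points, matching the common library convention). Low-density frames —
   transitions between basins — are labelled noise (-1).
4. **Census.** `census()` counts the stable states, the noise fraction, and
   the state populations; `population_table()` reports the top macrostates
   S1..Sn plus an aggregated "Other".
5. **Free-energy landscape.** Binning the projection on an equal-width 2-D
   grid gives occupancy probabilities P, converted by Boltzmann inversion to
   dG = -kB T ln(P / Pmax), kB = 0.0019872 kcal/(mol K), default T = 310 K.
   The modal bin sits at exactly 0 by construction.

`conformational_landscape()` runs steps 1–5 and returns a classed object
with `print`, `summary`, and `plot` methods.

### Calibrating eps from the k-distance graph

`kdistance_eps()` sorts every point's distance to its k-th nearest neighbor
(k = 4 by default, matching `min_samples`) and looks for the elbow of the
curve. The elbow is operationalized as the point of maximum perpendicular
distance to the chord joining the curve's endpoints (the Kneedle criterion),
with both axes normalized to [0, 1]; this makes the selection equivariant
under uniform scaling of the projection. Two degenerate situations are
handled explicitly:

* a flat curve (all k-distances equal) warns and returns the common value;
* a curve with **no separated noise scale** — the k-distance never rises
  well clear (3x) of the candidate elbow — indicates an essentially unimodal
  projection. The chord criterion then lands mid-curve and would shred the
  single dense state into fragments, so the function warns and returns the
  upper end of the curve (the 99.5th percentile) instead. We adopted this
  two-branch rule after observing exactly that failure mode on single-basin
  ensembles; for any ensemble with genuine transition noise the chord branch
  is the one taken.

In multi-system studies, eps should be calibrated once on the most
heterogeneous (apo) system and frozen across systems so censuses are
directly comparable; `run_pipeline()` does this by default (`calibrate_on`),
and a fixed `eps` can be supplied instead (e.g. the published value 1.2 when
reproducing a study's own projections — note that eps lives in projection
score units, so a value tuned to one PCA is not transferable to another).

### Numerical conventions

* Empty FEL bins carry a finite cap (maximum finite dG plus one
  contour-level spacing, dG_max / 100) instead of infinity, keeping grids
  renderable and serializable. With a single occupied bin the spacing
  degenerates, and kB T ln 2 is used.
* DBSCAN expands clusters in index order; border points join the first
  cluster that reaches them. Tests assert only order-invariant quantities
  (noise set and the partition of core points).
* All coordinates are Ångström, times ps, energies kcal/mol. Residue
  numbers are taken verbatim from the input topology (no renumbering), so
  published residue labels (Cys125, Glu451) are addressable directly.

## Supporting analyses

**Stability metrics.** `rmsd_series()` (fit and measurement masks separately
configurable; reference = first frame by default, or an external model for
deviation-from-crystal measurements), `radius_of_gyration()` (mass-weighted
by default), and `rmsf_profile()` (iterative-mean alignment; per-residue
Calpha profiles or per-atom profiles for bound-ligand flexibility). Both
Calpha and backbone masks are supported for RMSD; published figures are
ambiguous between the two conventions, so neither is asserted as canonical.

**Correlated motions.** `dccm()` computes the dynamic cross-correlation
matrix C_ij over Calpha deviations from time-mean positions after alignment,
and `domain_network()` reduces it to signed mean correlations between named
functional domains (`domain_map()`; the C-terminal domain 339–480 and Cys125
are built-in defaults for SESN2, other domain ranges are user-supplied
because no published residue ranges exist for them). Sign is retained so
anti-correlated domain pairs remain visible; `network_report()` applies a
display threshold (default 0.25, a package choice — no published value
exists).

One property worth knowing: global superposition absorbs part of any
*coherent* collective motion into the fitted rigid transform, attenuating
(never flipping) block correlations. The generator's planted-correlation
closed form (below) therefore holds exactly on unaligned frames and
approximately after alignment; the test suite checks both.

**Ligand contacts.** `detect_contacts()` classifies hydrogen bonds
(donor–acceptor heavy-atom distance <= 3.5 Å, plus a >= 120° donor-H-acceptor
angle whenever an explicit hydrogen is attached; with no hydrogens the
distance rule alone applies), hydrophobic contacts (apolar carbon pairs <=
4.5 Å), ionic contacts (opposite formal-charge group centroids <= 4.0 Å) and
water bridges (one water hydrogen-bonded to both partners in the same
frame). Every cutoff is a named argument of `contact_criteria()`: published
interaction diagnostics rarely state their thresholds, so these are declared
standard-practice defaults, not reverse-engineered values.
`interaction_fractions()` reports per-(residue, type) occupancy over frames,
capped at presence (not multiplicity) per frame.

**Energetics.** MM/GBSA component tables are inputs, not computed here.
`summarize_energetics()` gives per-system mean ± sample SD;
`ttest_from_summary()` implements pooled and Welch two-sample tests directly
from summary statistics, because published tables report only mean ± SD over
n = 3 replicates. The pooled test is the default: at n = 3 it reproduces the
published significance pattern for the SESN2–BCAA hierarchy
(`sesn2_mmgbsa()` ships the published summary; leucine vs valine p = 0.034,
leucine vs isoleucine p = 0.155 — recomputed from the rounded table to about
1e-3). No multiple-testing correction is applied: the two comparisons are
planned, and raw p-values are the published convention.

## The synthetic-ensemble generator

`simulate_ensemble()` is a statistical emulator of the features the census
pipeline assumes — not an MD engine. It generates, per replicate:

* a self-avoiding random-coil Calpha chain (3.8 Å bonds);
* K metastable basin centers: per-residue displacements of magnitude Δ
  (`basin_separation`) in basin-specific directions drawn from a fixed 2-D
  latent plane (ring placement with angular jitter and a small out-of-plane
  component). Placing the basin scatter in a plane guarantees the top-2 PC
  projection preserves all pairwise separations; with fully isotropic random
  directions the centers span K-1 dimensions and the 2-D projection
  collapses some pairs for many seeds, which would misrepresent what the
  census can recover. Real proteins concentrate their slow motions in a few
  collective coordinates, so a low-dimensional basin manifold is also the
  physically sensible emulation;
* basin visits with uniform jump targets and state-dependent geometric
  dwell means K·occupancy·`mean_dwell`, which realizes the requested
  stationary occupancies exactly in expectation (memoryless dwell is chosen
  because only occupancies and noise fractions are analyzed, not kinetics;
  `mean_dwell` controls kinetic trapping);
* per switch, `transition_length` interpolated corridor frames labelled -1,
  at uniformly drawn positions along a per-switch randomly bowed in-plane
  arc. Both randomizations matter: fixed interpolation fractions on a shared
  straight corridor pile repeated passages onto a few dense spots that
  DBSCAN picks up as spurious states, the opposite of the low-density
  corridors transitions are meant to populate;
* isotropic Gaussian noise (σ per coordinate) within basins and corridors;
* optional planted correlation blocks: a shared standard-normal latent
  factor times a fixed unit direction added to every residue of a block,
  with amplitude a² = 3σ²ρ/(1-ρ) so the expected inter-block correlation on
  raw frames is exactly ρ (rank-1 planting gives this closed form);
* an optional pseudo-ligand: each declared contact adds one atom that sits
  at ideal geometry (2.9 Å hydrogen bond to a pocket hydroxyl, 4.0 Å
  hydrophobic contact to a pocket Calpha) in a Bernoulli(bound_fraction)
  subset of frames and >= 8 Å away otherwise. Hydrogen-bond pocket residues
  are emitted as serine-like (CA + OG) so heavy-atom donor/acceptor rules
  apply naturally.

Replicate r is seeded with `seed + r`; identical specs are bit-identical.
Ground truth records per-frame basin labels (-1 for transitions), the
realized noise fraction, expected block correlations, and realized contact
fractions.

**What the generator does not emulate:** explicit solvent and hydrogens,
anharmonic basin shapes, gradual (non-interpolated) transition kinetics,
correlated noise between residues beyond the planted blocks, and ligand
dynamics beyond bound/unbound teleportation. Passing the recovery tests
therefore demonstrates that the pipeline measures what it claims on data
satisfying its own assumptions — not that any particular real system meets
those assumptions.

## Validation design and problem sizes

The test suite checks every numerical path against an independent route:
DBSCAN against a brute-force density-reachability oracle (core counting plus
graph components) on random instances; superposition against an exhaustive
rotation-grid oracle; RMSD/Rg/RMSF/DCCM against naive double-loop
summations and closed forms (two equal masses: Rg = d/2; unit-cube corners:
Rg = sqrt(3)/2; 2:1 occupancy: ΔΔG = kB·310·ln 2 = 0.427 kcal/mol); the
summary-statistics t-test against `t.test()` on reconstructed raw
replicates.

End-to-end, the census chain is required to recover planted K ∈
{1, 2, 3, 5, 9} exactly in at least 95% of 20 seeded runs each (Δ = 8σ,
10% target noise), with measured noise within ±0.02 of ground truth. These
runs use 40 residues and 3 × 400 frames — sized so the full validation runs
in about two minutes while keeping every basin visited many times; the same
conditions at larger frame counts only improve separation. The four-system
demo (`make_demo()`) mirrors a study layout of 3 replicates × 4 systems with
decreasing heterogeneity (9/7/3/3 basins, noise targets from 11.5% down to
2.5%, with longer dwell in the locked systems emulating kinetic trapping);
its acceptance check is deliberately directional (ordering of state counts
and noise fractions), since absolute counts depend on the original study's
trajectories.

## Known limitations

* The census operates on a 2-D projection; states separated only in higher
  components are merged, a property inherited from the method being
  reimplemented. The `pc_model` retains the full spectrum so users can check
  how much variance PC1/PC2 capture.
* eps calibration is heuristic; the two-branch elbow rule is robust across
  the regimes tested here but any automatic elbow can be defeated by
  multi-scale cluster structure. A fixed eps can always be supplied.
* Heavy-atom hydrogen-bond detection without explicit hydrogens
  over-counts borderline geometries; with hydrogens present the angular
  term applies.
* The energetics layer treats replicate means as the experimental unit
  (n = 3); per-frame testing would require the original per-frame energies.
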
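# conflock

Quantifying ligand-induced **conformational locking** from molecular
dynamics trajectory ensembles.

Flexible ligand sensors — the motivating system is Sestrin2 (SESN2), the
leucine sensor upstream of mTORC1 — sample many metastable conformations
when unbound. Binding of the right ligand collapses that heterogeneity into
a few stable, signalling-competent states. `conflock` measures this collapse
for computational structural biologists working with replicate MD
simulations: it turns trajectories into a **conformational state census**
(how many stable states, how much time in transitions, how populated the
dominant state) and surrounds that core with the standard supporting
analyses.

## The core quantification

For each system, replicate trajectories are concatenated and

1. frames are Kabsch-superposed on the Cα atoms (iterative-mean reference);
2. the 3N-dimensional Cα coordinates are projected onto their first two
   principal components, PC1/PC2;
3. the projection is clustered with DBSCAN (own implementation), with
   `eps` calibrated at the elbow of the k-distance graph (k = 4, Kneedle
   chord criterion) and `min_samples = 4`; low-density frames are labelled
   noise, i.e. transition states;
4. the census reports `n_states`, `noise_fraction` and state populations;
5. the Gibbs free-energy landscape is reconstructed on the same plane by
   Boltzmann inversion,

   ΔG(bin) = −k_B T ln( P(bin) / P_max ),  k_B = 0.0019872 kcal/(mol·K), T = 310 K.

A strongly locking ligand shows up as: fewer stable states, a smaller noise
(transition) fraction, and a population concentrated in a few macrostates.

Supporting modules: trajectory/topology I/O (multi-model PDB, DCD, XTC) with
an atom-selection mini-language; RMSD / radius-of-gyration / RMSF metrics;
dynamic cross-correlation matrices (DCCM) reduced to domain-level allosteric
networks; protein–ligand interaction fractions (H-bonds, hydrophobic, ionic,
water bridges); pooled/Welch t-tests over per-replicate MM/GBSA tables; and
a seeded synthetic-ensemble generator with planted ground truth that the
test suite uses to validate the whole chain end-to-end.

## Worked example

Generate a three-basin synthetic system (three replicates, 400 frames each,
basin separation 8σ, 10% target transition noise) and fit its landscape:

```r
library(conflock)

spec <- synthetic_spec(n_residues = 40, n_basins = 3, basin_separation = 4,
                       intra_basin_sigma = 0.5, mean_dwell = 18,
                       target_noise_fraction = 0.10, n_replicates = 3,
                       n_frames = 400, seed = 42)
sim  <- simulate_ensemble(spec)
ca   <- which(sim$topology$calpha)
land <- conformational_landscape(sim$ensemble, ca)
summary(land)
#> System: synthetic_concat
#> State census: 3 stable states; 8.9% noise (transitions); 38.2% in largest state
#> Macrostate populations:
#>  state   fraction percent
#>     S1 0.38250000   38.2%
#>     S2 0.30833333   30.8%
#>     S3 0.22000000   22.0%
#>  Other 0.08916667    8.9%
```

The three planted basins are recovered exactly; the 8.9% "Other" fraction is
the generator's transition frames (ground truth 9.5% for this seed), the
low-density corridors DBSCAN classifies as noise. `plot(land)` shows the
labelled PC1/PC2 projection; `plot(land, "fel")` the free-energy surface.

Replicate-level binding-energy statistics, using the packaged published
MM/GBSA summary for the SESN2–BCAA complexes (n = 3 replicates each):

```r
s <- sesn2_mmgbsa()
compare_systems(s, "leucine", "valine")
#> Two-sample t-test (pooled): mean diff -7.28 kcal/mol, t = -3.170, df = 4.00, p = 0.034
mean_difference(s, "leucine", "valine")
#> [1] 7.28
```

Leucine's ~7.3 kcal/mol binding advantage over valine is significant at
n = 3 (p = 0.034), while the ~3.1 kcal/mol advantage over isoleucine is not
(p ≈ 0.155).

A four-system study layout (apo-like, intermediate, two locked-like systems;
3 replicates each) is available as `make_demo()`, and `run_pipeline()` runs
every stage over all systems with eps frozen from the apo-like calibration:

```r
demo   <- make_demo(seed = 11)
report <- run_pipeline(demo$config)
census_table(report)
#>              system n_states pct_noise pct_largest error
#> 1          apo_like        9  7.916667    14.25000
#> 2 intermediate_like        7  7.833333    19.41667
#> 3     locked_like_a        3  4.750000    33.83333
#> 4     locked_like_b        3  2.416667    37.50000
```

The locked-like systems collapse to 3 states with ~2–5% transition noise
while the apo-like system stays heterogeneous — the conformational-locking
signature.

## Selection mini-language

`select_atoms(topology, expr)` supports the role keywords `calpha`,
`backbone`, `ligand`, `water`, `protein`, `all`, residue ranges
(`resid 339-480`, `resid 125, 451`), and `and` / `or` / `not` with
parentheses. `calpha` and `backbone` exclude ligand and water atoms.

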
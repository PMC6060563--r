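# spinemorph

Quantitative morphology of dendritic spines from 3D triangle meshes.

Dendritic spines — the micrometre-scale protrusions that receive most
excitatory synapses — are routinely reconstructed from confocal stacks as
individual surface meshes, one per spine, with a manually marked
*insertion point* where the spine emerges from its dendritic shaft.
`spinemorph` implements the full analysis chain for such data:

1. **Repair** — fragmented meshes are rejoined by voxel-domain
   morphological closing (spherical structuring element, escalating
   radius, bridge-only retention) and detached spines are reattached by
   growing the missing base slice by slice (each gap slice is the
   2D-Gaussian-blurred, thresholded copy of the slice above), followed by
   curvature-flow smoothing and a volume/components quality gate.
2. **Descriptor** — each spine is summarized by 54 features built from
   the geodesic distance field µ from the insertion point: the field is
   split into K = 7 equal intervals `r_i = (i·α/7, (i+1)·α/7]` (α = max
   µ), the six boundary level sets are fitted by ellipses in their PCA
   planes (adjacent regions share their boundary ellipse), and the
   features collect the inter-centroid heights |h_i|, semi-axes
   `B_i^R ≥ B_i^r`, bending cosines cos φ_i = h_i·h_{i+1}/(|h_i||h_{i+1}|),
   the spherical angles θ_i, Θ_i, Φ_i of centroid vectors and ellipse
   normals in a spine-local frame, section area ratios φ_24, φ_26, φ_46,
   per-region convex-hull volumes V_i and the total volume V — 36
   morphological + 18 directional features, invariant to rigid motion.
3. **Clustering** — Gaussian mixtures `f(x) = Σ_c π_c N(x | µ_c, Σ_c)`
   fitted by EM (k-means++ restarts, full / diagonal / tied covariances),
   model selection by `BIC = 2 log L − k log n` (higher is better), soft
   memberships, per-cluster |log10 det Σ_c|, Bhattacharyya distances with
   classical MDS embedding, misclassification overlaps
   `ω_{j|i} = P[π_i N_i(x) < π_j N_j(x) | x ~ N_i]`, and χ² contingency
   tests against metadata.
4. **Simulation** — feature vectors sampled from a fitted component are
   rebuilt into ellipse skeletons, lofted into closed meshes, smoothed by
   Loop subdivision, and scored for realism by the cross-validated
   accuracy of a real-vs-simulated classifier (≈ 0.5 means
   indistinguishable).

A first-class synthetic-data module (`make_synthetic_spine`,
`corrupt_mesh`, `sample_feature_population`) generates parametric spine
meshes with closed-form cross-section oracles, fragmentation/detachment
corruptions, and 54-feature mixture populations with known parameters, so
the entire pipeline is testable without any experimental data.

## Worked example

```r
library(spinemorph)

## A corrupted synthetic spine, repaired
sp  <- make_synthetic_spine(spine_spec("mushroom_like"), seed = 7,
                            roughness = 0.015)
bad <- corrupt_mesh(sp$mesh, "fragment", magnitude = 0.6, sp$insertion)
validate_mesh(bad$mesh)$n_components
#> [1] 2
rep <- repair_spine(list(spine_id = "demo", mesh = bad$mesh,
                         insertion = bad$insertion))
rep$action; rep$accepted; round(rep$volume_after / rep$volume_before, 3)
#> [1] "closed"
#> [1] TRUE
#> [1] 1.028

## The 54-feature descriptor
fx <- extract_features(rep$mesh, sp$insertion)
length(fx$features)
#> [1] 54
round(fx$features[c("h1", "R5", "cos_phi3", "V")], 4)
#>       h1       R5 cos_phi3        V
#>   0.2301   0.3813   0.9929   0.2446
```

The repaired spine is a single watertight body whose volume changed by
2.8%; its first region is 0.23 µm tall, the fifth boundary ellipse (on
the head) has a 0.38 µm semi-major axis, the spine is nearly straight at
region 3 (cos φ ≈ 0.99), and it encloses 0.24 µm³.

```r
## Cluster a synthetic population and inspect the solution
pop <- sample_feature_population(3, 200, separation = 5, seed = 1)
fit <- fit_mixture(pop$X, C_range = 1:5, seed = 1, n_init = 2,
                   covariance = "diagonal", tol = 1e-4)
fit
#> Gaussian mixture: C = 3 components, d = 54, n = 600
#>   logL = -43957.73, BIC = -90000.85 (higher is better)
#>   weights: 0.333 0.331 0.336
round(cluster_distance_matrix(fit), 1)   # Bhattacharyya distances
#>      [,1] [,2] [,3]
#> [1,]  0.0  3.5  3.4
#> [2,]  3.5  0.0  6.4
#> [3,]  3.4  6.4  0.0
mem <- memberships(fit, pop$X)
round(100 * mean(mem$p_star > 0.99), 1)  # confidently assigned spines
#> [1] 94.5

## Simulate spines from component 1 and score realism
sims <- simulate_spines(fit, cluster = 1, n = 3, simulation_config(seed = 3))
validate_mesh(sims$meshes[[1]])$watertight
#> [1] TRUE
real1 <- pop$X[mem$label == 1, ]
simf  <- sample_features(fit, 1, nrow(real1), seed = 4)
round(realism_score(real1, simf, folds = 10, seed = 5)$accuracy, 3)
#> [1] 0.48
```

BIC picks the three generating clusters, 94.5% of spines have a
membership probability above 0.99, and a decision tree cannot tell
simulated spines from the cluster they were fitted to (cross-validated
accuracy 0.48 ≈ chance).

A command-line wrapper over the same functions lives at
`inst/cli/spinemorph.R`
(`Rscript spinemorph.R synth|repair|extract|cluster|simulate|validate-realism|run …`),
and `run_pipeline()` wires all stages end to end with one seed and a
manifest.

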
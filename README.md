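# triconnectome

High-resolution, surface-based structural connectome construction and
analysis in R.

Most structural brain-network studies parcel the cortex into ~100–1000
regions. At much higher resolution — where every *triangle* of a
downsampled cortical surface mesh (~50,000 triangles, a few mm² each) is
a network node — the network can be analysed *within* single atlas areas,
revealing modular structure that parcellated connectomes average away.
`triconnectome` implements that analysis chain for researchers in
connectomics and network neuroscience:

1. **Network construction.** Triangles are nodes. Local lateral
   connectivity links each triangle to its three mesh neighbors (keeping
   the network connected); long-range connectivity is added by snapping
   each tractography streamline's two endpoints to the nearest triangle
   centers (Euclidean distance). The local and long-range matrices are
   summed and binarised. Streamlines with implausible lengths
   (< 10 mm or > 300 mm) or per-step turning angles > 60° are excluded
   first, with per-rule accounting.
2. **Topological scale-invariance.** Maximum excluded mass burning
   (MEMB) box covering computes N_B(ℓ_B), the number of boxes of
   chemical size ℓ_B needed to cover the network, for 1 < ℓ_B < 11. On a
   scale-invariant network N_B(ℓ_B)/N follows a power law; the fractal
   (box) dimension d_B is the negative slope of log N_B(ℓ_B)/N versus
   log ℓ_B.
3. **Within-area modules.** For each area's induced subgraph, Louvain
   modularity Q(γ) is maximised 25 times per resolution γ on a grid
   0.6–1.4 (step 0.02), and likewise on a random graph with the same
   N and k. Q_MAX(γ) = Q̄_net(γ) − Q̄_rand(γ); the resolution γ* maximising
   Q_MAX is selected, and a consensus partition (pairwise
   co-classification, threshold τ = 0.5, re-clustered to convergence)
   summarises the 25 runs at γ*.
4. **Module-to-module targeting.** For every pair of modules in two
   different areas, the edge density (inter-area edges divided by all
   possible node pairs) quantifies whether long-range connections
   terminate in specific modules. Compared with same-size random
   networks (modules re-detected on each), targeted connectivity shows
   *more* zero-density module pairs but *higher* nonzero densities, and
   the package also tests association of module-pair connectivity with
   centroid distance (rank-biserial effect size, permutation p) and with
   gyral/sulcal/saddle surface classes (Cramér's V on discrete-curvature
   classes).

Every input has a synthetic generator — bumpy area-labelled icospheres,
planted contiguous modules, streamlines with controllable
module-targeting fidelity and contamination, (u,v)-flower graphs of
known fractal dimension ln(u+v)/ln(u), and planted-partition (SBM)
graphs — so the full chain is testable without imaging data.

## Worked example

```r
library(triconnectome)

# a synthetic "subject": 1280-triangle bumpy sphere, 4 areas,
# 5 planted modules per area, 2000 streamlines at fidelity 0.9
scene <- makeSyntheticScene(nStreamlines = 2000L, seed = 42L)
scene
#> SyntheticScene: TriangleMesh: 642 vertices, 1280 triangles, 4 areas
#>    2000 streamlines, 20 planted modules, fidelity 0.9

filt <- filterStreamlines(scene@streamlines)
filt$counts
#>         kept length-short  length-long        angle         mask
#>         1900           34           33           33            0

centers <- triangleCenters(scene@mesh)
snap <- mapEndpoints(filt$kept, centers)
net <- assembleNetwork(triangleAdjacency(scene@mesh), snap$edges,
                       nTriangles(scene@mesh), areaLabels(scene@mesh),
                       centers)$network
net
#> ConnectomeNetwork: 1280 nodes, 3730 edges, 4 areas

# box-covering curve and fractal dimension of the combined network
fitFractalDimension(boxcountCurve(net), nNodes(net))
#> FractalFit: d_B = 3.2006 (se 0.2127, R^2 0.9912) over ell_B {3,5,7,9}

# within-area consensus modules (reduced scan for the example)
wam <- withinAreaModules(net, gammaGrid = seq(0.6, 1.4, by = 0.1),
                         nRuns = 5L, seed = 1L)
wam$scans[["area1"]]
#> GammaScanResult: 9 gammas x 5 runs; gamma* = 0.60, QMax* = 0.2501; 5 consensus modules

# the consensus recovers the 5 planted modules of area1 (adjusted Rand)
idx <- which(areaLabels(net) == "area1")
adjustedRandIndex(as.integer(factor(wam$modules$module[idx])),
                  scene@plantedModules[idx])
#> [1] 0.9366967
```

The fitted d_B ≈ 3.2 says boxes of doubled chemical size cover the
network with about 2^3.2 times fewer boxes over the fitted range — the
log–log fit quality (R² = 0.99) is what indicates scale-invariance. The
γ scan found its largest modularity excess over the random null at
γ* = 0.6, where the consensus over 5 runs yields exactly the 5 planted
modules (ARI 0.94 against the planted labels).

The same chain runs from the shell:

```sh
Rscript inst/scripts/triconnectome-cli.R run-all --seed 42 --out out/
```

writing the mesh (OFF), streamlines (TCK), network (MatrixMarket pattern
symmetric + node TSV), box counts, γ-scan tables, consensus partition
and targeting statistics, plus a `manifest.json` that records seeds and
supports resuming (`--config cfg.yaml` accepts a YAML config; see
`defaultPipelineConfig()`).

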
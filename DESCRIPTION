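Package: triconnectome
Title: High-Resolution Surface-Based Connectome Construction and
    Scale-Invariance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds high-resolution structural brain networks in which
    triangles of a cortical surface mesh are nodes, local lateral
    connectivity links mesh-adjacent triangles, and long-range
    connectivity is added by snapping tractography streamline endpoints
    to the nearest triangle centers. Provides maximum excluded mass
    burning (MEMB) box covering with fractal-dimension estimation,
    resolution-scanned Louvain consensus modularity against same-size
    random-graph nulls, and module-to-module targeting statistics
    (edge densities of module pairs between areas, distance
    association, curvature-class preference). Includes synthetic-data
    generators (bumpy area-labelled icospheres, planted module-targeted
    streamlines, (u,v)-flower fractal benchmarks, planted-partition
    graphs) so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    igraph,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'boxcover.R'
    'mesh.R'
    'curvature.R'
    'io.R'
    'modularity.R'
    'modstats.R'
    'synth-graphs.R'
    'streamlines.R'
    'synth-scene.R'
    'pipeline.R'
    'triconnectome-package.R'
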
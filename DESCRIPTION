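Package: mgvs
Title: Model-Guided Virtual Screening with Graph-Edit-Distance Analog Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for model-guided virtual screening: filter generated
    candidate molecules (PAINS substructures, drug-likeness ranges, and
    irregular ring/double-bond rules), retrieve synthesizable analogs from a
    local compound library by anonymous-graph graph-edit-distance search,
    score ligands through a pluggable docking adapter (external Vina-family
    engine or a deterministic mock), and compare predicted binding poses by
    geometric protein-ligand interaction matching. Includes the evaluation
    statistics used to benchmark generate-then-retrieve screening against
    random virtual screening (ligand-efficiency rankings, pool-size curves,
    Welch tests, and distance-score correlations) and a synthetic fixture
    generator for reproducible desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    bio3d,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    optparse
SystemRequirements: OpenBabel (obabel on PATH) for 3D conformer generation
    and MMFF94 relaxation; not needed for 2D filtering, search or matching.
Config/testthat/edition: 3
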
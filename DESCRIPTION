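Package: phenotrack
Title: Dose-Response Phenotypic Trajectory Analysis for High-Content Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanism-of-action profiling of small molecules from per-cell
    high-content screening feature tables. Implements measurement transforms,
    stain-background and plate-control normalization, over-classed multi-class
    linear discriminant analysis (each compound-by-concentration treatment is
    its own class) alongside mechanism-class LDA and PCA, Gaussian phenotype
    distribution overlap, maximum sequential weighted overlap (MSWO) between
    dose-ordered phenotypic trajectories, phenotypic activity scoring, UPGMA
    clustering with Newick export, and exemplar-based classification with a
    maximum a posteriori threshold for rejecting compounds into an
    "Unspecified" class. Includes a synthetic screen generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
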
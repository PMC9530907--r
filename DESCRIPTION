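Package: geicells
Title: Biclustering Two-Way Phenotype Tables into Cells with Homogeneous
    Genotype-by-Environment Interaction
Version: 0.1.0
Authors@R:
    person("geicells", "maintainers", email = "maintainers@geicells.org",
           role = c("aut", "cre"))
Description: Models genotype-by-environment interaction (GEI) from a two-way
    table of phenotype means with arbitrary missing cells.  Rows (genotypes)
    and columns (environments) are biclustered into cells within which GEI is
    approximately constant, so that a separate no-interaction (additive) model
    fits inside every cell; cluster counts are chosen on a grid by the total
    within-cell error of those fits.  Includes the four standard response
    transformations used for clustering, a missing-data-tolerant alternating
    least-squares biclustering algorithm with random restarts and an
    exhaustive oracle for tiny instances, benchmark models (additive,
    cell-means, Finlay-Wilkinson regression on the mean, AMMI with Gollob
    degrees of freedom), a synthetic-data generator with planted block
    structure and missing-not-at-random masks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
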
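Package: ecgem
Title: Enzyme-Constrained Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and analysis of enzyme-constrained genome-scale
    metabolic models (ecGSMMs). Expands a stoichiometric model GECKO-style by
    treating enzymes as pseudo-metabolites with 1/kcat coefficients, arm
    reactions for isozymes and abundance-bounded enzyme-usage reactions;
    ingests kcat and protein-abundance evidence with taxonomic fallback
    matching; corrects over-constraining kcat values by apparent catalytic
    rate (kapp) sweeps over substrate and oxygen condition grids; and provides
    the LP-based phenotype suite: flux balance analysis, parsimonious FBA,
    robustness surfaces, flux variability analysis with variability-reduction
    statistics, single-gene knockouts (grRatio), differential enzyme usage
    across carbon sources, and metabolite-graph connectivity indices. Includes
    a synthetic toy-model generator with known analytic optima for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
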
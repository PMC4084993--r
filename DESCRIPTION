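Package: decophy
Title: Dispersal-Extinction-Cladogenesis Models for Historical
    Biogeography and Cophylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood inference under the
    dispersal-extinction-cladogenesis (DEC) model of geographic range
    evolution on dated phylogenies, with time-stratified dispersal
    multipliers, ancestral-scenario estimation with relative
    probabilities, and multi-model consensus rules.  Extends the model to
    cophylogenetics through the area-equals-host analogy: host
    repertoires are encoded as DEC ranges, reconstructions are translated
    into cospeciation, host-switch, duplication and lineage-loss events,
    and host-parasite associations are classified into hierarchical
    codivergence levels.  Includes an LCA-mapping permutation test of
    host-parasite tree congruence and forward simulators (Yule host
    trees, codiversification with logged event histories, DEC range
    histories) that provide ground truth for validation.  Ships the
    parasite-host-area association table for Margotrema flukes and their
    goodeine fish hosts from central Mexico as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
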
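Package: orthodesign
Title: Orthogonal Metabolic Pathway Design with Elementary Flux Modes and Metabolic Valves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how separable chemical production is from biomass
    formation in a stoichiometric metabolic network, and designs branched
    "valve" strain topologies. Enumerates elementary flux modes, partitions
    them into biomass-only and product-only sets, and computes an
    orthogonality score from their support overlap (with bimodality-aware
    mode estimation). Implements ValveFind: minimal cut sets that guarantee
    a product yield at zero growth, identification of a single valve
    reaction whose reactivation restores near-wild-type growth, precursor
    synthesizability audits, and ranking of designs by orthogonality.
    Includes flux balance and variability analysis, valve-throttled
    production envelopes, and minimum protein cost estimation of pathways
    with thermodynamic and saturation decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
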
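Package: pathweaver
Title: Balanced Subnetwork Extraction and MILP Enumeration of Heterologous
    Production Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a balanced subnetwork of biochemical reactions that
    connects a target compound, together with all of its cosubstrates and
    byproducts, to the native metabolism of a host organism; integrates the
    subnetwork into the host's genome-scale stoichiometric model; enumerates
    minimal feasible production pathways by mixed-integer optimization with
    integer cuts; and ranks the pathways by product yield, pathway size or
    enzyme-assignment weight, and thermodynamic feasibility. Includes a
    reaction-database data model with element and charge balance checking,
    weighted k-shortest loopless path search over reactant-product-pair
    graphs, precursor selection by carbon count and maximum common
    substructure, COBRA-JSON and SBML readers and writers, Gephi GDF export,
    thermodynamics-based flux analysis, and deterministic synthetic fixtures
    for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    pracma,
    optparse
Config/testthat/edition: 3
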
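Package: mdindexr
Title: Mining and Indexing Molecular Dynamics Files in Generalist Data Repositories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers, indexes, parses and profiles molecular dynamics (MD)
    simulation files scattered across generalist data repositories such as
    Zenodo, Figshare and the Open Science Framework. Implements the
    Explore-and-Expand harvesting strategy over pluggable repository adapters
    (including zip-archive preview listing and false-positive cleaning),
    native parsers for the Gromacs .gro, .mdp, .xtc and .log file formats,
    rule-based metadata inference (MD engine assignment, residue-category
    composition, all-atom versus coarse-grain resolution, production-run
    labelling, thermostat and barostat vocabulary normalisation), and an
    aggregation layer producing corpus-level summary tables, distributions
    and a searchable index with tab-separated export. Deterministic synthetic
    generators for every input format make the full pipeline testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
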
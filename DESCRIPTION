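Package: thermalB
Title: Temperature-Resolved Decomposition of Crystallographic B-Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multi-temperature protein crystal
    structure series: PDB reading with header metadata (data-collection
    temperature, Wilson B), Kabsch least-squares superposition and
    per-residue displacement profiles, B-factor aggregation and
    normalization, linear and single-exponential temperature regression
    of displacements and B-factors (zero-Kelvin amplitude B0 and thermal
    constant k), conserved-water tracking across a temperature series,
    cross-correlation of thermal parameters with conformational
    plasticity, comparison of heterogeneous depositions of one protein,
    and a synthetic PDB-ensemble generator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
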
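Package: plasmidrace
Title: Competition Dynamics and Streamlining Detection for Conjugative Plasmids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how streamlined (accessory-region-deleted)
    variants of conjugative plasmids displace their ancestors. Implements a
    four-compartment ODE model of competition between a wildtype and a
    mutant plasmid (entry exclusion, co-infection, segregational loss,
    horizontal and vertical transmission advantages, host influx) with
    event-detected replacement times and parameter sweeps; a
    sequencing-depth deconvolution that infers the mixture of full-length
    and streamlined plasmid copies in a clone from per-base coverage and
    calls the deleted interval; and assay-level estimators for conjugative
    transfer efficiency, plate-count densities and maximal growth rate from
    OD600 curves. A synthetic-data module generates all inputs with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
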
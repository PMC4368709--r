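Package: domainscape
Title: Domain-Level Landscape of Cancer-Type-Specific Somatic Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps somatic missense mutations onto protein domain instances
    and scans for cancer-type-specific significantly mutated domain
    instances (SMDs) and within-domain mutational hotspots using Fisher's
    exact test with Benjamini-Hochberg false-discovery-rate control.
    Computes the hotspot-ratio statistic that separates oncogene-like
    (recurrent, concentrated) from tumor-suppressor-like (dispersed)
    mutation patterns, quantifies the overlap of hotspots with annotated
    functional sites, and pools hotspots across instances of the same
    domain type. Includes a seeded synthetic cohort generator with planted
    SMDs and hotspots for end-to-end validation, plus a scan/report
    pipeline over COSMIC-style tab-separated inputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
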
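Package: chemregistry
Title: Curated Chemical Substance Registry with Identifier Conflict Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A registry engine for curated chemical substance data. Enforces a
    strict one-to-one-to-one mapping between CAS Registry Numbers, preferred
    names and chemical structures; validates CAS RN check digits; resolves
    queries through active identifiers, deleted CAS RNs and synonyms;
    bulk-loads external source databases through sequential quality filters
    with conflict quarantine and tiered quality-control levels; bins source
    lists into typed curation queues; derives QSAR-ready and MS-ready
    structure forms by desalting and stereochemistry removal; and enumerates
    congener families (Markush substitution patterns) up to scaffold
    symmetry. Structure identity is keyed by standard InChIKeys computed via
    Open Babel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stringi,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
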
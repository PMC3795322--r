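Package: goherence
Title: Annotation Coherence Metrics and Annotation Extension for Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing the coherence of Gene Ontology (or any
    DAG-structured vocabulary) annotation within protein families and for
    proposing extensions of under-specific annotations.  Parses OBO
    ontologies and GAF annotation files, applies true-path-rule propagation,
    computes information-content based family metrics (GOscore,
    GOoccurrence), performs per-family term enrichment with
    Benjamini-Yekutieli correction, renders annotation flow graphs, and
    identifies coherent support sets together with extension candidate
    proteins.  Includes deterministic synthetic-scenario generators that
    emulate the annotation structure of polysaccharide-lyase enzyme
    families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
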
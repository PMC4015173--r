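Package: rinchi
Title: Reaction InChI (RInChI) Identifiers, Hashed Keys and Reaction
    Database Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds canonical RInChI (version 0.02) identifier strings for
    chemical reactions from MDL RXN and RD files, together with their
    RAuxInfo companions and four hashed RInChIKey variants (long and short,
    versions A and B).  Reaction identifiers are assembled from standard
    InChI (1S) strings of the participating molecules, which are obtained
    through the Open Babel command line tool.  The package also decodes
    identifiers back to reaction files, combines multistep sequences into
    an overall reaction identifier, and provides database-scale analyses
    operating directly on identifier strings: deduplication, reaction
    partner search, ring-change and stereocentre-change statistics, and
    corpus summaries.  A fixture module generates toy molecules, reaction
    files and seeded synthetic reaction corpora with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (>= 3.0) with InChI support ('obabel' on the
    PATH)
Config/testthat/edition: 3
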
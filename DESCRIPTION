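Package: recarb
Title: Building, Rebuilding and Validation of N-Glycan Trees in
    Crystallographic Protein Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated curation of N-linked glycosylation in protein
    crystal structures. Detects and generates missing covalent link
    records between asparagine side chains and N-acetylglucosamine,
    validates pyranose ring geometry with Cremer-Pople puckering
    parameters and a three-tier quality status, scores carbohydrate
    residues against real-space electron density (RSCC, EDIA and a
    density-ratio metric), and crops, extends, rebuilds and adds whole
    N-glycosylation trees using template-based residue placement with
    the acceptance, grafting and restoration rules used in large-scale
    model re-refinement. Ships a synthetic glycosite generator so the
    full pipeline is testable without experimental data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
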
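Package: drumbeat
Title: Time-Resolved Probabilistic Graph Analysis of Residue-Contact Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies residue-contact communities that enable and effect
    conformational transitions in molecular-dynamics trajectories. Binary
    residue-contact fingerprints are filtered by pairwise mutual information,
    aggregated into a universal dataset with transition-enriched subsampling,
    and modelled as a directed acyclic probabilistic graph over contacts.
    The static graph is then re-parametrized along each trajectory with
    sliding-window mutual information, yielding time-resolved allosteric
    communities (TRACs) whose weighted-degree peaks mark transition events.
    Companion tools rank and order enabler/effector communities, delineate
    conformational states by principal component analysis, and score the
    evolutionary conservation and class specificity of community residues
    via Von Neumann entropy of alignment columns.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
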
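Package: fabseq
Title: Antibody Variable-Domain Sequencing from CryoEM Models and De Novo
    Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Template-guided assembly of error-prone antibody sequence reads
    into variable-domain consensus sequences. Reads are amino-acid chains
    extracted from cryoEM atomic models (per-residue confidence in the
    B-factor column) or de novo LC-MS/MS peptides with local confidence
    scores. Reads are matched to immunoglobulin germline V/J/C templates by
    local alignment, assembled into confidence-weighted consensus sequences,
    CDR3 is detected between the conserved Cys/Trp-Phe anchors, and
    recombined V+CDR3+J templates (with germline decoys) guide a second
    assembly pass over peptide reads. Includes evaluation metrics (V-gene
    identity, CDR3 statistics, score-identity correlation) and a seeded
    synthetic-data generator for ground-truthed benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
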
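Package: fvorient
Title: Variable Domain Orientation Analysis for Antibodies and T-Cell
    Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Geometric and sequence analyses of paired immunoglobulin
    variable domains (antibody VH-VL and T-cell receptor Vbeta-Valpha).
    Implements a bidirectional inter-domain orientation RMSD with
    complete-linkage clustering, six absolute orientation measures (five
    angles and a pivot-axis length) built from coresets, consensus domains
    and registered reference frames, the TCR-pMHC docking angle with the
    canonical 40-85 degree classification, an orientation-grafting
    protocol that transplants decoy inter-domain poses into a native
    receptor-pMHC complex with steric clash and contact quantification,
    IMGT-position-wise conservation analyses (domain equivalence support,
    divergent conserved interface positions, CDR3 length distributions, a
    greedy sequence-identity redundancy filter), and a deterministic
    synthetic-structure generator providing ground-truth poses and toy
    pMHC complexes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
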
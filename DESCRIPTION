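Package: zfscore
Title: Zinc Finger Protein-DNA Binding Specificity from Interfacial
    Hydrogen-Bond Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Ab-initio engineering of Cys2His2 zinc finger proteins against
    double-stranded DNA targets. Builds idealized B-form DNA models for 3-bp
    sub-site and 27-bp synergistic targets, enumerates mutant recognition
    helices on the Zif-268 scaffold, threads side chains onto a fixed-backbone
    protein-DNA complex using a rotamer library, detects interfacial hydrogen
    bonds between amino-acid and nucleotide N/O/S atoms, scores them with an
    AMBER99-style 10-12 hydrogen-bond potential, and ranks candidate helices
    per sub-site (modular binding) or per whole target (synergistic binding).
    Includes a synthetic-complex fixture generator with analytically known
    interface energies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'chemistry.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'dna_model.R'
    'structure_io.R'
    'ihbe_scorer.R'
    'mutator.R'
    'fixtures.R'
    'helix_library.R'
    'rank_pipeline.R'
    'seq_targets.R'
    'zfscore-package.R'
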
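Package: antartools
Title: Analysis Toolkit for ANTAR-Mediated Antitermination: Conservation,
    Interfaces, SELEX, Binding and Readthrough
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the computational stages used to dissect
    autoinhibitory coupling between a ligand-sensing NIT domain and an
    RNA-binding ANTAR domain in one-component antitermination regulators
    such as Klebsiella oxytoca NasR. Provides per-column conservation and
    group-versus-rest differential Kullback-Leibler (KL) divergence scoring
    on labeled protein alignments with a conserved-position caller;
    distance-based detection and classification of interdomain residue
    pairing from atomic coordinates; simulation and analysis of SELEX
    selections for the tandem two-hairpin ANTAR RNA motif; Hill-equation
    fitting of fluorescence-anisotropy titrations with variant
    classification and ion-response curves; and quantification of
    transcription readthrough fractions from gel band intensities. Seeded
    synthetic-data generators with recorded ground truth make every stage
    testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
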
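Package: daqrefine
Title: Per-Residue Map-Model Quality Scoring and Local Refinement Support for Cryo-EM Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores each residue of a cryo-EM-derived protein model with a
    log-ratio amino-acid quality score (DAQ(AA)) computed from a 20-channel
    amino-acid probability volume, smooths the scores along the chain to
    expose sequence-register shifts, and prepares the inputs for
    structure-prediction-based local refinement: a trimmed template holding
    only confident residues and a multiple sequence alignment with confident
    columns masked. Also provides model-quality metrics against a reference
    (Kabsch superposition, Calpha r.m.s.d., GDT-HA, misaligned-segment
    detection), DAQ-based ranking of candidate refined models, and a
    synthetic-fixture generator (ideal backbones, oracle probability
    volumes, injected register-shift and conformational errors) so the whole
    pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
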
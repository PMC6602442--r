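Package: refine2lite
Title: Desk-Scale Protein Model Refinement by Pool-Based Conformational Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines single-chain protein models at desk scale. Estimates
    residue-wise model error from structural fluctuation, fragment-library
    agreement and sequence-profile conservation, detects unreliable local
    regions, and refines the model by an iterative pool-based conformational
    search with six structure operators (fragment assembly, loop modelling,
    side-chain perturbation, normal-mode perturbation, structure
    hybridization, secondary-structure perturbation), restrained relaxation
    under harmonic or Lorentzian distance restraints, and restraint-free
    final scoring. Includes model-quality metrics (CA-RMSD, GDT-HA, LDDT,
    TM-score, clash score), analytic triaxial loop closure, elastic-network
    normal modes, and a synthetic-fixture generator so the whole protocol is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
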
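Package: rotpos
Title: Sequence-Dependent Nucleosome Positioning from DNA Deformation Energy
Version: 0.1.0
Authors@R:
    person("rotpos", "developers", email = "rotpos@example.org", role = c("aut", "cre"))
Description: Predicts nucleosome occupancy and rotational positioning from DNA
    sequence using a base-pair-step elastic deformation-energy model. Computes
    bending and shearing energies of sliding windows against a superhelical
    nucleosome template, converts them to occupancy via a Boltzmann score with
    a Gaussian center-weighting kernel, and via a wave-packet correlation
    ("rotational positioning index") whose upper envelope yields a second
    occupancy estimate. Includes rotational-strength diagnostics (sliding-window
    standard deviation and 10-bp Fourier power), processing of experimental
    nucleosome-center-positioning score tracks (center-weighted occupancy,
    greedy dyad calling with a minimum-spacing rule), strand-aware metagene
    profiling around genomic anchors, and synthetic-data generators with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
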
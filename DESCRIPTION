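Package: vibronic
Title: Linear Vibronic Coupling Models, Wavepacket Dynamics, and
    Aggregation-Dependent Absorption Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling the optical response of aggregating
    chromophores with linear vibronic coupling (LVC) Hamiltonians.
    Builds monomer and dimer Hamiltonians over local-excitation and
    charge-transfer diabatic states (including Jahn-Teller linear
    couplings), propagates nuclear wavepackets exactly in a
    harmonic-oscillator product basis to obtain correlation functions
    and diabatic-state populations, converts correlation functions into
    vibronic absorption spectra by Fourier transform with Gaussian
    damping, reduces many-mode Hamiltonians with a hierarchical
    effective-mode transformation, and connects spectra to
    conformational dynamics through RMSD (Daura) clustering of
    stacked-dimer trajectories, cluster-weighted spectral averaging and
    inter-monomer geometry descriptors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
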
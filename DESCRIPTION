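Package: ucjcirc
Title: Unitary Cluster Jastrow Ansatze with Exact Givens-Rotation Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the three k-fold unitary cluster Jastrow (uCJ)
    wavefunction ansatze for molecular electronic structure on quantum
    computers: Re-uCJ (real orbital rotations), Im-uCJ (imaginary rotations)
    and g-uCJ (general complex rotations).  Provides Jordan-Wigner fermionic
    operator algebra, exact (Trotter-free) circuit synthesis via generalized
    complex Givens rotations, CNOT/T-gate resource accounting, a sparse
    statevector simulator with qubit-wise-commuting shot sampling, classical
    variational optimization (including perfect-pairing staged warm starts
    and continuation scans), spin-adapted configuration state function
    analysis, FCIDUMP input/output, and a minimal s-type Gaussian RHF/UHF
    backend for hydrogen-cluster benchmark systems.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
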
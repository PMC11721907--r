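Package: vqebench
Title: Variational Quantum Eigensolver Benchmarks for Active-Space
    Molecular Hamiltonians
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for benchmarking variational quantum eigensolver (VQE)
    calculations of molecular ground-state energies on a classical
    statevector simulator.  Provides STO-3G orbital counting and
    active-space bookkeeping, FCIDUMP integral input with frozen-core
    folding, the Jordan-Wigner fermion-to-qubit mapping, five
    hardware-efficient ansatz circuits plus a Trotterized UCCSD ansatz,
    parameter-shift gradient descent with a seventh-decimal convergence
    rule, and determinant-based FCI and CISD reference energies via
    Slater-Condon matrix elements.  A benchmark driver runs the ansatz by
    active-space matrix and writes tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
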
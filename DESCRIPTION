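Package: frdo
Title: Freeze-and-Release Direct Optimization of Excited-State Mean-Field Solutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variational excited-state self-consistent-field solutions are
    saddle points of the electronic energy and are prone to variational
    collapse, especially for charge-transfer states.  This package implements
    freeze-and-release direct orbital optimization: a constrained
    minimization with the hole and excited-electron orbitals frozen,
    followed by an unconstrained limited-memory SR1 saddle-point search with
    an indefinite diagonal preconditioner.  It includes the maximum-overlap
    (MOM) occupation-control baseline, numeric electronic Hessian and
    saddle-point-order analysis, charge-transfer diagnostics (Le Bahers
    charge-transfer distance, spin contamination, spin purification), and a
    self-contained Pariser-Parr-Pople donor-acceptor model backend with a
    seeded fixture generator for testing the optimizers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
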
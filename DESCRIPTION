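Package: dendritaper
Title: Passive Voltage, Optimal Taper and Current Transfer in Dendritic Cables
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analytical (method-of-multiple-scales) solutions for the passive
    voltage in dendritic cables with arbitrary radius taper, a conservative
    finite-difference cable solver used as a numerical oracle on both
    unbranched cables and full branched morphologies, the variationally
    optimal quadratic taper that maximises current transfer to the soma, a
    derivative-free segment optimiser reproducing the quadratic optimum
    non-parametrically, and an algorithm that maps the optimal taper onto
    arbitrary branched trees via apparent lengths and Rall's 3/2 branching
    rule. Includes SWC morphology input/output and generators for synthetic
    cables and random binary trees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, pracma
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
biocViews: Software, Electrophysiology, MathematicalBiology
RoxygenNote: 7.3.3
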
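Package: calvaria
Title: Finite-Element Simulation of Post-Operative Calvarial Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale finite-element modelling of infant calvarial growth
    after reconstructive surgery for sagittal craniosynostosis. Generates a
    parametric labelled skull (bone plates, sutures, craniotomies, optional
    cerebrospinal-fluid layer, brain), drives intracranial expansion through a
    thermal-expansion analogy with penalty frictional contact between the
    intracranial volume and the inner calvaria, applies gradual (front-based,
    hydrostatic-strain gated) or bulk (modulus ramp) bone-formation rules, and
    reports craniometric dimensions, cephalic index, suture patency timelines
    and regional contact-pressure statistics, including a built-in grid of
    material-property and formation-rate sensitivity experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Matrix, stats, utils, graphics, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse, withr, xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
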
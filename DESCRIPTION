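Package: MechanoMemory
Title: Motor-Clutch Modelling and Quantification of Stiffness-Driven YAP
    Mechanical Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Mechanistic modelling and measurement tools for mechanical
    memory in mesenchymal stem cells. Implements a stochastic motor-clutch
    traction simulator in which N-cadherin (HAVDI) ligation lowers the
    integrin clutch binding rate through a stiffness-dependent activation
    law, a viscoelastic-plastic nucleus whose irreversible flattening
    stores mechanical dose, a linear flattening-to-YAP
    nuclear/cytoplasmic-ratio shuttling model, and the standard
    measurement formulas used alongside such experiments: Hertz spherical
    indentation fitting, sparse and confluent nuclear/cytoplasmic
    intensity ratios, nuclear flattening from z-stacks, thresholded
    co-localization fractions and positive-cell fractions. Synthetic-data
    generators with known ground truth make every stage testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    EBImage,
    methods,
    Rcpp,
    stats,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'MechanoMemory-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'kon.R'
    'clutch.R'
    'nucleus.R'
    'protocol.R'
    'config.R'
    'imaging.R'
    'indentation.R'
    'synthetic.R'
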
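Package: egfrtree
Title: Decision-Tree Selection of Glomerular Filtration Rate Estimation Equations
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating glomerular filtration rate (GFR) in chronic
    kidney disease from serum creatinine and cystatin C. Implements a library
    of thirteen published eGFR equations (Cockcroft-Gault, the MDRD family,
    the CKD-EPI family, BIS-2, MacIsaac, Ruijin and Xiangya), Du Bois body
    surface area normalisation, best-matched-equation labelling against
    measured GFR, a from-scratch classification tree (entropy impurity,
    information-gain splitting over mixed numeric and categorical covariates)
    that selects the optimal equation per patient, an evaluation battery
    (RMSE, MAE, Bland-Altman limits of agreement), and a synthetic cohort
    generator with a planted equation-selection structure for end-to-end
    testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
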
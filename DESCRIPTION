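Package: icdrt
Title: Tumor-Immune Dynamics of Radiotherapy Combined with SIRPa-CD47
    Checkpoint Immunotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ordinary-differential-equation models of in vivo tumor growth
    under radiotherapy and macrophage-based immunotherapy targeting the
    SIRPa-CD47 "don't eat me" checkpoint. Couples logistic tumor growth with
    effector-cell killing and macrophage phagocytosis, linear-quadratic (LQ)
    radiation survival with a sublethal-damage repair function, and an
    immunogenic-cell-death (ICD) term I = A(1-S) that amplifies
    radiation-induced killing when the checkpoint is disrupted. Provides a
    staged four-step least-squares calibration with parameter freezing,
    parametric Poisson bootstrap uncertainty, local sensitivity ranking,
    profile-likelihood practical identifiability, abscopal (out-of-field)
    tumor predictions, treatment-efficacy phase maps over activation,
    phagocytosis and dose, and a synthetic-cohort generator with the
    statistical structure the calibration assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    minpack.lm,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
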
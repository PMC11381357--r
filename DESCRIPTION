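Package: tmsdkinetics
Title: Sequence-Dependent Kinetics of Toehold-Mediated DNA Strand Displacement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how invader-strand sequence controls the rate of
    toehold-mediated DNA strand displacement (TMSD). Simulates or ingests
    fluorescence kinetic traces, converts them to product concentration via a
    standard curve, fits second-order rate constants and Arrhenius apparent
    activation energies, computes a 16-variable structural and thermodynamic
    description of each invader from a built-in nucleic-acid secondary-structure
    partition function (with an import adapter for externally computed pair
    probabilities), and evaluates random-forest variable importance, Pearson
    correlations, and three-class rate prediction with one-vs-rest ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    minpack.lm,
    randomForest,
    e1071,
    rpart,
    pROC,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
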
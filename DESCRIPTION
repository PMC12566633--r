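Package: recsel
Title: Recurrent Selection Evaluation for Half-Sib Progeny Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating recurrent selection strategies in
    half-sib progeny trials of outcrossing crops such as tropical maize.
    Simulates lattice-design S0 trials with paired selfed (S1) trials and
    known genetic truth; estimates half-sib variance components,
    family-mean heritabilities, and the phenotypic and genotypic
    covariance matrices of family means; fits the trial mixed model by
    EM-REML with BLUP prediction of progeny genotypic values through
    Henderson's mixed-model equations; ranks progenies by the Smith-Hazel,
    base, and Mulamba-Mock rank-summation selection indexes as well as by
    BLUP of grain yield and of inbreeding depression; predicts and
    compares genetic gains under truncation selection; and quantifies
    agreement among selection strategies with coincidence and Jaccard
    overlap statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
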
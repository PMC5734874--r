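Package: quiesmut
Title: Mutation Accumulation Analysis for Quiescent Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing spontaneous mutation accumulation in
    non-dividing (quiescent) cell populations assayed through a reporter
    gene. Summarises mutational spectra (transition/transversion ratio,
    AT bias, insertion/deletion balance) after clonal-redundancy
    filtering, enumerates potential single-nucleotide substitutions of a
    coding sequence by codon effect, estimates the number of hidden
    phenotype-causing targets from hits-per-target distributions by
    exchangeable multinomial occupancy maximum likelihood, corrects
    phenotypic mutation rates to total rates with genome extrapolation,
    fits linear accumulation slopes, tests Poisson homogeneity of
    per-genome mutation counts, and generates synthetic datasets with the
    statistical structure the analysis assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
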
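Package: cmih
Type: Package
Title: Conditional Mutual Information Estimation and Testing for Mixed Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates conditional mutual information for samples that mix
    qualitative (categorical) and quantitative (real-valued) variables by
    combining plug-in histogram entropies for the qualitative components with
    Kozachenko-Leonenko k-nearest-neighbour entropies for the quantitative
    components, conditioned on qualitative bins (the CMIh hybrid estimator).
    Also provides the classical kNN estimators of Frenzel-Pompe,
    Rahimzamani-Asnani-Viswanath-Kannan and Mesner-Shalizi for comparison,
    global and local permutation conditional-independence tests including a
    local adaptive test (LocAT) suited to mixed conditioning sets, and
    synthetic benchmark generators with analytic ground truths.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, jsonlite, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
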
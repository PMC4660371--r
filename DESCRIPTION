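Package: fourstrand
Title: F-Statistics and Drift-Based Demographic Inference for Ancient DNA Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for population-genetic analysis of merged ancient and modern
    SNP panels: allele-frequency estimation with pseudo-haploid samples,
    f2/f3/f4 and D statistics with weighted block-jackknife standard errors,
    outgroup-f3 topology and affinity tests, admixture-f3 source scans,
    f4-ratio ancestry proportions, moments-based split-time fitting, PCA with
    least-squares projection of incomplete samples, runs-of-homozygosity
    detection, EIGENSTRAT input/output, and a drift simulator over population
    trees with admixture edges that doubles as an exact moment oracle for
    expected f-statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
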
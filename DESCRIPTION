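Package: msatpop
Title: Microsatellite Population Genetics for Wine Yeast Strain Typing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing diploid microsatellite (SSR) multilocus
    genotypes of Saccharomyces cerevisiae isolates from vineyard and winery
    spontaneous fermentations. Reads and validates isolate and commercial
    reference genotype tables, bins raw fragment sizes into alleles, builds
    multilocus genotypes (MLGs) and clone-censors them; computes Bruvo
    stepwise-mutation distances and classifies strains as commercial,
    commercial-related or unique; provides per-locus heterozygosity and
    inbreeding statistics, Hardy-Weinberg tests and pairwise F_ST with
    permutation p-values; rarefaction of MLG richness, genotype accumulation
    curves, chi-square tests with adjusted standardized residuals, Friedman
    and Welch tests; a Bayesian admixture model with population inbreeding
    fitted by Gibbs sampling, with DIC-based selection of the number of
    clusters, greedy multi-run label alignment and ancestry-profile R-squared
    permutation tests; and a synthetic genotype generator with full ground
    truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    vegan,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
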
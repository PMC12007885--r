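Package: genosynth
Title: Balanced Synthetic Genotype Benchmarks with Privacy Perturbation,
    Watermark SNPs and Mendelian Relatives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates balanced, ancestry-labelled synthetic genotype
    datasets from any additively encoded (0/1/2) genotype matrix.  Provides
    PLINK-style quality control (minor allele frequency, missingness and
    exact Hardy-Weinberg filters), PCA-based population stratification, a
    constrained local-differential-privacy randomized response that perturbs
    genotypes without 0<->2 transitions, logit-model binary phenotype
    simulation with exact case/control balance, watermark SNP generation for
    verifying outsourced association analyses, and Mendelian simulation of
    multi-generation synthetic relatives scored with the KING robust kinship
    estimator.  A Balding-Nichols founder-population simulator supplies
    realistic multi-ancestry input when real data are unavailable, and an
    end-to-end pipeline writes the five-file CSV bundle used downstream.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
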
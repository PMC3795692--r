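Package: rotbreed
Title: Rotational Breeding Pedigrees and Quantitative Genetics of
    Divergent Selection Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and analysing long-term artificial
    selection colonies maintained under rotational breeding. Builds
    idealized and randomized breeding pedigrees, computes additive
    relationship matrices and inbreeding coefficients by the tabular
    method, iterates closed-form expectations for inbreeding and
    heterozygosity from per-generation breeder counts, performs
    Mendelian gene-drop simulation of SNP panels through arbitrary
    pedigrees (founders modelled as mosaics of inbred ancestral
    strains), and re-implements the downstream population-genetic
    analyses such colonies require: marker quality control, observed
    heterozygosity, runs of homozygosity, linkage-disequilibrium decay,
    two-group AMOVA, IBS/MDS, IBD sharing proportions, and sex
    inference from X-chromosome markers. Quantitative-genetic tools
    include phenotype simulation under additive architectures, a full
    divergent-selection experiment driver, mid-parent and animal-model
    REML heritability estimation with sparse inverse relationship
    matrices, and the Castle-Wright estimator of effective QTL number.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
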
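Package: eegfbat
Title: Family-Based Association Testing of Quantitative Resting-EEG Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Extracts quantitative resting-state EEG phenotypes (relative mean
    band power and dominant-frequency variability, summarized over scalp
    regions) from continuous multichannel recordings, and tests them for
    allelic association within nuclear families using the univariate FBAT
    statistic and its multivariate FBAT-GEE extension, conditioning on
    parental genotypes under Mendelian transmission. Includes linkage PED
    input/output, recessive/additive/dominant genotype codings, a Monte-Carlo
    transmission null, and seedable generators for pedigrees, genotype-linked
    phenotypes and raw oscillatory EEG so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
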
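Package: sebclass
Title: Mutational Classification of Sebaceous Carcinoma Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the tumor-classification analysis
    used in whole-exome studies of sebaceous carcinoma: somatic variant site
    filtering with a paired tumor/normal genotype model, 96-channel
    trinucleotide mutational-signature decomposition by non-negative least
    squares, microsatellite-instability scoring from homopolymer repeat-length
    distributions, allele-specific copy-number segmentation with joint
    purity/ploidy estimation, candidate neoepitope enumeration, expression
    correlation mapping, and the final three-class (UV-damage / MSI /
    pauci-mutational) tumor assignment. Ships a synthetic-data module that
    generates every pipeline input with known ground truth so the whole
    analysis is testable end to end without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    ape
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
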
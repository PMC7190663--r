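Package: allokaryo
Title: Coverage-Based Karyotyping of Multi-Species Yeast Allopolyploids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers integer chromosome copy numbers, arm-level unbalanced
    translocations, and flow-cytometry-calibrated ploidy for interspecies
    yeast hybrids from windowed depth-of-coverage over a concatenated
    multi-species reference. Quantifies per-parent genome retention and
    genome size, counts new chromosomal aberrations along a crossing
    pedigree, classifies mitochondrial inheritance (homoplasmic,
    heteroplasmic, recombinant), tests selection-cassette copy number by
    coverage ratio, and estimates maximum specific growth rates from optical
    density time series. Includes a synthetic allopolyploid data generator
    with ground-truth karyotypes so every inference stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
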
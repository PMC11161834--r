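Package: circsat
Title: Microsatellite-Derived Extrachromosomal Circular DNA from Inverse-PCR Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse extrachromosomal circular DNAs
    (eccDNAs) arising from non-B DNA microsatellites integrated at an
    engineered ectopic chromosomal site. Decatenates concatemeric inverse-PCR
    circular-consensus long reads into monomer PCR products, aligns monomers
    to a hybrid reference with an internal seed-and-extend aligner, chains
    local alignments into template-switch domains, measures microhomology
    overlap at template-switch and circularization junctions, and computes
    mutation-rate tables, per-kilobase deletion metrics and trinucleotide
    substitution signatures. Ships a fully parameterized synthetic-data
    generator (ectopic-site contigs, eccDNA structures with engineered
    junction homologies, rolling-circle concatemer reads) with ground truth,
    so every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    withr
Config/testthat/edition: 3
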
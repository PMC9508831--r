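Package: strainasm
Title: Strain-Aware Overlap-Graph Assembly of Short-Read Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assembles short-read metagenome sequencing data at strain
    resolution using overlap graphs throughout. Reads are quality
    controlled, all-vs-all suffix-prefix (dovetail) overlaps are detected
    with minimizer seeding and scored by a weighted combination of overlap
    identity and overlap length, reads are grouped by size-capped
    single-linkage clustering over the sorted overlaps, each cluster is
    assembled locally into error-corrected strain-specific contigs via
    iterative best-overlap merging with quality-weighted consensus, and
    cluster contigs are joined along unique, read-supported paths of a
    global overlap graph into master contigs. Includes a synthetic
    strain-community simulator (multi-species, multi-strain communities at
    controlled average nucleotide identity with log-normal strain
    abundances) and an assembly evaluator computing genome fraction, N50,
    NGA50, error rate, N rate and misassembled-contig rate against truth
    genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    parallel,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
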
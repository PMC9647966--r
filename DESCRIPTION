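Package: snpfinger
Title: SNP Marker Screening, Panel Simulation and Cultivar DNA Fingerprinting
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building SNP-based DNA fingerprinting systems for
    crop cultivars. Filters a genome-wide variant set down to high-quality
    fourfold-degenerate candidate markers (biallelic, low heterozygosity,
    low missingness, high minor allele frequency, clean 100 bp flanks),
    screens candidates for KASP assay design (flank extraction, GC content,
    window uniqueness), computes per-marker diversity statistics (MAF, PIC,
    observed heterozygosity, gene diversity, Ts/Tv spectrum), selects
    minimal marker panels by randomized discernibility simulation, and
    builds a cultivar fingerprint database with duplicate-genotype
    detection and plain-text barcode payloads. Ships a synthetic-fixture
    generator (toy genome, GFF3 annotation, multi-sample VCF with planted
    structure) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
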
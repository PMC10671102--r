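Package: mitohap
Title: Forensic Mitochondrial DNA Haplotyping and Population Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building forensic-quality human mitochondrial genome
    (mtDNA) haplotypes from per-position read-evidence tables and for the
    population statistics used to weigh mtDNA evidence. Implements
    threshold-based variant calling (minimum read depth and a 10 percent
    minimum variant frequency that suppresses interference from nuclear
    mtDNA segments, NUMTs), point-heteroplasmy reporting with IUPAC codes,
    length-heteroplasmy handling in homopolymeric C-stretches via the
    major-length-molecule rule, EMPOP-style rCRS-relative haplotype notation,
    literal and pattern haplotype matching over forensic ranges (HVS, control
    region, mitogenome), random match probability and haplotype diversity
    from haplotype frequency spectra, maternal-relative deduplication,
    chi-squared comparison of haplogroup distributions with Yates's
    correction, and haplogroup assignment against a variant-annotated tree.
    A seeded simulator generates populations of haplotypes and realistic
    pileups (depth variation, sequencing noise, heteroplasmy, NUMT
    contamination, homopolymer coverage dropout) for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
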
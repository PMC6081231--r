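Package: mipkit
Title: Single-Molecule Molecular Inversion Probe Panel Design, Simulation and Variant Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for single-molecule molecular inversion
    probe (smMIP) targeted sequencing panels. Tiles padded target regions
    with capture probes and assembles synthesis oligos with amplification
    flanks and EarI release sites; simulates diploid capture with molecular
    tags, PCR duplicates and base errors against planted truth variants;
    assigns read pairs to probes by arm matching, deduplicates by molecular
    tag and builds per-molecule consensus inserts; computes unique-molecule
    depth and sample/exon coverage QC; calls diploid genotypes from
    per-probe gapped alignments and pileups and writes VCF; scores call
    sets against a truth set (sensitivity, genotype concordance); and
    provides clinical-style annotation utilities (HGVS codon arithmetic
    with signal-peptide renumbering, pedigree segregation, allele-frequency
    filtering, cohort phenotype summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
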
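Package: snpdepth
Title: Depth-Aware SNP Frequency Estimation from Transcriptome Contigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls single-nucleotide polymorphisms from reads aligned to
    transcriptome contig consensus sequences using a conservative filter
    cascade (depth, minor-allele support, flanking quality, homopolymer and
    indel/triallelic exclusion), tabulates per-contig SNP, transition and
    transversion counts for protein-coding versus non-coding transcripts,
    fits candidate negative-binomial regressions of SNP counts on contig
    length, depth and coding class, ranks them by AIC and Akaike weights,
    and predicts the standardized SNP count expected at a reference contig
    length and depth. A synthetic-data module generates contig alignments
    with planted variants and filter-rule decoys, plus count tables drawn
    from a known negative-binomial model, so the whole pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    tools,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
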
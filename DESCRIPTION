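Package: sltrans
Title: Spliced-Leader Trans-Splicing Detection and Analysis for Protist Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies spliced-leader (SL) exons on the 5' ends of
    assembled transcripts, discovers SL-RNA genes in genomic contigs using splice-donor
    and poly-T terminator rules, quantifies SL-based segregation of a transcriptome,
    tests SL-defined transcript pools for GO-term enrichment by permutation and for
    abundance shifts by nonparametric rank tests, and builds gap-as-fifth-state
    parsimony trees of SL exon sequences. Includes a synthetic-data generator that
    emulates SL-bearing transcriptomes and genomes with known ground truth, so every
    stage of the pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
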
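Package: mexscan
Title: Micro-Exon Discovery and Domain-Level Evolutionary Analysis for Plant Transcription-Factor Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls micro-exons (coding length <= 51 nt) from genome annotation,
    projects them into protein coordinates, quantifies their enrichment in AP2
    and K-box domains, classifies AP2/ERF and MIKC-type MADS-box genes from
    Pfam-style domain architectures, types micro-exons by domain context and
    length (R1M1/R1M2/R1M3/R2M1; tandem K-box M1/M2), and compares evolutionary
    constraint (Ka/Ks, Nei-Gojobori counting with Jukes-Cantor correction) of
    micro-exon windows against whole domains, with neighbor-joining trees and
    bootstrap support for domain sequence sets. Includes a fully specified
    synthetic-genome generator with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
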
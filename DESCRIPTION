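Package: cdsannot
Title: Alignment-Free Identification and Hierarchical Annotation of
    Bacterial Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates protein-coding genes on assembled bacterial genomes
    using alignment-free sequence identification (AFSI): full-length MD5
    digests plus a length-equality check against a compiled, versioned,
    hierarchical protein-annotation store (UPS/IPS/PSC/PSCC, mirroring the
    UniRef100/UniRef90/UniRef50 cluster hierarchy), with pairwise-alignment
    homology fallback, curated expert-rule refinement, small-ORF (sORF)
    detection, origin-spanning CDS merging on circular replicons, and
    GFF3/JSON/FASTA/TSV export. Ships a deterministic synthetic-data
    generator producing toy reference proteomes and genomes with planted
    features for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    DBI,
    RSQLite,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    openssl,
    optparse,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    digest,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
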
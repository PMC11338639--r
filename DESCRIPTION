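Package: gutcodh
Title: Mining and Profiling Putative Anaerobic CO Dehydrogenase Genes in
    Gut Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering putative nickel-containing carbon
    monoxide dehydrogenase (pCODH, cooS/cdhA) genes in annotated prokaryotic
    genomes, validating candidates by conservation of the metal-cluster and
    acid-base active-site motifs, typing the genomic context around each
    validated gene into eight marker-defined classes, profiling
    Wood-Ljungdahl-pathway gene complements (including the Fdh-lacking form
    and alternative formate-acquisition routes), and quantifying transcript
    abundance (detection, RPKM, TPM) from metatranscriptome reads. Includes a
    deterministic synthetic-data generator that plants cooS homologs at
    controlled identity levels and motif states, marker-defined genomic
    contexts, WLP gene complements, and error-free reads, so every stage has
    a planted-truth recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
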
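Package: recodon
Title: Detection and Proteogenomic Validation of Stop Codon Reassignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects alternate genetic codes in assembled genome bins and
    validates them proteogenomically. Infers the meaning of each codon from
    amino acids observed at conserved columns of conserved protein families,
    normalized by the codon occurrence expected from genomic GC content;
    calls open reading frames under candidate codes with optional stop-codon
    readthrough; builds code-variant proteome databases with decoys and
    contaminants; and arbitrates between code hypotheses by counting
    identified tryptic peptides unique to each variant under ppm mass
    tolerance and spectral-count filters. Includes a seeded synthetic-data
    generator (genomes with a planted recoded stop codon, divergent homolog
    families, noisy peptide identifications) so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
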
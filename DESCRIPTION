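Package: tandemstop
Title: Tandem Stop Codon Overrepresentation in 3' UTRs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and quantifies tandem stop codons (TSCs), the in-frame
    backup stop codons found within the first few triplet positions of a
    gene's 3' untranslated region. Extracts fixed-length UTR windows
    downstream of annotated stop codons from genome FASTA plus GFF3
    annotation under organism-specific genetic codes (including ciliate
    UAR-to-glutamine and UGA reassignments), computes observed versus
    composition-expected first-occurrence stop counts at positions +1 to +6
    under a geometric null model, derives per-position and combined stop
    codon overrepresentation scores, compares organism groups with two-tailed
    Mann-Whitney tests under Bonferroni correction, and tests TSC enrichment
    in highly expressed genes via codon adaptation index quartiles. Ships a
    synthetic genome generator with controllable UTR composition, stop-codon
    dictionary, planted TSC enrichment and codon-usage bias for end-to-end
    validation without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
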
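Package: breakome
Title: Nucleotide-Resolution Hotspot Analysis of DNA Single-Strand Breaks and Abasic Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing strand-specific, single-nucleotide maps of DNA
    single-strand breaks (SSBs) and abasic (AP) sites. Calls break hotspots at
    several stringencies (sample-level and sample-shared), compares observed
    hotspot fractions against a uniform randomised-placement null, quantifies
    enrichment around transcription start sites (aggregate density profiles,
    the TSS enrichment ratio R and per-distance-bin odds ratios), measures
    template-strand bias, probes base-excision-repair provenance through
    SSB-AP overlap odds ratios and CG-dinucleotide context, extracts
    positional base-composition motifs, and associates TSS-proximal hotspots
    with gene expression. Ships a synthetic breakome generator with known
    planted structure (TSS enrichment, strand bias, shared hot positions,
    AP coupling, expression effects) so the full pipeline is testable
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
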
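Package: abassembly
Title: Template-Based Assembly of Antibody De Novo Peptide Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assembles antibody sequences from bottom-up proteomics de novo
    peptide reads by template matching. Short peptide reads (5-40 amino
    acids) with per-residue confidence scores are placed onto germline V/J/C
    template segments by local Smith-Waterman alignment under a
    mass-spectrometry-aware scoring alphabet (isobaric I/L scored as
    identical), combined into quality- and abundance-weighted consensus
    sequences, and recombined into full heavy and light chains with
    reconstruction of the CDRH3 junction from overhanging reads. Includes
    repertoire profiling (cladogram placement of unique and shared reads,
    per-template summaries, CDR read tables), a ground-truthed synthetic
    data generator (germline families, somatic hypermutation, multi-protease
    in-silico digestion, noisy reads), a batch-configuration pipeline driver
    and an HTML/TSV report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    Biostrings,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
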
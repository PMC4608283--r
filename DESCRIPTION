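Package: ltrscan
Title: Structural Annotation, Classification and Dating of Full-Length
    LTR Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects full-length LTR retrotransposons in genome
    assemblies from their structural hallmarks (paired long terminal
    repeats, target-site duplications, primer-binding site and
    polypurine tract), classifies them into the Copia and Gypsy
    superfamilies and their lineages from internal protein-coding
    domains and reverse-transcriptase phylogeny, clusters them into
    families under the 70/70 identity-coverage rule, counts genomic
    copies and chromosomal densities, dates insertions from LTR-pair
    divergence under the Kimura two-parameter model, and profiles
    per-element expression across tissues from short reads.  Ships a
    synthetic-genome simulator that plants elements with full ground
    truth so every stage is validated against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
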
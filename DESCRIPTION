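Package: rscout
Title: Receptor Gene-Family Scouting and Curation in Insect Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering and curating odorant-receptor
    (OR) and ionotropic-receptor (IR) gene families in insect genome assemblies.
    Implements a six-frame translated homology search with seeded X-drop
    extension, colinear exon chaining, GT-AG splice-site refinement, rule-based
    curation (fragment filtering, pseudogene and partial-model classification,
    allelic-variant exclusion versus tandem-paralog retention,
    reciprocal-best-hit naming), catalog identity statistics, intron-position
    conservation mapping on a common amino-acid scale, neighbor-joining
    phylogenies on JTT maximum-likelihood distances with bootstrap supports and
    ortholog-subgroup extraction, hydropathy-based transmembrane-segment
    counting, IR ligand-binding-domain annotation transfer, and relative
    expression analysis of qPCR Ct tables by the 2^-ddCt method. Includes a
    synthetic-genome generator with machine-readable ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
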
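Package: retrotarget
Title: Target-Site Specificity Analysis for Site-Specific Non-LTR Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the integration-site specificity of
    non-LTR retrotransposons that target multicopy genes such as U2
    snRNA genes. Provides a synthetic-genome generator that emulates
    tandem target-gene arrays and element insertions with known cleavage
    geometry (blunt joints, target site duplications, or 5' target
    deletions), a seed-and-extend local-alignment scanner with a
    Smith-Waterman oracle, 3'-terminus-anchored copy detection, junction
    flank classification with TSD and target-deletion inference, an
    intact-versus-disrupted target-gene census, family clustering with
    majority-rule consensus building and neighbor-joining trees, and an
    end-to-end pipeline that scores its own recovery against simulation
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    mclust,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
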
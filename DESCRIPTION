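Package: avb6suite
Title: Serology, TGF-beta Blocking Assays, Epithelial Signatures and
    Swiss-Roll Unrolling for Anti-Integrin Autoantibody Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studies of anti-alpha-v-beta-6 integrin
    autoantibodies in ulcerative colitis: ROC/Youden seropositivity
    thresholding and quantification of ELISA data against monoclonal
    standard curves; percent-inhibition statistics and inhibitory-sample
    classification for TGF-beta adhesion-blocking and reporter assays;
    per-sample epithelial lineage signature scoring from expression
    matrices; and digital unrolling of swiss-roll colon spatial
    transcriptomics into colon-length by crypt-lumen coordinates with
    goblet-cell composition profiles. Seeded generators emulate every
    input with known ground truth so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
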
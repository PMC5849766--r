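Package: targetid
Title: Integrative Copy-Number/Expression Addiction Scoring and RNAi Screen
    Analytics for Triple Negative Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements an integrative "Target ID" pipeline for prioritising
    candidate tumor addiction genes in triple negative breast cancer from paired
    gene-centric copy-number and expression profiles: copy-number gain and
    cis-correlation filters, binned weighted feature scoring with capped blocks,
    and a complementary expression-centered selection arm. Also provides RNAi
    screen analytics (plate-median normalization, normalized percent inhibition,
    Z-prime and replicate-concordance quality control, primary/top-10/secondary
    hit-calling rule engines), co-upregulation correlation/Ward clustering with a
    multi-gene composite expression score, and centrosome-abnormality biomarker
    scoring (centrosome amplification and pericentrin abnormality scores with
    regression and survival-split association reports). Synthetic-data
    generators with planted structure make every stage testable without access
    to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    mclust,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
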
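Package: plastidtraj
Title: Quantitative Trajectories of Chloroplast Biogenesis Along the
    Cereal Leaf Developmental Gradient
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs mesophyll-cell and chloroplast development along
    the base-to-tip developmental gradient of a cereal leaf. Maps leaf
    position to cell age, converts flow-cytometry S-phase fractions into
    cell-division correction factors, computes division-corrected plastid
    proliferation and growth rates with two-phase (plastid vs chloroplast
    build-up) detection, quantifies plastid genome copy number per haploid
    nuclear genome and plastid ribosome build-up (16S/18S rRNA ratio) from
    absolute qPCR standard curves, builds the dynamically-expressed-gene
    transcriptome map (RPM normalisation, expression filters, PCA with
    load-factor gene sets, weighted co-expression modules ordered by peak
    timing, hypergeometric enrichment), and ranks candidate transcriptional
    regulators against genes for chloroplast-targeted proteins with a
    tree-ensemble importance scheme. A synthetic-data generator with
    planted ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
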
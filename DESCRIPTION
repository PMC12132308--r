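Package: fearfish
Title: Behavioral Phenotyping and Brain Activity Networks for Zebrafish Fear Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for individual differences in
    zebrafish fear memory. Converts pose-tracked swimming (head/trunk/tail
    coordinates at 60 fps) into windowed kinematic features, classifies five
    swimming behaviors with a tuned random forest, summarizes per-fish
    freezing and evasion, computes Markov transition matrices of behavioral
    states, identifies behavioral clusters with a similarity-score k-nearest
    neighbor network and Louvain community detection, relates regional cfos
    cell counts to behavior with mean-centered behavioral partial least
    squares (permutation and bootstrap-ratio inference), and builds
    FDR-thresholded Pearson correlation networks between brain regions with
    confidence-interval based unique-edge detection. A synthetic-data module
    generates all pipeline inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
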
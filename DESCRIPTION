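Package: conemap
Title: Convex-Cone Matrix Factorisation for Calcium-Imaging Movies of the
    Insect Antennal Lobe
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts glomerular signals from calcium-imaging movies of the
    insect antennal lobe by a column-based non-negative matrix factorisation
    driven by greedy convex-cone fitting. Movies (frames by pixels) are
    z-score normalised and reduced by iterative PCA; extreme-vector selection
    then picks near-pure pixel time series, and a signal-refinement step
    averages out residual noise to produce glomerular maps, pure glomerular
    time series and denoised low-rank reconstructions of the movie. Includes
    a synthetic-movie generator with known ground-truth sources, a
    signal-recovery correlation score and a noise-sweep benchmark, movie I/O
    for multi-page TIFF stacks and delimited matrices, and preprocessing
    (movement stabilisation, baseline fold change, spatial and temporal
    filtering, image arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    ggplot2,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
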
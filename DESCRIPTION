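Package: fetalplanes
Title: Texture-Based Classification of Maternal-Fetal Ultrasound Planes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for classifying grayscale ultrasound standard planes from
    texture alone: gray-level co-occurrence matrix (GLCM) Haralick features,
    wrapper feature selection by particle swarm optimization, grey wolf
    optimization and their hybrid, and a fast radial basis function network
    classifier trained through an epsilon-insensitive-loss dual quadratic
    program with fuzzy C-means derived centers. Includes a seeded synthetic
    texture generator emulating speckled ultrasound-like images, class
    rebalancing utilities, per-class and macro evaluation metrics, and an
    end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    e1071,
    jpeg,
    optparse,
    png,
    quadprog,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
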
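Package: mirperm
Title: Permutation-Based Marker Selection for Two-Group miRNA Microarray Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Differential microRNA expression analysis for small two-group
    microarray designs using the signal-to-noise-ratio (SNR) statistic with an
    exhaustive or sampled permutation null, pooled ("smoothed") empirical
    p-values, Benjamini-Hochberg false-discovery-rate control and joint fold
    change / p / FDR significance calls. Includes probe-level background
    filtering and probe-to-miRNA collapsing, score-thresholded miRNA target
    mapping with cross-miRNA overlap accounting, Fisher-exact gene-set
    enrichment with per-set average p-values, replicate assay statistics
    (fold changes, Grubbs outlier screening, Welch t-tests, delta-delta-Ct
    quantification), a seeded synthetic-data generator that emulates a
    3-vs-3 probe-level miRNA array study with known ground truth, and an
    end-to-end pipeline driver with a reproducibility manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
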
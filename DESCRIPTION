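Package: litlinkr
Title: Literature-Based Discovery by Serial Co-Occurrence Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for literature-based discovery over corpora of scientific
    abstracts. Builds a positional inverted index over tokenized titles and
    abstracts, matches user-defined concepts (synonym sets, exact
    case-insensitive phrase matching), and scores pairwise term associations
    with the one-sided Fisher's exact test on 2x2 abstract-count tables.
    Supports single-stage pair search as well as serial two-stage open
    (A-B-C) and closed (A-B, B-C) discovery with p-value thresholding, a cap
    on surviving intermediate pairs, and prediction-score ranking. Significant
    pairs can be annotated with typed relations from a knowledge-graph triples
    file. Includes a synthetic-corpus generator with planted co-occurrence
    structure for calibration and power testing, and a command-line interface.
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
    readr,
    rlang,
    stringi,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
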
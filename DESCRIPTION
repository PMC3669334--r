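Package: tissuespec
Title: Cross-Species Discovery of Tissue-Specific Genes from GEO DataSets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies tissue-specific genes from GEO DataSet (GDS) microarray
    expression tables for two species. Parses full SOFT files, averages
    replicate samples per tissue, computes a ratio-based tissue-specificity
    score (mean expression in a target tissue relative to the mean of the
    other tissues, and its reciprocal), ranks genes per target tissue,
    intersects top-ranked genes across species by symbol or an ortholog map,
    and confirms candidates with per-gene one-way ANOVA followed by Fisher's
    protected least significant difference test. Includes summary-statistics
    ANOVA for published mean/SEM tables, reference-gene normalization, a
    spike-in simulator that emits parseable SOFT files with known
    tissue-specific ground truth, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    dplyr,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
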
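Package: mucikit
Title: Screening and Quantification of Mucinolysome-Encoding Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering cellulosome-like mucin-degrading
    multi-enzyme systems (mucinolysomes) in gut bacterial genomes and
    metagenome-assembled genomes. Parses HMMER and dbCAN-style domain hit
    tables, filters and resolves per-protein domain architectures, applies a
    genome-level cohesin/dockerin/mucin-glycoside-hydrolase decision rule,
    scores predicted cohesin-dockerin complex structures with interface
    contact counts, interface plDDT and pDockQ, benchmarks predicted
    interaction matrices against experimental ground truth, computes breadth
    of coverage, average read depth, relative abundance, presence and
    prevalence from read-mapping results, and summarizes mucin-responsive
    differential gene expression. A seed-deterministic synthetic-data module
    generates fixtures with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
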
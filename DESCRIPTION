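Package: scarscope
Title: Double-Strand-Break Repair Outcome Analysis from Junction Scars,
    Resection Tracks, Reporter Assays and Foci Images
Version: 0.1.0
Authors@R:
    person("scarscope", "developers", email = "scarscope@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for quantifying how cells repair DNA
    double-strand breaks. Classifies translocation-junction reads into
    deletion, insertion and microhomology scars against a predicted
    blunt-fusion product; quantifies DNA end resection from END-seq-style
    coverage around AsiSI restriction motifs (binning, cut-site calling,
    peak-width resection distances, top-site ranking, heatmap matrices);
    scores homologous-recombination and theta-mediated end-joining
    reporter assays from digital droplet PCR counts; bins CRISPR clones
    by biallelic frameshift status; computes Mendelian cross expectations
    with lethality renormalization and chi-square goodness of fit;
    normalizes marker-chromosome counts; fits four-parameter log-logistic
    dose-response curves for IC50 estimation; and counts
    irradiation-induced nuclear foci by threshold segmentation. Every
    analysis stage is paired with a seeded synthetic-data generator that
    produces inputs with the assumed statistical structure plus matching
    ground-truth tables, so the whole pipeline is testable end to end
    without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
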
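Package: arseq
Title: Simulation and Analysis of Autonomous Replication Sequencing Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse AR-seq (autonomous replication
    sequencing) screens, in which a random fragment library from a
    multi-replicon bacterial genome is passed through host-transformation
    and plasmid re-isolation bottlenecks so that only clones carrying an
    autonomous replication sequence (ARS) persist. Provides a synthetic-data
    generator (genomes with duplications, clone libraries, paired-end reads,
    droplet digital PCR assays, flow-cytometry histograms, plasmid
    segregation trajectories), a self-contained paired-end read mapper with
    identity and length-fraction filters and an explicit multi-mapping
    policy, per-replicon composition and coverage analysis, windowed
    enrichment scoring and ARS candidate calling, Poisson-based ddPCR copy
    number estimation combined with flow-cytometry ploidy into per-cell
    plasmid copy ranges, Poisson-corrected protein distances with
    pairwise deletion and neighbor-joining tree construction, and an
    end-to-end pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
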
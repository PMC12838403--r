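Package: gagcluster
Title: Detection and Typing of Bacterial Isomerase-Reductase Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome mining of bacterial gene clusters encoding the
    nonhomologous isofunctional DHU isomerases (KduI, DhuI) and the
    short-chain dehydrogenase-reductase family reductases (KduD, DhuD)
    involved in glycosaminoglycan and pectin catabolism. Provides an
    internal protein search engine (affine-gap pairwise alignment,
    profile construction with decoy-calibrated full-sequence E-values),
    the iterative non-redundant query-selection procedure, intergenic
    distance based cluster pairing and classification into the 16
    possible isomerase-reductase configurations, tandem-cluster
    detection, strain-level possession and co-occurrence accounting,
    taxon and abundance summaries, a representative 16S selection rule,
    and seeded synthetic-genome generators with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
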
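#' Pipeline configuration
#'
#' Bundles the thresholds that govern the whole analysis. Defaults are the
#' study conditions: homologs accepted at full-sequence E < 1e-5, query
#' non-redundancy below 97% global identity, 20 selection rounds (21 queries
#' including the seed), isomerase-reductase pairing at an intergenic gap of
#' at most 500 bp, distance histograms cut at 1000 bp, and 16S representative
#' clustering at 90% identity.
#'
#' @param evalue_threshold full-sequence E-value acceptance threshold.
#' @param identity_threshold percent identity ceiling for query redundancy.
#' @param selection_rounds number of iterative query-selection rounds.
#' @param cluster_gap_bp maximum intergenic gap (bp) for a cluster call.
#' @param plot_gap_bp histogram cutoff (bp) for distance tables.
#' @param rep16s_identity percent identity threshold for 16S centroid
#'   clustering.
#' @param rng_seed integer seed used by seeded internals (decoy shuffling).
#' @return An object of class `cluster_config` (a validated list).
#' @examples
#' cfg <- cluster_config()
#' cfg$cluster_gap_bp
#' @export
cluster_config <- function(evalue_threshold = 1e-5,
                           identity_threshold = 97,
                           selection_rounds = 20L,
                           cluster_gap_bp = 500L,
                           plot_gap_bp = 1000L,
                           rep16s_identity = 90,
                           rng_seed = 1L) {
  stopifnot(evalue_threshold > 0,
            identity_threshold > 0, identity_threshold <= 100,
            rep16s_identity > 0, rep16s_identity <= 100,
            selection_rounds >= 1, cluster_gap_bp >= 0, plot_gap_bp > 0)
  structure(list(evalue_threshold = evalue_threshold,
                 identity_threshold = identity_threshold,
                 selection_rounds = as.integer(selection_rounds),
                 cluster_gap_bp = as.integer(cluster_gap_bp),
                 plot_gap_bp = as.integer(plot_gap_bp),
                 rep16s_identity = rep16s_identity,
                 rng_seed = as.integer(rng_seed)),
            class = "cluster_config")
}

#' @export
print.cluster_config <- function(x, ...) {
  cat("cluster_config:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
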
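# End-to-end orchestration: query selection -> family profiles -> profile
# search -> family assignment -> cluster calls -> tandem chains ->
# possession/co-occurrence/separate-loci -> taxon summaries, with optional
# abundance, habitat and 16S stages. Stages communicate through plain data
# frames (written as TSVs when an output directory is given) so any stage
# can be rerun independently.

write_stage <- function(x, out_dir, name) {
  if (is.null(out_dir)) return(NULL)
  path <- file.path(out_dir, paste0(name, ".tsv"))
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full cluster-mining pipeline
#'
#' Executes, in order: per-family iterative query selection, profile
#' construction and calibration, profile search over the protein universe,
#' best-hit family assignment, cluster pairing/typing per genome, tandem
#' merging, possession matrix, co-occurrence ratios, separate-loci
#' accounting, distance tables, and type-by-phylum summaries (plus optional
#' abundance-by-type, habitat-by-type and representative-16S stages).
#' Deterministic under a fixed `cfg$rng_seed`.
#'
#' @param annotations named list of [genome_annotation()] objects (gene ids
#'   must be unique across the set, e.g. genome-prefixed).
#' @param seed_proteins named character vector of seed proteins; names are
#'   family labels (a subset of the 10 known families).
#' @param lineages lineage data.frame, or NULL (strains then summarize as
#'   "unclassified" with a warning).
#' @param cfg a [cluster_config()].
#' @param abundance optional long abundance data.frame (sample_id,
#'   genome_id, abundance).
#' @param habitat optional habitat score data.frame (genome_id + category
#'   columns).
#' @param rep16s optional named nucleotide sequences for representative
#'   selection.
#' @param out_dir optional directory for stage TSVs.
#' @return list of stage results plus a `manifest` (config snapshot, input
#'   sizes, per-stage output paths, seeds).
#' @export
run_all <- function(annotations, seed_proteins, lineages = NULL,
                    cfg = cluster_config(), abundance = NULL, habitat = NULL,
                    rep16s = NULL, out_dir = NULL) {
  stopifnot(length(annotations) >= 1, !is.null(names(seed_proteins)),
            all(names(seed_proteins) %in% FAMILIES))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  gene_genome <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(genome_id = a$genome_id, gene_id = a$genes$gene_id,
               protein = a$genes$protein, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(gene_genome$gene_id)) {
    stopf("gene ids must be unique across genomes")
  }
  universe <- setNames(gene_genome$protein, gene_genome$gene_id)
  universe <- universe[nzchar(universe)]
  paths <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  hits <- list(); query_sets <- list(); profiles <- list()
  for (fam in names(seed_proteins)) {
    qs <- run_stage("select_queries",
                    select_queries(setNames(seed_proteins[fam],
                                            paste0(fam, "_seed")),
                                   fam, universe, cfg))
    prof <- run_stage("family_profile", family_profile(qs))
    cal <- run_stage("calibrate_evalues",
                     calibrate_evalues(prof, universe, seed = cfg$rng_seed))
    h <- run_stage("profile_search",
                   profile_search(prof, universe, cal, cfg$evalue_threshold,
                                  family = fam))
    query_sets[[fam]] <- qs
    profiles[[fam]] <- prof
    hits[[fam]] <- h
  }
  hits <- do.call(rbind, hits)
  hits <- merge(hits, gene_genome[, c("gene_id", "genome_id")], by = "gene_id",
                sort = TRUE)
  assignments <- run_stage("assign_families", assign_families(hits, cfg))
  paths$assignments <- write_stage(assignments, out_dir, "assignments")

  calls <- do.call(rbind, lapply(annotations, function(a) {
    find_pairs(a, assignments[assignments$genome_id == a$genome_id, ], cfg)
  }))
  rownames(calls) <- NULL
  tandems <- do.call(rbind, lapply(split(calls, calls$genome_id), merge_tandem))
  if (is.null(tandems)) tandems <- merge_tandem(calls[0, ])
  rownames(tandems) <- NULL
  paths$calls <- write_stage(calls, out_dir, "calls")
  paths$tandems <- write_stage(tandems, out_dir, "tandems")

  genome_ids <- vapply(annotations, `[[`, character(1), "genome_id")
  pm <- run_stage("possession_matrix",
                  possession_matrix(assignments, calls, genome_ids))
  cooc <- cooccurrence_ratios(pm)
  seploci <- separate_loci(pm)
  dists <- distance_table(calls, cfg)
  paths$cooccurrence <- write_stage(cooc, out_dir, "cooccurrence")
  paths$distance_summary <- write_stage(dists$summary, out_dir, "distance_summary")
  paths$possession_presence <- write_stage(
    cbind(genome_id = rownames(pm$presence), pm$presence), out_dir,
    "possession_presence")
  paths$possession_copies <- write_stage(
    cbind(genome_id = rownames(pm$copies), pm$copies), out_dir,
    "possession_copies")

  if (is.null(lineages)) {
    warnf("no lineage table supplied; phylum summaries use 'unclassified'")
    lineages <- data.frame(genome_id = genome_ids, phylum = "unclassified",
                           family = "", genus = "", species = "",
                           stringsAsFactors = FALSE)
  }
  tbp <- run_stage("type_by_phylum",
                   suppressWarnings(type_by_phylum(pm, lineages)))

  abt <- if (!is.null(abundance)) {
    run_stage("abundance_by_type", abundance_by_type(abundance, pm))
  }
  hbt <- if (!is.null(habitat)) {
    run_stage("habitat_by_type", habitat_by_type(habitat, pm))
  }
  rep16 <- if (!is.null(rep16s)) {
    run_stage("select_rep_16s", select_rep_16s(rep16s, cfg))
  }

  manifest <- list(config = unclass(cfg),
                   n_genomes = length(annotations),
                   n_proteins = length(universe),
                   n_hits = nrow(hits),
                   n_assignments = nrow(assignments),
                   n_calls = nrow(calls),
                   n_tandems = nrow(tandems),
                   families = names(seed_proteins),
                   output_paths = paths)
  list(query_sets = query_sets, profiles = profiles, hits = hits,
       assignments = assignments, calls = calls, tandems = tandems,
       possession = pm, cooccurrence = cooc, separate_loci = seploci,
       distance = dists, type_by_phylum = tbp, abundance_by_type = abt,
       habitat_by_type = hbt, rep16s = rep16, manifest = manifest)
}
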
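# Downstream aggregations: type x phylum tables, abundance-by-type with rank
# tests, habitat-score-by-type, and the representative-16S selection rule.

#' Cluster-type by phylum strain counts and proportions
#'
#' A strain positive for two labels (e.g. via a tandem cluster) counts once
#' under each label. Strains without a lineage are grouped under
#' "unclassified" with a warning.
#'
#' @param pm a [possession_matrix()].
#' @param lineages data.frame with genome_id and phylum (see
#'   [read_lineage_table()]).
#' @return list: `counts` (label x phylum matrix), `prop_by_type` (rows sum
#'   to 1), `prop_by_phylum` (columns sum to 1 over labels), `type_totals`.
#' @export
type_by_phylum <- function(pm, lineages) {
  pres <- pm$presence
  labels <- enumerate_configurations()
  phy <- setNames(lineages$phylum, lineages$genome_id)
  strains <- rownames(pres)
  strain_phy <- setNames(unname(phy[strains]), strains)
  pos <- rownames(pres)[pres$any_cluster]
  n_missing <- sum(is.na(strain_phy[pos]) | !nzchar(strain_phy[pos]))
  if (n_missing) {
    warnf("%d cluster-positive strain(s) without lineage grouped as 'unclassified'",
          n_missing)
  }
  strain_phy[is.na(strain_phy) | !nzchar(strain_phy)] <- "unclassified"
  phyla <- sort(unique(strain_phy[pos]))
  if (!length(phyla)) phyla <- "unclassified"
  counts <- matrix(0L, length(labels), length(phyla),
                   dimnames = list(labels, phyla))
  for (l in labels) {
    who <- strains[pres[[l]]]
    if (length(who)) {
      t <- table(factor(strain_phy[who], levels = phyla))
      counts[l, ] <- as.integer(t)
    }
  }
  totals <- rowSums(counts)
  prop_by_type <- counts / ifelse(totals > 0, totals, 1)
  csums <- colSums(counts)
  prop_by_phylum <- t(t(counts) / ifelse(csums > 0, csums, 1))
  list(counts = counts, prop_by_type = prop_by_type,
       prop_by_phylum = prop_by_phylum, type_totals = totals)
}

#' Per-sample cluster-type abundance with rank tests
#'
#' Per sample and cluster-type label, the summed relative abundance of
#' label-positive strains (a strain positive for two labels contributes to
#' both, mirroring per-type totals elsewhere). An omnibus Kruskal-Wallis
#' test and two-sided pairwise Wilcoxon rank-sum tests are run on the raw
#' sums and, in parallel, on per-carrier-strain abundances (the sum divided
#' by the number of label-positive strains). The raw sums are the quantity
#' plotted in per-type abundance figures, but their rank tests confound
#' abundance with type prevalence: a type carried by more strains sums
#' higher even when every strain is drawn from the same abundance
#' distribution. The per-strain scale removes that confound, so the
#' compound enrichment flag (`top_label`, `top_significant`) is defined on
#' it.
#'
#' @param ab long data.frame: sample_id, genome_id, abundance (fractions).
#' @param pm a [possession_matrix()].
#' @param labels labels to aggregate (default: every label with at least one
#'   positive strain).
#' @param alpha significance level for the compound top-type flag.
#' @return list: `abundance` (long sample_id/label/abundance/
#'   abundance_per_strain), `cohort_mean` (per-label means over samples on
#'   both scales), `kruskal_p`/`pairwise_p` (raw sums), `kruskal_p_strain`/
#'   `pairwise_p_strain` (per-strain scale; pairwise matrices from
#'   [stats::pairwise.wilcox.test()] with `p.adjust.method = "none"`),
#'   `top_label` (highest per-strain cohort mean) and `top_significant`
#'   (TRUE when the omnibus and every pairwise test of the top label
#'   against the others fall below `alpha` on the per-strain scale - the
#'   compound claim "this type is significantly higher than all others").
#' @export
abundance_by_type <- function(ab, pm, labels = NULL, alpha = 0.01) {
  stopifnot(all(c("sample_id", "genome_id", "abundance") %in% names(ab)))
  pres <- pm$presence
  overlap <- intersect(unique(ab$genome_id), rownames(pres))
  if (!length(overlap)) stopf("no overlap between abundance table and possession matrix")
  if (is.null(labels)) {
    labels <- enumerate_configurations()
    labels <- labels[vapply(labels, function(l) any(pres[[l]]), logical(1))]
  }
  if (!length(labels)) stopf("no cluster-positive strains to aggregate")
  samples <- sort(unique(ab$sample_id))
  n_strains <- vapply(labels, function(l) sum(pres[[l]]), integer(1))
  rows <- list()
  for (l in labels) {
    strains <- rownames(pres)[pres[[l]]]
    sub <- ab[ab$genome_id %in% strains, , drop = FALSE]
    sums <- tapply(sub$abundance, factor(sub$sample_id, levels = samples), sum)
    sums[is.na(sums)] <- 0
    rows[[l]] <- data.frame(sample_id = samples, label = l,
                            abundance = as.numeric(sums),
                            abundance_per_strain = as.numeric(sums) / n_strains[[l]],
                            stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  rownames(long) <- NULL
  flab <- factor(long$label)
  kw <- kruskal.test(long$abundance, flab)
  kw_strain <- kruskal.test(long$abundance_per_strain, flab)
  pw <- pw_strain <- NULL
  if (length(labels) > 1L) {
    pw <- suppressWarnings(pairwise.wilcox.test(long$abundance, flab,
                                                p.adjust.method = "none"))$p.value
    pw_strain <- suppressWarnings(
      pairwise.wilcox.test(long$abundance_per_strain, flab,
                           p.adjust.method = "none"))$p.value
  }
  means <- tapply(long$abundance, long$label, mean)
  means_strain <- tapply(long$abundance_per_strain, long$label, mean)
  top <- names(means_strain)[which.max(means_strain)]
  top_sig <- if (is.null(pw_strain)) FALSE else {
    p <- c(if (top %in% rownames(pw_strain)) pw_strain[top, ],
           if (top %in% colnames(pw_strain)) pw_strain[, top])
    p <- p[!is.na(p)]
    isTRUE(kw_strain$p.value < alpha) && length(p) && all(p < alpha)
  }
  list(abundance = long,
       cohort_mean = data.frame(label = names(means),
                                mean_abundance = as.numeric(means),
                                mean_abundance_per_strain =
                                  as.numeric(means_strain[names(means)]),
                                stringsAsFactors = FALSE),
       kruskal_p = kw$p.value, pairwise_p = pw,
       kruskal_p_strain = kw_strain$p.value, pairwise_p_strain = pw_strain,
       top_label = top, top_significant = top_sig)
}

#' Habitat preference score means by cluster type
#'
#' Per label and habitat category, the mean score over label-positive
#' strains, flagged above/below the across-label mean for that category.
#' When `categories` is NULL, categories are kept only if their mean exceeds
#' `min_score` for at least one label. Labels without positive strains are
#' excluded.
#'
#' @param scores data.frame: genome_id plus one numeric column per category.
#' @param pm a [possession_matrix()].
#' @param categories category columns to keep (NULL = auto-filter).
#' @param min_score auto-filter threshold.
#' @return list: `means` (label x category), `overall` (per-category mean
#'   across labels), `flags` ("above"/"below").
#' @export
habitat_by_type <- function(scores, pm, categories = NULL, min_score = 10) {
  stopifnot("genome_id" %in% names(scores))
  pres <- pm$presence
  all_cats <- setdiff(names(scores), "genome_id")
  labels <- enumerate_configurations()
  labels <- labels[vapply(labels, function(l) any(pres[[l]]), logical(1))]
  if (!length(labels)) stopf("no cluster-positive strains")
  sc <- scores[match(rownames(pres), scores$genome_id), all_cats, drop = FALSE]
  means <- matrix(NA_real_, length(labels), length(all_cats),
                  dimnames = list(labels, all_cats))
  for (l in labels) {
    sub <- sc[pres[[l]], , drop = FALSE]
    means[l, ] <- colMeans(sub, na.rm = TRUE)
  }
  if (is.null(categories)) {
    keep <- apply(means, 2, function(v) any(v > min_score, na.rm = TRUE))
    categories <- all_cats[keep]
  }
  means <- means[, categories, drop = FALSE]
  overall <- colMeans(means, na.rm = TRUE)
  flags <- ifelse(t(t(means) > overall), "above", "below")
  list(means = means, overall = overall, flags = flags)
}

#' Select a representative 16S sequence by greedy centroid clustering
#'
#' Sequences are processed in length-descending order (ties by id); each
#' joins the first existing centroid with global nucleotide identity at or
#' above the threshold, otherwise it founds a new cluster. The centroid of
#' the largest cluster is returned; a size tie goes to the longer centroid
#' (then lexicographic id).
#'
#' @param seqs named character vector of nucleotide sequences (or a
#'   DNAStringSet).
#' @param cfg a [cluster_config()] (threshold `rep16s_identity`).
#' @param model nucleotide substitution model.
#' @return list: `representative_id`, `representative`, `clusters`
#'   (data.frame seq_id, centroid_id, identity_pct).
#' @export
select_rep_16s <- function(seqs, cfg = cluster_config(),
                           model = substitution_model("nucleotide")) {
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  if (!length(seqs)) stopf("no 16S sequences supplied")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  centroids <- integer(0) # indices into seqs, in founding order
  assign_df <- data.frame(seq_id = character(0), centroid_id = character(0),
                          identity_pct = numeric(0), stringsAsFactors = FALSE)
  membership <- integer(length(seqs))
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(centroids)) {
      idy <- global_identity(seqs[[i]], seqs[[centroids[k]]], model)
      if (idy >= cfg$rep16s_identity) {
        membership[i] <- k
        assign_df <- rbind(assign_df, data.frame(
          seq_id = names(seqs)[i], centroid_id = names(seqs)[centroids[k]],
          identity_pct = idy, stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, i)
      membership[i] <- length(centroids)
      assign_df <- rbind(assign_df, data.frame(
        seq_id = names(seqs)[i], centroid_id = names(seqs)[i],
        identity_pct = 100, stringsAsFactors = FALSE))
    }
  }
  sizes <- tabulate(membership, nbins = length(centroids))
  cen_len <- nchar(seqs[centroids])
  cen_id <- names(seqs)[centroids]
  pick <- order(-sizes, -cen_len, cen_id)[1]
  list(representative_id = cen_id[pick],
       representative = unname(seqs[[centroids[pick]]]),
       clusters = assign_df)
}
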
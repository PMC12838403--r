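# Strain-level inventories: best-hit family assignment, possession matrix,
# co-occurrence ratios with the auxiliary DHU-pathway families, and the
# separate-loci accounting of cluster-negative strains.

#' Assign one family per gene from combined search hits
#'
#' Hits from the (cross-reacting) family profiles are disambiguated by the
#' best-hit rule: per gene keep the family with the minimum E-value (ties:
#' maximum score, then the fixed family priority kduI, dhuI, kduD, dhuD,
#' ugl, ogl, yteR, kdgA, kdgK, kdgF). Genes whose best E-value does not
#' beat the threshold are dropped.
#'
#' @param hits data.frame with gene_id, family, score, evalue (optionally
#'   genome_id, carried through).
#' @param cfg a [cluster_config()].
#' @return data.frame with one row per assigned gene.
#' @export
assign_families <- function(hits, cfg = cluster_config()) {
  cols <- c(intersect("genome_id", names(hits)),
            c("gene_id", "family", "score", "evalue"))
  empty <- hits[0, cols, drop = FALSE]
  if (!nrow(hits)) return(empty)
  prio <- match(hits$family, FAMILIES)
  ord <- order(hits$gene_id, hits$evalue, -hits$score, prio)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[!duplicated(hits$gene_id), , drop = FALSE]
  best <- best[best$evalue < cfg$evalue_threshold, cols, drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Strain x family/type possession matrix
#'
#' Boolean possession of the 10 gene families, the 16 cluster-type labels
#' and `any_cluster` (the OR over the label columns), plus per-family copy
#' counts. Copy counts are deliberately uncapped: extreme duplications are
#' reported as-is.
#'
#' @param assignments [assign_families()] output with a genome_id column.
#' @param calls combined [find_pairs()] output.
#' @param genome_ids all strain ids (strains without genes still get rows).
#' @return A `possession_matrix`: list with `presence` (logical data.frame,
#'   rownames = genome ids) and `copies` (integer data.frame, families).
#' @export
possession_matrix <- function(assignments, calls, genome_ids) {
  genome_ids <- unique(as.character(genome_ids))
  labels <- enumerate_configurations()
  pres <- matrix(FALSE, nrow = length(genome_ids),
                 ncol = length(FAMILIES) + length(labels) + 1L,
                 dimnames = list(genome_ids, c(FAMILIES, labels, "any_cluster")))
  copies <- matrix(0L, nrow = length(genome_ids), ncol = length(FAMILIES),
                   dimnames = list(genome_ids, FAMILIES))
  if (nrow(assignments)) {
    stopifnot("genome_id" %in% names(assignments))
    tab <- table(factor(assignments$genome_id, levels = genome_ids),
                 factor(assignments$family, levels = FAMILIES))
    copies[] <- as.integer(tab)
    pres[, FAMILIES] <- copies > 0L
  }
  if (nrow(calls)) {
    for (k in seq_len(nrow(calls))) {
      pres[calls$genome_id[k], calls$label[k]] <- TRUE
    }
  }
  pres[, "any_cluster"] <- rowSums(pres[, labels, drop = FALSE]) > 0L
  structure(list(presence = as.data.frame(pres), copies = as.data.frame(copies)),
            class = "possession_matrix")
}

#' @export
print.possession_matrix <- function(x, ...) {
  cat(sprintf("possession_matrix: %d strains, %d cluster-positive\n",
              nrow(x$presence), sum(x$presence$any_cluster)))
  invisible(x)
}

#' Co-occurrence of cluster types with auxiliary gene families
#'
#' For each cluster-type label (or overall, `by_label = FALSE`), the fraction
#' of positive strains that also carry each auxiliary family; numerator and
#' denominator are reported alongside. With `unit = "cluster"` the
#' denominator is cluster calls rather than strains (each call counts once,
#' checked against its own strain's possession).
#'
#' @param pm a [possession_matrix()].
#' @param aux auxiliary family columns to cross-tabulate.
#' @param by_label per-label (default) or overall.
#' @param unit `"strain"` or `"cluster"`; the latter requires `calls`.
#' @param calls combined [find_pairs()] output (cluster unit only).
#' @return data.frame: label, family, n, N, ratio (NA when N = 0).
#' @export
cooccurrence_ratios <- function(pm, aux = AUX_FAMILIES, by_label = TRUE,
                                unit = c("strain", "cluster"), calls = NULL) {
  unit <- match.arg(unit)
  pres <- pm$presence
  labels <- if (by_label) enumerate_configurations() else "any_cluster"
  rows <- list()
  for (l in labels) {
    for (a in aux) {
      if (unit == "strain") {
        N <- sum(pres[[l]])
        n <- sum(pres[[l]] & pres[[a]])
      } else {
        stopifnot(!is.null(calls))
        sub <- if (l == "any_cluster") calls else calls[calls$label == l, , drop = FALSE]
        N <- nrow(sub)
        n <- sum(pres[sub$genome_id, a])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        label = l, family = a, n = n, N = N,
        ratio = if (N > 0) n / N else NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Separate-loci accounting of cluster-negative strains
#'
#' Restricted to strains with no cluster of any type: per-family possession
#' counts, the cross-tabulations kduI & kduD, dhuI & dhuD, dhuI & kduD, and
#' the count of strains lacking all four core families.
#'
#' @param pm a [possession_matrix()].
#' @return list: `n_cluster_negative`, `family_counts` (named integer),
#'   `crosstab` (data.frame condition, n, N), `lacks_all_core`.
#' @export
separate_loci <- function(pm) {
  pres <- pm$presence
  neg <- pres[!pres$any_cluster, , drop = FALSE]
  core <- c("kduI", "kduD", "dhuI", "dhuD")
  crosstab <- data.frame(
    condition = c("kduI_with_kduD", "dhuI_with_dhuD", "dhuI_with_kduD"),
    n = c(sum(neg$kduI & neg$kduD), sum(neg$dhuI & neg$dhuD),
          sum(neg$dhuI & neg$kduD)),
    N = c(sum(neg$kduI), sum(neg$dhuI), sum(neg$dhuI)),
    stringsAsFactors = FALSE)
  list(n_cluster_negative = nrow(neg),
       family_counts = colSums(neg[, FAMILIES, drop = FALSE]),
       crosstab = crosstab,
       lacks_all_core = sum(rowSums(neg[, core, drop = FALSE]) == 0L))
}
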
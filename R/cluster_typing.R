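# Cluster pairing and typing. An isomerase (kduI or dhuI) and a reductase
# (kduD or dhuD) on the same contig whose intergenic gap is at most the
# configured cutoff (default 500 bp) form a putative cluster, classified
# into one of 16 configurations: 8 parallel types A-H named by gene content
# and transcription order, plus 8 antiparallel types Ac-Hc.
#
# Parallel letter map (upstream gene first in transcription order):
#   A kduI-kduD   B kduD-kduI   C dhuI-dhuD   D dhuD-dhuI
#   E kduI-dhuD   F dhuD-kduI   G dhuI-kduD   H kduD-dhuI
# Antiparallel convention: for a content pair with parallel letters X
# (isomerase-first) and Y (reductase-first), Xc = divergent arrangement
# (adjacent 5' ends), Yc = convergent (adjacent 3' ends). The convention is
# isolated here so it can be corrected in one place.

PARALLEL_LETTERS <- data.frame(
  letter = LETTERS[1:8],
  iso_family = c("kduI", "kduI", "dhuI", "dhuI", "kduI", "kduI", "dhuI", "dhuI"),
  red_family = c("kduD", "kduD", "dhuD", "dhuD", "dhuD", "dhuD", "kduD", "kduD"),
  iso_first = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
  stringsAsFactors = FALSE
)

#' All 16 cluster-type labels
#'
#' 2 isomerases x 2 reductases x 2 transcription orders give the 8 parallel
#' types A-H; each of the 4 content pairs additionally admits divergent and
#' convergent antiparallel arrangements, giving Ac-Hc.
#'
#' @return Character vector of the 16 distinct labels.
#' @examples
#' enumerate_configurations()
#' @export
enumerate_configurations <- function() {
  c(LETTERS[1:8], paste0(LETTERS[1:8], "c"))
}

#' Intergenic gap between two genes on one contig
#'
#' With u the gene with the smaller start and v the other, the gap is
#' `max(0, v$start - u$end - 1)`: abutting genes give 0 and overlapping
#' genes are clamped to 0. Symmetric in argument order.
#'
#' @param g1,g2 gene records (lists or one-row data.frames with contig_id,
#'   start, end).
#' @return Integer gap in bp.
#' @examples
#' intergenic_gap(list(contig_id = "c", start = 1, end = 1000),
#'                list(contig_id = "c", start = 1100, end = 2000)) # 99
#' @export
intergenic_gap <- function(g1, g2) {
  if (g1$contig_id != g2$contig_id) {
    stopf("genes are on different contigs ('%s' vs '%s')",
          g1$contig_id, g2$contig_id)
  }
  if (g1$start > g2$start) { tmp <- g1; g1 <- g2; g2 <- tmp }
  max(0L, as.integer(g2$start) - as.integer(g1$end) - 1L)
}

#' Classify an isomerase-reductase pair into one of the 16 types
#'
#' Each gene is a list with contig_id, start, end, strand and family
#' (isomerase in kduI/dhuI, reductase in kduD/dhuD). Parallel pairs are
#' labeled by transcription order (the upstream gene - smaller coordinate on
#' `+`, larger on `-` - is named first); antiparallel pairs get the
#' content-matched `c` label (divergent = isomerase-first letter, convergent
#' = reductase-first letter). Reverse-complementing the contig does not
#' change the label.
#'
#' @param iso isomerase gene record (with `family`).
#' @param red reductase gene record (with `family`).
#' @return A single label from [enumerate_configurations()].
#' @export
classify_pair <- function(iso, red) {
  if (!iso$family %in% ISO_FAMILIES) {
    stopf("'%s' is not an isomerase family", iso$family)
  }
  if (!red$family %in% RED_FAMILIES) {
    stopf("'%s' is not a reductase family", red$family)
  }
  if (iso$contig_id != red$contig_id) stopf("genes are on different contigs")
  content <- PARALLEL_LETTERS[PARALLEL_LETTERS$iso_family == iso$family &
                              PARALLEL_LETTERS$red_family == red$family, ]
  x_letter <- content$letter[content$iso_first]    # isomerase-first order
  y_letter <- content$letter[!content$iso_first]   # reductase-first order
  if (iso$strand == red$strand) {
    # upstream (first-transcribed) gene: smaller start on '+', larger on '-'
    iso_first <- if (iso$strand == "+") iso$start < red$start else iso$start > red$start
    if (iso_first) x_letter else y_letter
  } else {
    left <- if (iso$start <= red$start) iso else red
    divergent <- left$strand == "-"
    paste0(if (divergent) x_letter else y_letter, "c")
  }
}

gene_record <- function(genes, i, family = NULL) {
  rec <- list(gene_id = genes$gene_id[i], contig_id = genes$contig_id[i],
              start = genes$start[i], end = genes$end[i],
              strand = genes$strand[i])
  if (!is.null(family)) rec$family <- family
  rec
}

#' Find and classify all isomerase-reductase cluster calls in a genome
#'
#' Every isomerase-reductase gene pair sharing a contig with intergenic gap
#' at most `cfg$cluster_gap_bp` becomes a call, regardless of relative
#' strand or intervening genes (which are recorded). One gene may appear in
#' several calls. Output is independent of gene input order.
#'
#' @param ann a [genome_annotation()].
#' @param assignments data.frame with gene_id and family columns (e.g. from
#'   [assign_families()]).
#' @param cfg a [cluster_config()].
#' @return data.frame of calls: genome_id, contig_id, iso_gene_id,
#'   iso_family, iso_start, red_gene_id, red_family, red_start, iso_strand,
#'   red_strand, label, gap_bp, intervening (comma-joined gene ids).
#' @export
find_pairs <- function(ann, assignments, cfg = cluster_config()) {
  empty <- data.frame(genome_id = character(0), contig_id = character(0),
                      iso_gene_id = character(0), iso_family = character(0),
                      iso_start = integer(0), red_gene_id = character(0),
                      red_family = character(0), red_start = integer(0),
                      iso_strand = character(0), red_strand = character(0),
                      label = character(0), gap_bp = integer(0),
                      intervening = character(0), stringsAsFactors = FALSE)
  genes <- ann$genes
  fam <- setNames(assignments$family, assignments$gene_id)
  fam <- fam[names(fam) %in% genes$gene_id]
  iso_ids <- names(fam)[fam %in% ISO_FAMILIES]
  red_ids <- names(fam)[fam %in% RED_FAMILIES]
  if (!length(iso_ids) || !length(red_ids)) return(empty)
  idx <- setNames(seq_len(nrow(genes)), genes$gene_id)
  rows <- list()
  for (ii in iso_ids) {
    for (ri in red_ids) {
      gi <- idx[[ii]]; gr <- idx[[ri]]
      if (genes$contig_id[gi] != genes$contig_id[gr]) next
      iso <- gene_record(genes, gi, fam[[ii]])
      red <- gene_record(genes, gr, fam[[ri]])
      gap <- intergenic_gap(iso, red)
      if (gap > cfg$cluster_gap_bp) next
      u <- if (iso$start <= red$start) iso else red
      v <- if (iso$start <= red$start) red else iso
      inter <- genes$gene_id[genes$contig_id == iso$contig_id &
                             genes$start > u$end & genes$end < v$start]
      inter <- setdiff(inter, c(iso$gene_id, red$gene_id))
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = ann$genome_id, contig_id = iso$contig_id,
        iso_gene_id = iso$gene_id, iso_family = iso$family,
        iso_start = iso$start, red_gene_id = red$gene_id,
        red_family = red$family, red_start = red$start,
        iso_strand = iso$strand, red_strand = red$strand,
        label = classify_pair(iso, red), gap_bp = gap,
        intervening = paste(sort(inter), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id,
                   pmin(genes$start[idx[out$iso_gene_id]],
                        genes$start[idx[out$red_gene_id]]),
                   out$iso_gene_id, out$red_gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge overlapping same-direction calls into tandem clusters
#'
#' Maximal chains of parallel calls that share a gene and run in the same
#' direction are reported as tandem clusters (three or more genes, e.g.
#' kduI-kduD-dhuI). Tandem detection never removes the constituent pair
#' calls: a tandem strain stays positive for each constituent type.
#' Antiparallel calls never enter chains.
#'
#' @param calls a [find_pairs()] data.frame from one genome.
#' @return data.frame: genome_id, contig_id, chain_string (families in
#'   transcription order, joined by `-`), gene_ids (comma-joined, same
#'   order), constituent_labels (comma-joined, sorted), n_genes.
#' @export
merge_tandem <- function(calls) {
  empty <- data.frame(genome_id = character(0), contig_id = character(0),
                      chain_string = character(0), gene_ids = character(0),
                      constituent_labels = character(0), n_genes = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(calls)) return(empty)
  par <- calls[!grepl("c$", calls$label), , drop = FALSE]
  n <- nrow(par)
  if (n < 2L) return(empty)
  comp <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      share <- length(intersect(c(par$iso_gene_id[i], par$red_gene_id[i]),
                                c(par$iso_gene_id[j], par$red_gene_id[j]))) > 0
      same_dir <- par$iso_strand[i] == par$iso_strand[j]
      if (share && same_dir && par$contig_id[i] == par$contig_id[j]) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  rows <- list()
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (length(members) < 2L) next
    gdf <- unique(rbind(
      data.frame(gene_id = par$iso_gene_id[members],
                 family = par$iso_family[members],
                 start = par$iso_start[members], stringsAsFactors = FALSE),
      data.frame(gene_id = par$red_gene_id[members],
                 family = par$red_family[members],
                 start = par$red_start[members], stringsAsFactors = FALSE)))
    # transcription order: ascending start on '+', descending on '-'
    ord <- order(gdf$start)
    if (par$iso_strand[members[1]] == "-") ord <- rev(ord)
    gdf <- gdf[ord, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = par$genome_id[members[1]],
      contig_id = par$contig_id[members[1]],
      chain_string = paste(gdf$family, collapse = "-"),
      gene_ids = paste(gdf$gene_id, collapse = ","),
      constituent_labels = paste(sort(par$label[members]), collapse = ","),
      n_genes = nrow(gdf), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$contig_id, out$gene_ids), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-type intergenic distance summaries
#'
#' For each observed label: call count, median and quartiles of the gap
#' (all calls already satisfy the cluster cutoff), and a histogram of gaps
#' in 50 bp bins up to `cfg$plot_gap_bp`.
#'
#' @param calls a [find_pairs()] data.frame (any number of genomes).
#' @param cfg a [cluster_config()].
#' @return list with `summary` (label, n, median_gap, q1_gap, q3_gap) and
#'   `histogram` (label, bin_start, bin_end, count) data.frames.
#' @export
distance_table <- function(calls, cfg = cluster_config()) {
  if (!nrow(calls)) {
    return(list(summary = data.frame(label = character(0), n = integer(0),
                                     median_gap = numeric(0), q1_gap = numeric(0),
                                     q3_gap = numeric(0)),
                histogram = data.frame(label = character(0), bin_start = integer(0),
                                       bin_end = integer(0), count = integer(0))))
  }
  labs <- sort(unique(calls$label))
  summ <- do.call(rbind, lapply(labs, function(l) {
    g <- calls$gap_bp[calls$label == l & calls$gap_bp <= cfg$cluster_gap_bp]
    data.frame(label = l, n = length(g), median_gap = median(g),
               q1_gap = unname(quantile(g, 0.25)),
               q3_gap = unname(quantile(g, 0.75)), stringsAsFactors = FALSE)
  }))
  breaks <- seq(0L, cfg$plot_gap_bp, by = 50L)
  hist_df <- do.call(rbind, lapply(labs, function(l) {
    g <- calls$gap_bp[calls$label == l & calls$gap_bp <= cfg$plot_gap_bp]
    bin <- pmin(g %/% 50L, length(breaks) - 2L)
    cnt <- tabulate(bin + 1L, nbins = length(breaks) - 1L)
    data.frame(label = l, bin_start = breaks[-length(breaks)],
               bin_end = breaks[-1], count = cnt, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- rownames(hist_df) <- NULL
  list(summary = summ, histogram = hist_df)
}
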
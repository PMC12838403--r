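# Data model and I/O for annotated genomes. Coordinates are 1-based
# inclusive (GFF3/GenBank convention); genes are stored by contig
# coordinates and sorted by (contig, start, gene_id); transcription order is
# computed on demand, never stored.

#' Construct a genome annotation
#'
#' @param genome_id genome identifier (e.g. an assembly accession).
#' @param contigs named numeric vector of contig lengths (bp).
#' @param genes data.frame with columns gene_id, contig_id, start, end,
#'   strand (`+`/`-`), protein (may be empty for non-coding features).
#' @return A `genome_annotation`: validated, proteins uppercased with a
#'   terminal stop stripped, genes sorted by (contig, start, gene_id).
#' @export
genome_annotation <- function(genome_id, contigs, genes) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  required <- c("gene_id", "contig_id", "start", "end", "strand", "protein")
  missing <- setdiff(required, names(genes))
  if (length(missing)) stopf("genes table lacks column(s): %s",
                             paste(missing, collapse = ", "))
  genes <- genes[required]
  genes$gene_id <- as.character(genes$gene_id)
  genes$contig_id <- as.character(genes$contig_id)
  genes$strand <- as.character(genes$strand)
  genes$protein <- toupper(sub("\\*$", "", as.character(genes$protein)))
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$gene_id)) {
    stopf("duplicate gene id(s): %s",
          paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  bad <- which(genes$start < 1L | genes$end < genes$start)
  if (length(bad)) stopf("gene '%s': invalid coordinates (start %d, end %d)",
                         genes$gene_id[bad[1]], genes$start[bad[1]], genes$end[bad[1]])
  if (!all(genes$strand %in% c("+", "-"))) {
    stopf("strand must be '+' or '-'")
  }
  contigs <- setNames(as.numeric(contigs), names(contigs))
  unknown <- setdiff(unique(genes$contig_id), names(contigs))
  if (length(unknown)) stopf("gene contig(s) missing from contig table: %s",
                             paste(unknown, collapse = ", "))
  too_long <- which(genes$end > contigs[genes$contig_id])
  if (length(too_long)) stopf("gene '%s' extends past the end of contig '%s'",
                              genes$gene_id[too_long[1]],
                              genes$contig_id[too_long[1]])
  genes <- genes[order(genes$contig_id, genes$start, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(genome_id = genome_id, contigs = contigs, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation '%s': %d contig(s), %d gene(s)\n",
              x$genome_id, length(x$contigs), nrow(x$genes)))
  invisible(x)
}

#' Read a genome annotation from GFF3 + protein FASTA
#'
#' CDS features carrying an `ID` attribute become genes; proteins are
#' attached by matching FASTA record ids (text before the first whitespace)
#' to those IDs. CDS without a matching protein get an empty protein with a
#' warning; unmatched FASTA records are ignored with a warning.
#'
#' @param gff_path path to a GFF3 file.
#' @param protein_fasta_path path to the matching protein FASTA.
#' @param genome_id genome identifier (default: GFF file stem).
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(gff_path, protein_fasta_path,
                            genome_id = sub("\\.gff3?(\\.gz)?$", "",
                                            basename(gff_path))) {
  lines <- readLines(gff_path, warn = FALSE)
  seqlens <- c()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      if (startsWith(ln, "##sequence-region")) {
        f <- strsplit(trimws(ln), "\\s+")[[1]]
        if (length(f) >= 4) seqlens[f[2]] <- as.numeric(f[4])
      }
      next
    }
    if (length(strsplit(ln, "\t", fixed = TRUE)[[1]]) != 9L) {
      stopf("malformed GFF line %d in '%s' (expected 9 tab-separated fields)",
            i, gff_path)
    }
  }
  gff <- rtracklayer::readGFF(gff_path)
  cds <- as.data.frame(gff[gff$type == "CDS", , drop = FALSE])
  if (!nrow(cds)) stopf("no CDS features in '%s'", gff_path)
  if (!"ID" %in% names(cds) || any(is.na(cds$ID))) {
    stopf("CDS features in '%s' must carry ID attributes", gff_path)
  }
  ids <- as.character(cds$ID)
  if (anyDuplicated(ids)) {
    stopf("duplicate CDS ID(s) in '%s': %s", gff_path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  aa <- Biostrings::readAAStringSet(protein_fasta_path)
  prot <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  matched <- intersect(ids, names(prot))
  if (length(setdiff(ids, names(prot)))) {
    warnf("%d CDS without a matching protein record (attached empty)",
          length(setdiff(ids, names(prot))))
  }
  extra <- setdiff(names(prot), ids)
  if (length(extra)) {
    warnf("%d protein record(s) without a matching CDS ignored", length(extra))
  }
  proteins <- setNames(rep("", length(ids)), ids)
  proteins[matched] <- prot[matched]
  genes <- data.frame(gene_id = ids,
                      contig_id = as.character(cds$seqid),
                      start = as.integer(cds$start),
                      end = as.integer(cds$end),
                      strand = as.character(cds$strand),
                      protein = unname(proteins),
                      stringsAsFactors = FALSE)
  contig_ids <- unique(genes$contig_id)
  contigs <- setNames(vapply(contig_ids, function(cid) {
    if (cid %in% names(seqlens)) seqlens[[cid]]
    else max(genes$end[genes$contig_id == cid])
  }, numeric(1)), contig_ids)
  genome_annotation(genome_id, contigs, genes)
}

#' Read genome annotation(s) from a flat gene table
#'
#' The TSV must have columns genome_id, contig_id, gene_id, start, end,
#' strand, protein (an optional `contig_length` column fixes contig sizes;
#' otherwise the max gene end per contig is used).
#'
#' @param tsv_path path to the table.
#' @return A [genome_annotation()] if the table holds one genome, otherwise
#'   a named list of annotations.
#' @export
read_gene_table <- function(tsv_path) {
  tab <- read.delim(tsv_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  required <- c("genome_id", "contig_id", "gene_id", "start", "end",
                "strand", "protein")
  missing <- setdiff(required, names(tab))
  if (length(missing)) stopf("gene table lacks column(s): %s",
                             paste(missing, collapse = ", "))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad)) stopf("row %d: non-integer %s '%s'", bad[1], col,
                           tab[[col]][bad[1]])
    tab[[col]] <- as.integer(v)
  }
  bad <- which(tab$end < tab$start)
  if (length(bad)) stopf("row %d (gene '%s'): end < start", bad[1],
                         tab$gene_id[bad[1]])
  tab$protein[is.na(tab$protein)] <- ""
  build_one <- function(sub) {
    cl <- if ("contig_length" %in% names(sub)) {
      lens <- suppressWarnings(as.numeric(sub$contig_length))
      tapply(lens, sub$contig_id, max)
    } else tapply(sub$end, sub$contig_id, max)
    genome_annotation(sub$genome_id[1], setNames(as.numeric(cl), names(cl)),
                      sub[, c("gene_id", "contig_id", "start", "end",
                              "strand", "protein")])
  }
  gids <- unique(tab$genome_id)
  if (length(gids) == 1L) return(build_one(tab))
  setNames(lapply(gids, function(g) build_one(tab[tab$genome_id == g, ])), gids)
}

#' Write annotation(s) to a flat gene table
#'
#' Inverse of [read_gene_table()]; the round trip preserves every field of
#' every gene exactly.
#'
#' @param ann a `genome_annotation` or list of them.
#' @param tsv_path output path.
#' @return `tsv_path`, invisibly.
#' @export
write_gene_table <- function(ann, tsv_path) {
  if (inherits(ann, "genome_annotation")) ann <- list(ann)
  rows <- do.call(rbind, lapply(ann, function(a) {
    g <- a$genes
    data.frame(genome_id = a$genome_id, contig_id = g$contig_id,
               gene_id = g$gene_id, start = g$start, end = g$end,
               strand = g$strand, protein = g$protein,
               contig_length = unname(a$contigs[g$contig_id]),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsv_path)
}

#' Read a taxonomy lineage table
#'
#' TSV with columns genome_id, phylum, family, genus, species (missing rank
#' columns are filled with empty strings).
#'
#' @param tsv_path path to the table.
#' @return data.frame of lineages.
#' @export
read_lineage_table <- function(tsv_path) {
  tab <- read.delim(tsv_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!"genome_id" %in% names(tab)) stopf("lineage table lacks 'genome_id'")
  if (any(!nzchar(tab$genome_id))) stopf("lineage table has empty genome_id")
  for (col in c("phylum", "family", "genus", "species")) {
    if (!col %in% names(tab)) tab[[col]] <- ""
  }
  tab[, c("genome_id", "phylum", "family", "genus", "species")]
}
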
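# Profile construction and glocal profile search. A profile is a
# position-specific log-odds model over match columns of a multiple
# alignment; scoring is glocal (the whole profile must align, the target
# sequence has free flanks), and full-sequence E-values come from the same
# shuffled-decoy calibration as pairwise searches.

# Robinson-Robinson amino-acid background frequencies
aa_background <- function() {
  bg <- c(A = 0.0785, R = 0.0512, N = 0.0448, D = 0.0536, C = 0.0192,
          Q = 0.0426, E = 0.0622, G = 0.0738, H = 0.0219, I = 0.0514,
          L = 0.0901, K = 0.0574, M = 0.0224, F = 0.0385, P = 0.0520,
          S = 0.0712, T = 0.0584, W = 0.0132, Y = 0.0321, V = 0.0644)
  bg / sum(bg)
}

#' Build a profile model from aligned sequences
#'
#' Alignment columns with a gap fraction below 50% become match columns;
#' emissions are pseudocount-smoothed log2-odds against background
#' frequencies. The wildcard `X` is uninformative (log-odds 0).
#'
#' @param aligned character vector of equal-length aligned sequences
#'   (gaps as `-`).
#' @param ids source query identifiers (defaults to names).
#' @param pseudocount Laplace pseudocount weight on the background.
#' @param max_gap_frac columns with at least this gap fraction are skipped.
#' @return A `profile_model`: emissions matrix (match columns x alphabet),
#'   insert/delete affine costs (bits), source query ids.
#' @export
build_profile <- function(aligned, ids = names(aligned), pseudocount = 1,
                          max_gap_frac = 0.5) {
  stopifnot(length(aligned) >= 1)
  aligned <- toupper(aligned)
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1L) {
    stopf("aligned sequences must have equal length")
  }
  mat <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  match_cols <- which(gap_frac < max_gap_frac)
  if (!length(match_cols)) stopf("no match columns (all columns are mostly gaps)")
  bg <- aa_background()
  aa20 <- names(bg)
  emis <- matrix(0, nrow = length(match_cols), ncol = length(AA_ALPHABET),
                 dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_along(match_cols)) {
    col <- mat[, match_cols[k]]
    col <- col[col %in% aa20]
    cnt <- table(factor(col, levels = aa20))
    p <- (as.numeric(cnt) + pseudocount * bg) / (length(col) + pseudocount)
    emis[k, aa20] <- log2(p / bg)
  }
  structure(list(emissions = emis,
                 n_match_columns = length(match_cols),
                 source_query_ids = ids %||% paste0("q", seq_along(aligned)),
                 ins_open = 3, ins_extend = 0.3,
                 del_open = 3, del_extend = 0.3),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("profile_model: %d match columns from %d queries\n",
              x$n_match_columns, length(x$source_query_ids)))
  invisible(x)
}

#' Glocal score of one sequence against a profile
#'
#' @param profile a [build_profile()] model.
#' @param seq protein string.
#' @param model substitution model (for residue encoding only).
#' @return numeric score in bits.
#' @export
profile_score <- function(profile, seq, model = default_protein_model()) {
  cpp_profile_score(profile$emissions, encode_seq(seq, model),
                    profile$ins_open, profile$ins_extend,
                    profile$del_open, profile$del_extend)
}

#' Search a protein database with a profile
#'
#' Scores every (non-empty) protein, converts scores to full-sequence
#' E-values via the calibration, and keeps hits with `evalue < threshold`,
#' sorted by E-value ascending then gene id. Results do not depend on the
#' database input order.
#'
#' @param profile a `profile_model`.
#' @param db a named character vector of proteins or a `genome_annotation`.
#' @param cal an [calibrate_evalues()] result for this profile/database.
#' @param threshold E-value threshold.
#' @param family family label to stamp on the hits.
#' @param model substitution model (residue encoding).
#' @return data.frame: gene_id, family, score, evalue.
#' @export
profile_search <- function(profile, db, cal, threshold = 1e-5,
                           family = NA_character_,
                           model = default_protein_model()) {
  if (inherits(db, "genome_annotation")) {
    db <- setNames(db$genes$protein, db$genes$gene_id)
  }
  db <- db[nzchar(db)]
  if (!length(db)) {
    return(data.frame(gene_id = character(0), family = character(0),
                      score = numeric(0), evalue = numeric(0)))
  }
  enc <- lapply(unname(db), encode_seq, model = model)
  scores <- cpp_profile_score_batch(profile$emissions, enc,
                                    profile$ins_open, profile$ins_extend,
                                    profile$del_open, profile$del_extend)
  ev <- evalue_from_score(cal, scores)
  keep <- which(ev < threshold)
  out <- data.frame(gene_id = names(db)[keep],
                    family = rep(family, length(keep)),
                    score = scores[keep], evalue = ev[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$evalue, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Center-star progressive multiple alignment
#'
#' Internal aligner for query sets: picks the sequence with the highest total
#' pairwise global score as the center (ties by id), aligns every other
#' sequence to it, and merges the pairwise alignments on center coordinates.
#' Deterministic; input order does not change the result.
#'
#' @param seqs named character vector of sequences.
#' @param model substitution model.
#' @return Named character vector of equal-length aligned sequences.
#' @export
align_queries <- function(seqs, model = default_protein_model()) {
  stopifnot(length(seqs) >= 1)
  if (is.null(names(seqs))) names(seqs) <- paste0("q", seq_along(seqs))
  if (length(seqs) == 1L) return(seqs)
  n <- length(seqs)
  enc <- lapply(seqs, encode_seq, model = model)
  total <- vapply(seq_len(n), function(i) {
    sum(cpp_score_batch(enc[[i]], enc[-i], model$score_matrix,
                        model$gap_open, model$gap_extend, FALSE))
  }, numeric(1))
  ord <- order(-total, names(seqs))
  center <- ord[1]
  others <- setdiff(seq_len(n), center)
  L <- length(enc[[center]])
  alphabet <- model$alphabet

  # per pairwise alignment: residue aligned to each center position (or gap),
  # and insertions in L+1 slots (before pos 1 ... after pos L)
  pair <- lapply(others, function(i) {
    al <- cpp_pair_align(enc[[center]], enc[[i]], model$score_matrix,
                         model$gap_open, model$gap_extend, FALSE)
    at <- rep("-", L)
    ins <- vector("list", L + 1)
    for (s in seq_len(L + 1)) ins[[s]] <- character(0)
    cpos <- 0L
    for (k in seq_along(al$a_aln)) {
      if (al$a_aln[k] >= 0L) {
        cpos <- cpos + 1L
        if (al$b_aln[k] >= 0L) at[cpos] <- alphabet[al$b_aln[k] + 1L]
      } else {
        ins[[cpos + 1L]] <- c(ins[[cpos + 1L]], alphabet[al$b_aln[k] + 1L])
      }
    }
    list(at = at, ins = ins)
  })
  ins_max <- vapply(seq_len(L + 1), function(s) {
    max(c(0L, vapply(pair, function(p) length(p$ins[[s]]), integer(1))))
  }, integer(1))

  emit <- function(at, ins) {
    parts <- character(0)
    for (s in seq_len(L + 1)) {
      pad <- c(ins[[s]], rep("-", ins_max[s] - length(ins[[s]])))
      parts <- c(parts, pad, if (s <= L) at[s] else character(0))
    }
    paste(parts, collapse = "")
  }
  center_chars <- alphabet[enc[[center]] + 1L]
  out <- character(n)
  out[center] <- emit(center_chars, lapply(seq_len(L + 1), function(s) character(0)))
  for (k in seq_along(others)) {
    out[others[k]] <- emit(pair[[k]]$at, pair[[k]]$ins)
  }
  names(out) <- names(seqs)
  out
}

#' Write / read a profile model as plain text
#'
#' A simple documented text format: header lines (`family`, `ins_open`,
#' `ins_extend`, `del_open`, `del_extend`, `source_query_ids`) followed by
#' one tab-separated emission row per match column, with the alphabet as
#' the column header. The round trip preserves the model exactly.
#'
#' @param profile a `profile_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# gagcluster profile v1",
               paste0("family\t", profile$family %||% "NA"),
               paste0("ins_open\t", profile$ins_open),
               paste0("ins_extend\t", profile$ins_extend),
               paste0("del_open\t", profile$del_open),
               paste0("del_extend\t", profile$del_extend),
               paste0("source_query_ids\t",
                      paste(profile$source_query_ids, collapse = ",")),
               paste(colnames(profile$emissions), collapse = "\t")), con)
  write.table(profile$emissions, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# gagcluster profile")) {
    stopf("'%s' is not a serialized profile", path)
  }
  hdr <- strsplit(lines[2:7], "\t", fixed = TRUE)
  vals <- setNames(vapply(hdr, `[`, character(1), 2),
                   vapply(hdr, `[`, character(1), 1))
  alphabet <- strsplit(lines[8], "\t", fixed = TRUE)[[1]]
  emis <- do.call(rbind, lapply(lines[-(1:8)], function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  colnames(emis) <- alphabet
  prof <- structure(list(emissions = emis, n_match_columns = nrow(emis),
                         source_query_ids = strsplit(vals[["source_query_ids"]],
                                                     ",", fixed = TRUE)[[1]],
                         ins_open = as.numeric(vals[["ins_open"]]),
                         ins_extend = as.numeric(vals[["ins_extend"]]),
                         del_open = as.numeric(vals[["del_open"]]),
                         del_extend = as.numeric(vals[["del_extend"]])),
                    class = "profile_model")
  if (!identical(vals[["family"]], "NA")) prof$family <- vals[["family"]]
  prof
}

#' Export an alignment in Stockholm format
#'
#' @param aligned named character vector of equal-length aligned sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(aligned, path) {
  stopifnot(!is.null(names(aligned)),
            length(unique(nchar(aligned))) == 1L)
  ids <- gsub("\\s", "_", names(aligned))
  writeLines(c("# STOCKHOLM 1.0",
               sprintf("%-*s %s", max(nchar(ids)), ids, unname(aligned)),
               "//"), path)
  invisible(path)
}
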
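# Full-sequence E-value machinery. The internal scorer is not BLAST, so its
# score statistics are fitted empirically: shuffled-decoy searches give a
# Gumbel null, and E-values follow the Karlin-Altschul form
# E = K * m * N * exp(-lambda * S) with N the database size in residues.

EULER_GAMMA <- 0.5772156649015329

shuffle_seq <- function(x) {
  paste(sample(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Calibrate E-values against shuffled decoys
#'
#' Scores the query (a protein for pairwise searches, or a [build_profile()]
#' model for profile searches) against composition-matched decoys obtained by
#' shuffling sequences drawn from the database, then fits Gumbel parameters
#' by the method of moments. Deterministic given `seed`.
#'
#' @param x a protein string or a `profile_model`.
#' @param db named character vector of database proteins.
#' @param decoys number of shuffled decoys (>= 50).
#' @param seed integer RNG seed.
#' @param model substitution model for pairwise scoring.
#' @return An `evalue_calibration`: `lambda`, `K`, `database_size` (residues),
#'   `decoy_count`, `rng_seed`, plus the effective query length.
#' @export
calibrate_evalues <- function(x, db, decoys = 200L, seed = 1L,
                              model = default_protein_model()) {
  db <- db[nzchar(db)]
  stopifnot(length(db) > 0, decoys >= 50)
  decoy_seqs <- with_seed(seed, {
    src <- db[sample.int(length(db), decoys, replace = TRUE)]
    vapply(src, shuffle_seq, character(1), USE.NAMES = FALSE)
  })
  enc <- lapply(decoy_seqs, encode_seq, model = model)
  if (inherits(x, "profile_model")) {
    scores <- cpp_profile_score_batch(x$emissions, enc, x$ins_open,
                                      x$ins_extend, x$del_open, x$del_extend)
    m <- nrow(x$emissions)
  } else {
    qi <- encode_seq(x, model)
    scores <- cpp_score_batch(qi, enc, model$score_matrix,
                              model$gap_open, model$gap_extend, TRUE)
    m <- length(qi)
  }
  s <- sd(scores)
  if (!is.finite(s) || s < 1e-9) {
    stopf("degenerate decoy score distribution (sd = %g); cannot calibrate", s)
  }
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - EULER_GAMMA / lambda
  nbar <- mean(nchar(decoy_seqs))
  K <- exp(lambda * mu) / (m * nbar)
  structure(list(lambda = lambda, K = K,
                 database_size = sum(nchar(db)),
                 decoy_count = as.integer(decoys),
                 rng_seed = as.integer(seed),
                 query_length = m,
                 mean_decoy_length = nbar),
            class = "evalue_calibration")
}

#' @export
print.evalue_calibration <- function(x, ...) {
  cat(sprintf("evalue_calibration: lambda %.4f, K %.3g, db %d residues, %d decoys\n",
              x$lambda, x$K, x$database_size, x$decoy_count))
  invisible(x)
}

#' Convert a raw score to a full-sequence E-value
#'
#' `E = K * m * N * exp(-lambda * S)`; doubling `database_size` doubles the
#' E-value at fixed score.
#'
#' @param cal an [calibrate_evalues()] result.
#' @param score numeric score(s).
#' @param database_size database size in residues (defaults to the calibrated
#'   database).
#' @return E-value(s), strictly positive.
#' @export
evalue_from_score <- function(cal, score, database_size = cal$database_size) {
  stopifnot(inherits(cal, "evalue_calibration"))
  pmax(cal$K * cal$query_length * database_size * exp(-cal$lambda * score),
       .Machine$double.xmin)
}

#' Pairwise (blastp-like) search of one query against a protein database
#'
#' Local-alignment scores converted to full-sequence E-values via the
#' calibration; hits below the threshold are returned sorted by E-value,
#' then descending score, then target id.
#'
#' @param query protein string.
#' @param db named character vector of proteins.
#' @param cal an `evalue_calibration` for this query/database.
#' @param threshold E-value acceptance threshold.
#' @param model substitution model.
#' @param compute_identity attach local-alignment percent identity per hit.
#' @return data.frame: target_id, score, evalue (and identity_to_query_pct).
#' @export
search_pairwise <- function(query, db, cal, threshold = 1e-5,
                            model = default_protein_model(),
                            compute_identity = TRUE) {
  db <- db[nzchar(db)]
  if (!length(db)) {
    return(data.frame(target_id = character(0), score = numeric(0),
                      evalue = numeric(0),
                      identity_to_query_pct = numeric(0)))
  }
  qi <- encode_seq(query, model)
  enc <- lapply(unname(db), encode_seq, model = model)
  scores <- cpp_score_batch(qi, enc, model$score_matrix,
                            model$gap_open, model$gap_extend, TRUE)
  ev <- evalue_from_score(cal, scores)
  keep <- which(ev < threshold)
  out <- data.frame(target_id = names(db)[keep], score = scores[keep],
                    evalue = ev[keep], stringsAsFactors = FALSE)
  out <- out[order(out$evalue, -out$score, out$target_id), , drop = FALSE]
  if (compute_identity) {
    out$identity_to_query_pct <- vapply(out$target_id, function(id) {
      align_local(query, db[[id]], model)$identity_pct
    }, numeric(1), USE.NAMES = FALSE)
  }
  rownames(out) <- NULL
  out
}
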
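# Iterative non-redundant query selection: starting from one seed per family,
# repeatedly search the remaining pool, keep the lowest-E hit that is below
# the identity ceiling against EVERY already-selected query, remove it from
# the pool, and use it as the next query. With the default 20 rounds this
# yields up to 21 queries per family.

#' Iteratively select non-redundant queries for a family
#'
#' Each round searches the current query against the remaining pool at
#' `E < cfg$evalue_threshold`; among hits whose global identity to every
#' already-selected query is below `cfg$identity_threshold`, the hit with the
#' lowest E-value is selected (ties: higher score, then lexicographic id),
#' removed from the pool, and becomes the next query. Stops early when no
#' eligible candidate remains. Database records identical to the seed
#' sequence are removed from the pool up front.
#'
#' @param seed seed protein (optionally named; default name `"seed"`).
#' @param family family label.
#' @param db named character vector: the annotated protein universe.
#' @param cfg a [cluster_config()].
#' @param engine search backend: `function(query, pool)` returning a
#'   data.frame with `target_id`, `score`, `evalue` sorted by E-value. The
#'   default is the internal pairwise engine with decoy-calibrated E-values.
#' @param model substitution model.
#' @return A `query_set`: ordered named queries (first = seed),
#'   `rounds_executed`, `exhausted_early`.
#' @export
select_queries <- function(seed, family, db, cfg = cluster_config(),
                           engine = NULL, model = default_protein_model()) {
  stopifnot(is.character(seed), length(seed) == 1L, nzchar(seed))
  seed_id <- names(seed) %||% "seed"
  if (is.na(seed_id) || !nzchar(seed_id)) seed_id <- "seed"
  db <- db[nzchar(db)]
  pool <- db[db != unname(seed)]
  if (is.null(engine)) {
    if (length(db)) {
      cal <- calibrate_evalues(unname(seed), db, seed = cfg$rng_seed,
                               model = model)
      engine <- function(query, pool) {
        search_pairwise(query, pool, cal, cfg$evalue_threshold, model,
                        compute_identity = FALSE)
      }
    } else {
      engine <- function(query, pool) {
        data.frame(target_id = character(0), score = numeric(0),
                   evalue = numeric(0))
      }
    }
  }

  selected <- setNames(unname(seed), seed_id)
  memo <- new.env(parent = emptyenv()) # global identities, keyed cand|query
  ident <- function(cand_id, cand_seq, q_id, q_seq) {
    key <- paste(cand_id, q_id, sep = "\r")
    v <- memo[[key]]
    if (is.null(v)) {
      v <- global_identity(cand_seq, q_seq, model)
      memo[[key]] <- v
    }
    v
  }

  rounds <- 0L
  exhausted <- FALSE
  current <- unname(seed)
  for (r in seq_len(cfg$selection_rounds)) {
    if (!length(pool)) { exhausted <- TRUE; break }
    hits <- engine(current, pool)
    hits <- hits[order(hits$evalue, -hits$score, hits$target_id), , drop = FALSE]
    chosen <- NULL
    for (k in seq_len(nrow(hits))) {
      cand_id <- hits$target_id[k]
      cand_seq <- pool[[cand_id]]
      ok <- TRUE
      for (q in seq_along(selected)) {
        if (ident(cand_id, cand_seq, names(selected)[q], selected[[q]]) >=
            cfg$identity_threshold) { ok <- FALSE; break }
      }
      if (ok) { chosen <- cand_id; break }
    }
    if (is.null(chosen)) { exhausted <- TRUE; break }
    selected <- c(selected, setNames(pool[[chosen]], chosen))
    current <- pool[[chosen]]
    pool <- pool[names(pool) != chosen]
    rounds <- r
  }
  structure(list(family = family, queries = selected,
                 rounds_executed = rounds, exhausted_early = exhausted),
            class = "query_set")
}

#' @export
print.query_set <- function(x, ...) {
  cat(sprintf("query_set '%s': %d queries, %d rounds%s\n", x$family,
              length(x$queries), x$rounds_executed,
              if (x$exhausted_early) " (exhausted early)" else ""))
  invisible(x)
}

#' Build a family profile from a selected query set
#'
#' Aligns the queries (internal center-star aligner by default; any function
#' `seqs -> aligned seqs` can be supplied, e.g. a wrapper around an external
#' multiple aligner) and builds the position-specific profile.
#'
#' @param qs a [select_queries()] result.
#' @param aligner optional multiple-alignment backend.
#' @param model substitution model.
#' @return A `profile_model` with the family stamped on it.
#' @export
family_profile <- function(qs, aligner = NULL, model = default_protein_model()) {
  stopifnot(inherits(qs, "query_set"), length(qs$queries) >= 1)
  aligned <- tryCatch({
    if (is.null(aligner)) align_queries(qs$queries, model) else aligner(qs$queries)
  }, error = function(e) {
    stopf("alignment failed for family '%s': %s", qs$family, conditionMessage(e))
  })
  prof <- build_profile(aligned, ids = names(qs$queries))
  prof$family <- qs$family
  prof
}
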
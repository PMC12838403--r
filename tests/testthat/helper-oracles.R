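# Independent oracles and shared fixtures. The alignment oracle is a plain
# full-matrix Gotoh DP kept deliberately separate from the package's
# compiled implementation; gap convention: a gap of length k costs
# open + k * extend.

oracle_align_score <- function(a, b, mat, gap_open, gap_extend,
                               local = FALSE) {
  ai <- strsplit(a, "", fixed = TRUE)[[1]]
  bi <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ai); m <- length(bi)
  go <- gap_open + gap_extend; ge <- gap_extend
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (!local) {
    for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + (i - 1) * ge)
    for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + (j - 1) * ge)
  }
  best_local <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[ai[i - 1], bi[j - 1]]
      d <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      if (local) d <- max(d, 0)
      M[i, j] <- if (is.finite(d) || local) s + d else NEG
      X[i, j] <- max(M[i - 1, j] - go, X[i - 1, j] - ge, Y[i - 1, j] - go)
      Y[i, j] <- max(M[i, j - 1] - go, Y[i, j - 1] - ge, X[i, j - 1] - go)
      if (local && M[i, j] > best_local) best_local <- M[i, j]
    }
  }
  if (local) best_local else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# independent greedy centroid clustering (mirrors the published rule:
# length-descending, first centroid at >= threshold, largest cluster wins,
# ties to the longer centroid)
oracle_rep_16s <- function(seqs, threshold) {
  model <- substitution_model("nucleotide")
  ord <- names(seqs)[order(-nchar(seqs), names(seqs))]
  cents <- character(0)
  members <- list()
  for (id in ord) {
    hit <- NA
    for (c in cents) {
      if (global_identity(seqs[[id]], seqs[[c]], model) >= threshold) {
        hit <- c; break
      }
    }
    if (is.na(hit)) {
      cents <- c(cents, id)
      members[[id]] <- id
    } else {
      members[[hit]] <- c(members[[hit]], id)
    }
  }
  sizes <- vapply(cents, function(c) length(members[[c]]), integer(1))
  lens <- nchar(seqs[cents])
  cents[order(-sizes, -lens, cents)[1]]
}

random_aa <- function(n, seed) {
  with_seed(seed, paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                                 "I", "L", "K", "M", "F", "P", "S", "T", "W",
                                 "Y", "V"), n, replace = TRUE), collapse = ""))
}

random_nt <- function(n, seed) {
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""))
}

toy_annotation <- function(genome_id = "G", contig_len = 100000,
                           genes = NULL) {
  genome_annotation(genome_id, c(c1 = contig_len), genes)
}

# simple two-gene pair on one contig with a requested gap and strands
toy_pair_genes <- function(s1 = "+", s2 = "+", gap = 99, start1 = 1000,
                           len1 = 900, len2 = 800) {
  e1 <- start1 + len1 - 1
  s2_start <- e1 + gap + 1
  data.frame(gene_id = c("g1", "g2"), contig_id = "c1",
             start = c(start1, s2_start), end = c(e1, s2_start + len2 - 1),
             strand = c(s1, s2), protein = c("MKV", "MLV"),
             stringsAsFactors = FALSE)
}

# shared heavyweight fixture: a synthetic kduI family plus noise, and the
# query set / profile built from it (computed once per test run)
fixture_env <- new.env(parent = emptyenv())

family_fixture <- function() {
  if (is.null(fixture_env$fix)) {
    seeds <- default_family_seeds()
    fam <- synth_family(seeds$kduI, 60, c(40, 99), family = "kduI",
                        rng_seed = 11)
    noise <- setNames(vapply(1:40, function(i) random_protein(260, 1000 + i),
                             character(1)), sprintf("noise_%02d", 1:40))
    db <- c(fam, noise)
    cfg <- cluster_config()
    qs <- select_queries(setNames(seeds$kduI, "kduI_seed"), "kduI", db, cfg)
    prof <- family_profile(qs)
    cal <- calibrate_evalues(prof, db, seed = 1)
    fixture_env$fix <- list(seeds = seeds, fam = fam, noise = noise, db = db,
                            cfg = cfg, qs = qs, prof = prof, cal = cal)
  }
  fixture_env$fix
}

# planted-cluster genome set covering all 16 labels at the given gaps
plan_grid <- function(gaps) {
  labels <- enumerate_configurations()
  plans <- expand.grid(label = labels, gap_bp = gaps,
                       stringsAsFactors = FALSE)
  plans[order(plans$label, plans$gap_bp), ]
}
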
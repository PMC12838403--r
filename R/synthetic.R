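# Seeded synthetic-data generators: protein families on an identity ladder
# around a seed, annotated genomes with planted isomerase-reductase clusters
# of requested type and gap (plus composition-matched decoys), strain
# cohorts with phylum labels, and relative-abundance tables with planted
# per-type enrichment. Every generator is a pure function of its seed and
# emits a ground-truth table consistent with the generated data.

AA20 <- AA_ALPHABET[1:20]

#' Random protein drawn from background residue frequencies
#'
#' @param length protein length (residues).
#' @param rng_seed integer seed.
#' @return A protein string.
#' @export
random_protein <- function(length, rng_seed = 1L) {
  bg <- aa_background()
  with_seed(rng_seed,
            paste(sample(AA20, length, replace = TRUE, prob = bg), collapse = ""))
}

#' Mutate a protein to a target ungapped identity
#'
#' Substitutes uniformly chosen positions (replacement residues prefer
#' positive BLOSUM62 partners) so that the ungapped identity to the seed is
#' within one percentage point of the target. Deterministic per seed.
#'
#' @param seed_protein the seed sequence.
#' @param target_identity percent in (0, 100].
#' @param rng_seed integer seed.
#' @return Mutated protein string.
#' @export
mutate_protein <- function(seed_protein, target_identity, rng_seed = 1L) {
  stopifnot(target_identity > 0, target_identity <= 100)
  chars <- strsplit(toupper(seed_protein), "", fixed = TRUE)[[1]]
  L <- length(chars)
  m <- round(L * (100 - target_identity) / 100)
  achieved <- 100 * (L - m) / L
  if (abs(achieved - target_identity) > 1) {
    stopf("target identity %.1f%% unreachable for a %d-residue seed",
          target_identity, L)
  }
  if (m == 0L) return(paste(chars, collapse = ""))
  sub <- default_protein_model()$score_matrix
  with_seed(rng_seed, {
    pos <- sample.int(L, m)
    for (p in pos) {
      a <- chars[p]
      partners <- AA20[sub[a, AA20] > 0 & AA20 != a]
      if (!length(partners)) partners <- AA20[AA20 != a]
      chars[p] <- partners[sample.int(length(partners), 1L)]
    }
  })
  paste(chars, collapse = "")
}

#' Generate a labeled protein family on an identity ladder
#'
#' @param seed_protein family seed.
#' @param n number of variants.
#' @param identity_range target identities, evenly spaced over `(lo, hi)`.
#' @param family name prefix for member ids.
#' @param rng_seed integer seed.
#' @return Named character vector of `n` variants; target identities are
#'   attached as attribute `target_identity`.
#' @export
synth_family <- function(seed_protein, n, identity_range = c(40, 96),
                         family = "fam", rng_seed = 1L) {
  stopifnot(n >= 1)
  targets <- if (n == 1L) mean(identity_range)
             else seq(identity_range[1], identity_range[2], length.out = n)
  seeds <- derive_seeds(rng_seed, n)
  out <- vapply(seq_len(n), function(i) {
    mutate_protein(seed_protein, targets[i], seeds[i])
  }, character(1))
  names(out) <- sprintf("%s_%03d", family, seq_len(n))
  attr(out, "target_identity") <- targets
  out
}

#' Default synthetic family seed proteins
#'
#' Ten random proteins, one per family, with lengths typical of the real
#' enzymes (kduI 278, dhuI 149, kduD 253, dhuD 255 residues, etc.). These
#' are synthetic stand-ins for the published seed accessions, generated in
#' code from a fixed seed.
#'
#' @param rng_seed integer seed.
#' @return Named list of protein strings, one per family.
#' @export
default_family_seeds <- function(rng_seed = 1042L) {
  lens <- c(kduI = 278L, dhuI = 149L, kduD = 253L, dhuD = 255L,
            ugl = 377L, ogl = 388L, yteR = 349L, kdgA = 205L,
            kdgK = 309L, kdgF = 110L)
  seeds <- derive_seeds(rng_seed, length(lens))
  out <- lapply(seq_along(lens), function(i) random_protein(lens[i], seeds[i]))
  names(out) <- names(lens)
  out
}

#' Plan one planted cluster
#'
#' @param label a label from [enumerate_configurations()].
#' @param gap_bp intergenic gap to plant (bp, >= 0).
#' @param contig_id target contig.
#' @param anchor 1-based start of the left gene (NA = auto layout).
#' @param intervening integer vector of decoy gene lengths (bp) to place in
#'   the gap.
#' @return One-row plan data.frame (stackable with `rbind`).
#' @export
cluster_plan <- function(label, gap_bp, contig_id = "contig_1", anchor = NA,
                         intervening = integer(0)) {
  stopifnot(label %in% enumerate_configurations(), gap_bp >= 0)
  data.frame(label = label, gap_bp = as.integer(gap_bp),
             contig_id = contig_id, anchor = as.integer(anchor),
             intervening = I(list(as.integer(intervening))),
             stringsAsFactors = FALSE)
}

label_spec <- function(label) {
  letter <- substr(label, 1, 1)
  anti <- grepl("c$", label)
  row <- PARALLEL_LETTERS[PARALLEL_LETTERS$letter == letter, ]
  list(iso_family = row$iso_family, red_family = row$red_family,
       iso_first = row$iso_first, antiparallel = anti,
       divergent = anti && row$iso_first)
}

#' Generate a synthetic annotated genome with planted clusters
#'
#' Emits genes realizing each plan (coordinates and strands chosen to
#' produce the requested label; each planted pair is self-checked with
#' [classify_pair()] at generation time), optional single auxiliary-family
#' genes, and decoy genes built by shuffling family seeds and mutating, so
#' negatives are composition-matched. Planted loci are spaced far enough
#' apart that no unplanned pair satisfies the default gap cutoff.
#'
#' @param plans rbind-ed [cluster_plan()] rows (may have zero rows).
#' @param family_seeds named list of family seed proteins.
#' @param aux_families families to add as isolated single genes.
#' @param decoy_count number of decoy genes.
#' @param rng_seed integer seed.
#' @param genome_id genome identifier.
#' @return list with `annotation` (a [genome_annotation()]) and `truth`
#'   (planted calls, family memberships, decoy ids).
#' @export
synth_genome <- function(plans = NULL, family_seeds = default_family_seeds(),
                         aux_families = character(0), decoy_count = 5L,
                         rng_seed = 1L, genome_id = "synthetic_genome") {
  if (is.null(plans)) plans <- cluster_plan("A", 99)[0, ]
  n_plans <- nrow(plans)
  gene_rows <- list()
  truth_calls <- list()
  truth_fams <- list()
  decoy_ids <- character(0)
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("%s_g%03d", genome_id, counter)
  }
  seeds <- derive_seeds(rng_seed, max(1L, n_plans) * 4L + length(aux_families) +
                                  decoy_count + 8L)
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }
  cursor <- list() # per-contig next free coordinate
  with_seed(rng_seed, {
    for (k in seq_len(n_plans)) {
      spec <- label_spec(plans$label[k])
      cid <- plans$contig_id[k]
      iso_prot <- mutate_protein(family_seeds[[spec$iso_family]],
                                 runif(1, 60, 90), next_seed())
      red_prot <- mutate_protein(family_seeds[[spec$red_family]],
                                 runif(1, 60, 90), next_seed())
      iso_len <- 3L * (nchar(iso_prot) + 1L)
      red_len <- 3L * (nchar(red_prot) + 1L)
      gap <- plans$gap_bp[k]
      if (spec$antiparallel) {
        iso_left <- TRUE
        iso_strand <- if (spec$divergent) "-" else "+"
        red_strand <- if (spec$divergent) "+" else "-"
      } else {
        strand <- sample(c("+", "-"), 1L)
        first_is_iso <- spec$iso_first
        iso_left <- if (strand == "+") first_is_iso else !first_is_iso
        iso_strand <- red_strand <- strand
      }
      left_len <- if (iso_left) iso_len else red_len
      right_len <- if (iso_left) red_len else iso_len
      anchor <- plans$anchor[k]
      if (is.na(anchor)) {
        anchor <- (cursor[[cid]] %||% 1000L)
      }
      left_start <- as.integer(anchor)
      left_end <- left_start + left_len - 1L
      right_start <- left_end + gap + 1L
      right_end <- right_start + right_len - 1L
      prev <- cursor[[paste0(cid, ".spans")]] %||% list()
      for (sp in prev) {
        if (left_start <= sp[2] && right_end >= sp[1]) {
          stopf("overlapping plans on contig '%s'", cid)
        }
      }
      cursor[[paste0(cid, ".spans")]] <- c(prev, list(c(left_start, right_end)))
      cursor[[cid]] <- right_end + 5000L
      iso_id <- new_id(); red_id <- new_id()
      iso_rec <- list(gene_id = iso_id, contig_id = cid,
                      start = if (iso_left) left_start else right_start,
                      end = if (iso_left) left_end else right_end,
                      strand = iso_strand, family = spec$iso_family)
      red_rec <- list(gene_id = red_id, contig_id = cid,
                      start = if (iso_left) right_start else left_start,
                      end = if (iso_left) right_end else left_end,
                      strand = red_strand, family = spec$red_family)
      got <- classify_pair(iso_rec, red_rec)
      if (got != plans$label[k]) {
        stopf("internal self-check failed: planted %s classified as %s",
              plans$label[k], got)
      }
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = iso_id, contig_id = cid, start = iso_rec$start,
        end = iso_rec$end, strand = iso_strand, protein = iso_prot,
        stringsAsFactors = FALSE)
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = red_id, contig_id = cid, start = red_rec$start,
        end = red_rec$end, strand = red_strand, protein = red_prot,
        stringsAsFactors = FALSE)
      truth_calls[[length(truth_calls) + 1L]] <- data.frame(
        genome_id = genome_id, contig_id = cid, label = plans$label[k],
        iso_gene_id = iso_id, red_gene_id = red_id, gap_bp = gap,
        stringsAsFactors = FALSE)
      truth_fams[[length(truth_fams) + 1L]] <- data.frame(
        gene_id = c(iso_id, red_id),
        family = c(spec$iso_family, spec$red_family), stringsAsFactors = FALSE)
      for (ilen in plans$intervening[[k]]) {
        if (ilen > gap) stopf("intervening gene (%d bp) does not fit in a %d bp gap",
                              ilen, gap)
        pad <- (gap - ilen) %/% 2L
        istart <- left_end + 1L + pad
        iid <- new_id()
        iprot <- random_protein(max(30L, ilen %/% 3L - 1L), next_seed())
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          gene_id = iid, contig_id = cid, start = istart,
          end = istart + ilen - 1L, strand = sample(c("+", "-"), 1L),
          protein = iprot, stringsAsFactors = FALSE)
        decoy_ids <- c(decoy_ids, iid)
      }
    }
    # isolated auxiliary-family genes, well clear of the planted loci
    for (fam in aux_families) {
      cid <- "contig_1"
      prot <- mutate_protein(family_seeds[[fam]], runif(1, 60, 90), next_seed())
      len <- 3L * (nchar(prot) + 1L)
      start <- (cursor[[cid]] %||% 1000L)
      cursor[[cid]] <- start + len + 5000L
      gid <- new_id()
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = gid, contig_id = cid, start = start, end = start + len - 1L,
        strand = sample(c("+", "-"), 1L), protein = prot,
        stringsAsFactors = FALSE)
      truth_fams[[length(truth_fams) + 1L]] <- data.frame(
        gene_id = gid, family = fam, stringsAsFactors = FALSE)
    }
    # shuffled-then-mutated decoys: composition-matched negatives
    for (d in seq_len(decoy_count)) {
      src <- family_seeds[[sample.int(length(family_seeds), 1L)]]
      prot <- NULL
      for (try in 1:20) {
        cand <- mutate_protein(shuffle_seq(src), runif(1, 70, 90), next_seed())
        if (global_identity(cand, src) <= 30) { prot <- cand; break }
      }
      if (is.null(prot)) stopf("could not generate a <=30%% identity decoy")
      cid <- "contig_1"
      len <- 3L * (nchar(prot) + 1L)
      start <- (cursor[[cid]] %||% 1000L)
      cursor[[cid]] <- start + len + 2000L
      gid <- new_id()
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = gid, contig_id = cid, start = start, end = start + len - 1L,
        strand = sample(c("+", "-"), 1L), protein = prot,
        stringsAsFactors = FALSE)
      decoy_ids <- c(decoy_ids, gid)
    }
  })
  genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(gene_id = character(0), contig_id = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               protein = character(0), stringsAsFactors = FALSE)
  contig_ids <- unique(c(genes$contig_id, "contig_1"))
  contigs <- setNames(vapply(contig_ids, function(cid) {
    ends <- genes$end[genes$contig_id == cid]
    if (length(ends)) max(ends) + 500 else 1000
  }, numeric(1)), contig_ids)
  ann <- genome_annotation(genome_id, contigs, genes)
  truth <- list(genome_id = genome_id,
                calls = if (length(truth_calls)) do.call(rbind, truth_calls) else
                  data.frame(genome_id = character(0), contig_id = character(0),
                             label = character(0), iso_gene_id = character(0),
                             red_gene_id = character(0), gap_bp = integer(0),
                             stringsAsFactors = FALSE),
                families = if (length(truth_fams)) do.call(rbind, truth_fams) else
                  data.frame(gene_id = character(0), family = character(0),
                             stringsAsFactors = FALSE),
                decoys = decoy_ids)
  list(annotation = ann, truth = truth)
}

#' Generate a synthetic strain cohort
#'
#' Per-strain cluster-type and auxiliary-family possession are independent
#' Bernoulli draws; each positive label becomes one planted cluster with a
#' gap drawn from `gap_range`. A fraction of cluster-negative strains carry
#' kduI and kduD as isolated genes at separate loci. Emits genomes, a
#' lineage table, and a possession ground-truth table.
#'
#' @param n_strains cohort size.
#' @param phylum_weights named sampling weights for phylum labels.
#' @param label_frequencies named per-label planting probabilities (defaults
#'   to the seven parallel types observed in practice, A/B/D/E/F/G/H, at
#'   equal frequency).
#' @param aux_possession_probs named per-family possession probabilities.
#' @param gap_range inclusive range for planted gaps (bp).
#' @param separate_loci_prob probability that a cluster-negative strain
#'   carries kduI + kduD at separate loci.
#' @param decoy_count decoys per genome.
#' @param family_seeds named list of family seed proteins.
#' @param rng_seed integer seed.
#' @return list: `genomes` (named list of annotations), `lineages`,
#'   `truth` (possession data.frame, combined calls/families, decoys),
#'   `family_seeds`.
#' @export
synth_cohort <- function(n_strains = 100L,
                         phylum_weights = c(Pseudomonadota = 0.39,
                                            Actinomycetota = 0.18,
                                            Bacillota = 0.18,
                                            Bacteroidota = 0.09,
                                            Other = 0.16),
                         label_frequencies = setNames(rep(0.15, 7),
                                                      c("A", "B", "D", "E",
                                                        "F", "G", "H")),
                         aux_possession_probs = c(ugl = 0.5, ogl = 0.3,
                                                  yteR = 0.3, kdgA = 0.98,
                                                  kdgK = 0.98, kdgF = 0.4),
                         gap_range = c(0L, 99L),
                         separate_loci_prob = 0.1,
                         decoy_count = 2L,
                         family_seeds = NULL,
                         rng_seed = 1L) {
  stopifnot(all(label_frequencies >= 0), all(label_frequencies <= 1),
            all(names(label_frequencies) %in% enumerate_configurations()))
  seeds <- derive_seeds(rng_seed, n_strains + 2L)
  if (is.null(family_seeds)) family_seeds <- default_family_seeds(seeds[n_strains + 1L])
  labels <- names(label_frequencies)
  aux <- names(aux_possession_probs)
  all_labels <- enumerate_configurations()
  draws <- with_seed(seeds[n_strains + 2L], {
    list(lab = matrix(rbinom(n_strains * length(labels), 1L,
                             rep(label_frequencies, each = n_strains)) == 1L,
                      n_strains, length(labels), dimnames = list(NULL, labels)),
         aux = matrix(rbinom(n_strains * length(aux), 1L,
                             rep(aux_possession_probs, each = n_strains)) == 1L,
                      n_strains, length(aux), dimnames = list(NULL, aux)),
         gaps = matrix(sample(seq(gap_range[1], gap_range[2]),
                              n_strains * length(labels), replace = TRUE),
                       n_strains, length(labels)),
         phylum = sample(names(phylum_weights), n_strains, replace = TRUE,
                         prob = phylum_weights),
         fam_idx = sample.int(4L, n_strains, replace = TRUE),
         sep = runif(n_strains) < separate_loci_prob)
  })
  genomes <- vector("list", n_strains)
  strain_ids <- sprintf("strain_%04d", seq_len(n_strains))
  names(genomes) <- strain_ids
  calls_all <- list(); fams_all <- list(); decoys_all <- character(0)
  poss <- matrix(FALSE, n_strains, length(all_labels) + length(aux) + 1L,
                 dimnames = list(strain_ids, c(all_labels, aux, "separate_pair")))
  for (i in seq_len(n_strains)) {
    pos_labels <- labels[draws$lab[i, ]]
    plans <- NULL
    for (j in seq_along(pos_labels)) {
      p <- cluster_plan(pos_labels[j], draws$gaps[i, which(labels == pos_labels[j])[1]])
      plans <- if (is.null(plans)) p else rbind(plans, p)
    }
    aux_here <- aux[draws$aux[i, ]]
    sep_here <- !length(pos_labels) && draws$sep[i]
    if (sep_here) aux_here <- c(aux_here, "kduI", "kduD")
    g <- synth_genome(plans, family_seeds, aux_families = aux_here,
                      decoy_count = decoy_count, rng_seed = seeds[i],
                      genome_id = strain_ids[i])
    genomes[[i]] <- g$annotation
    if (nrow(g$truth$calls)) calls_all[[length(calls_all) + 1L]] <- g$truth$calls
    if (nrow(g$truth$families)) {
      f <- g$truth$families
      f$genome_id <- strain_ids[i]
      fams_all[[length(fams_all) + 1L]] <- f
    }
    decoys_all <- c(decoys_all, g$truth$decoys)
    poss[i, pos_labels] <- TRUE
    poss[i, aux[draws$aux[i, ]]] <- TRUE
    poss[i, "separate_pair"] <- sep_here
  }
  lineages <- data.frame(genome_id = strain_ids, phylum = draws$phylum,
                         family = paste0(draws$phylum, "_f", draws$fam_idx),
                         genus = paste0(draws$phylum, "_g", draws$fam_idx),
                         species = "", stringsAsFactors = FALSE)
  structure(list(genomes = genomes, lineages = lineages,
                 truth = list(possession = as.data.frame(poss),
                              calls = if (length(calls_all))
                                do.call(rbind, calls_all) else NULL,
                              families = if (length(fams_all))
                                do.call(rbind, fams_all) else NULL,
                              decoys = decoys_all),
                 family_seeds = family_seeds),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d strains, %d planted calls\n",
              length(x$genomes),
              if (is.null(x$truth$calls)) 0L else nrow(x$truth$calls)))
  invisible(x)
}

#' Generate a relative-abundance table for a cohort
#'
#' Per-strain, per-sample lognormal abundances: the log-mean is shifted by
#' `log(fold)` for strains positive for an enriched label, and each sample
#' is normalized to sum 1. The default dispersion (sdlog 2) reproduces the
#' heavy-tailed abundance distributions typical of gut metagenome profiles.
#'
#' @param cohort a [synth_cohort()] result.
#' @param n_samples number of samples.
#' @param enrichment named fold changes per label (defaults to none; folds
#'   must be > 0).
#' @param noise_dispersion lognormal sdlog of the per-sample noise.
#' @param rng_seed integer seed.
#' @return Long data.frame: sample_id, genome_id, abundance.
#' @export
synth_abundance <- function(cohort, n_samples = 50L, enrichment = NULL,
                            noise_dispersion = 2, rng_seed = 1L) {
  strains <- rownames(cohort$truth$possession)
  n <- length(strains)
  fold <- rep(1, n)
  if (!is.null(enrichment)) {
    stopifnot(all(enrichment > 0),
              all(names(enrichment) %in% enumerate_configurations()))
    for (l in names(enrichment)) {
      hit <- cohort$truth$possession[[l]]
      fold[hit] <- pmax(fold[hit], enrichment[[l]])
    }
  }
  with_seed(rng_seed, {
    rows <- lapply(seq_len(n_samples), function(s) {
      v <- exp(log(fold) + rnorm(n, 0, noise_dispersion))
      data.frame(sample_id = sprintf("sample_%03d", s), genome_id = strains,
                 abundance = v / sum(v), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
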
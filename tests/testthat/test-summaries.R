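pm_from <- function(strains, label_map, fam_map = NULL) {
  asg <- if (is.null(fam_map)) data.frame() else
    do.call(rbind, lapply(names(fam_map), function(s) {
      data.frame(genome_id = s, gene_id = paste0(s, "_", fam_map[[s]]),
                 family = fam_map[[s]], score = 100, evalue = 1e-30,
                 stringsAsFactors = FALSE)
    }))
  calls <- do.call(rbind, lapply(names(label_map), function(s) {
    do.call(rbind, lapply(label_map[[s]], function(l) {
      data.frame(genome_id = s, contig_id = "c1",
                 iso_gene_id = paste0(s, "_i_", l), iso_family = "kduI",
                 iso_start = 1, red_gene_id = paste0(s, "_r_", l),
                 red_family = "kduD", red_start = 2, iso_strand = "+",
                 red_strand = "+", label = l, gap_bp = 0L, intervening = "",
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(calls)) calls <- data.frame()
  possession_matrix(asg, calls, strains)
}

test_that("type-by-phylum counts strains once per label, including tandems", {
  pm <- pm_from(paste0("s", 1:4),
                list(s1 = "A", s2 = "A", s3 = "A", s4 = c("A", "H")))
  lin <- data.frame(genome_id = paste0("s", 1:4),
                    phylum = c("Pseudomonadota", "Pseudomonadota",
                               "Bacillota", "Bacillota"),
                    family = "", genus = "", species = "",
                    stringsAsFactors = FALSE)
  tb <- type_by_phylum(pm, lin)
  expect_equal(unname(tb$type_totals["A"]), 4)
  expect_equal(unname(tb$type_totals["H"]), 1)  # tandem strain counted under both
  expect_equal(unname(tb$counts["A", "Pseudomonadota"]), 2)
  expect_equal(unname(tb$prop_by_type["A", "Bacillota"]), 0.5)
  expect_equal(sum(tb$prop_by_type["A", ]), 1)
})

test_that("missing lineages warn and group under unclassified; empty matrix works", {
  pm <- pm_from(c("s1", "s2"), list(s1 = "A"))
  lin <- data.frame(genome_id = "s2", phylum = "Bacillota", family = "",
                    genus = "", species = "", stringsAsFactors = FALSE)
  expect_warning(tb <- type_by_phylum(pm, lin), "unclassified")
  expect_equal(unname(tb$counts["A", "unclassified"]), 1)
  pm0 <- pm_from("s1", list())
  tb0 <- suppressWarnings(type_by_phylum(pm0, lin))
  expect_true(all(tb0$counts == 0))
})

test_that("abundance aggregation sums label-positive strains per sample", {
  pm <- pm_from(c("s1", "s2", "s3"), list(s1 = "A", s2 = "A", s3 = "E"))
  ab <- data.frame(sample_id = "x", genome_id = c("s1", "s2", "s3"),
                   abundance = c(0.2, 0.3, 0.1), stringsAsFactors = FALSE)
  r <- abundance_by_type(ab, pm, labels = c("A", "E"))
  expect_equal(r$abundance$abundance[r$abundance$label == "A"], 0.5)
  expect_equal(r$abundance$abundance[r$abundance$label == "E"], 0.1)
  expect_equal(r$abundance$abundance_per_strain[r$abundance$label == "A"], 0.25)
  expect_error(abundance_by_type(
    data.frame(sample_id = "x", genome_id = "nope", abundance = 1), pm),
    "no overlap")
})

test_that("habitat means, category filter and above/below flags", {
  pm <- pm_from(c("s1", "s2", "s3"), list(s1 = "G", s2 = "G", s3 = "A"))
  sc <- data.frame(genome_id = c("s1", "s2", "s3"),
                   soil = c(20, 30, 2), cave = c(3, 4, 5),
                   stringsAsFactors = FALSE)
  h <- habitat_by_type(sc, pm)
  expect_equal(unname(h$means["G", "soil"]), 25)
  expect_false("cave" %in% colnames(h$means))     # all means <= 10 dropped
  expect_equal(unname(h$flags["G", "soil"]), "above")
  expect_equal(unname(h$flags["A", "soil"]), "below")
})

test_that("16S representative: single sequence, largest cluster, tie to longer", {
  base <- random_nt(300, 1)
  one <- select_rep_16s(c(only = base))
  expect_equal(one$representative_id, "only")
  # clusters of sizes 3 and 2: centroid of the triplet wins
  mut <- function(s, k, seed) {
    ch <- strsplit(s, "")[[1]]
    with_seed(seed, {
      pos <- sample(length(ch), k)
      ch[pos] <- vapply(ch[pos], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    })
    paste(ch, collapse = "")
  }
  fam1 <- c(a1 = base, a2 = mut(base, 10, 2), a3 = mut(base, 12, 3))
  other <- random_nt(300, 99)
  fam2 <- c(b1 = other, b2 = mut(other, 10, 4))
  r <- select_rep_16s(c(fam1, fam2))
  expect_equal(r$representative_id, oracle_rep_16s(c(fam1, fam2), 90))
  expect_true(r$representative_id %in% names(fam1))
  # every member is >= 90% identical to its centroid
  expect_true(all(r$clusters$identity_pct >= 90))
  # size tie: two clusters of two, the longer centroid wins
  long <- random_nt(320, 7)
  short <- random_nt(280, 8)
  tie <- c(L1 = long, L2 = mut(long, 8, 9), S1 = short, S2 = mut(short, 8, 10))
  rt <- select_rep_16s(tie)
  expect_equal(rt$representative_id, "L1")
  expect_equal(nchar(rt$representative), 320)
  expect_error(select_rep_16s(character(0)), "no 16S")
})
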
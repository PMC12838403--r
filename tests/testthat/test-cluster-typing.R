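mkgene <- function(id, start, end, strand, family = NULL, contig = "c1") {
  g <- list(gene_id = id, contig_id = contig, start = start, end = end,
            strand = strand)
  if (!is.null(family)) g$family <- family
  g
}

test_that("intergenic gap arithmetic: separated, abutting, overlapping", {
  u <- mkgene("u", 1, 1000, "+")
  v <- mkgene("v", 1100, 2000, "+")
  expect_equal(intergenic_gap(u, v), 99)
  expect_equal(intergenic_gap(v, u), 99) # symmetric
  expect_equal(intergenic_gap(u, mkgene("v", 1001, 2000, "+")), 0) # abutting
  expect_equal(intergenic_gap(u, mkgene("v", 900, 2000, "+")), 0)  # overlap clamps
  expect_error(intergenic_gap(u, mkgene("v", 1, 10, "+", contig = "c2")),
               "different contigs")
})

test_that("the typology has exactly 16 labels, 8 parallel and 8 antiparallel", {
  labs <- enumerate_configurations()
  expect_length(labs, 16)
  expect_length(unique(labs), 16)
  expect_identical(labs[1:8], LETTERS[1:8])
  expect_true(all(grepl("c$", labs[9:16])))
})

test_that("every raw strand/order/content configuration maps into the 16 labels", {
  # 4 content pairs x iso-left/right x 2 iso strands x 2 red strands = 32
  contents <- list(c("kduI", "kduD"), c("dhuI", "dhuD"),
                   c("kduI", "dhuD"), c("dhuI", "kduD"))
  seen <- character(0)
  rc_ok <- TRUE
  for (ct in contents) for (iso_left in c(TRUE, FALSE))
    for (s1 in c("+", "-")) for (s2 in c("+", "-")) {
      iso <- mkgene("i", if (iso_left) 100 else 2000,
                    if (iso_left) 900 else 2800, s1, ct[1])
      red <- mkgene("r", if (iso_left) 2000 else 100,
                    if (iso_left) 2800 else 900, s2, ct[2])
      lab <- classify_pair(iso, red)
      seen <- c(seen, lab)
      # reverse-complement the contig: reflect coordinates, flip strands
      L <- 5000
      flip <- function(g) {
        g2 <- g
        g2$start <- L - g$end + 1; g2$end <- L - g$start + 1
        g2$strand <- if (g$strand == "+") "-" else "+"
        g2
      }
      rc_ok <- rc_ok && identical(classify_pair(flip(iso), flip(red)), lab)
    }
  expect_setequal(unique(seen), enumerate_configurations())
  expect_length(seen, 32)
  expect_true(rc_ok)
  # each label realized exactly twice (once per reverse-complement partner)
  expect_true(all(table(seen) == 2))
})

test_that("published letter assignments hold for parallel pairs", {
  # upstream gene first: A kduI-kduD, H kduD-dhuI, and the '-'-strand mirror of A
  expect_equal(classify_pair(mkgene("i", 100, 1000, "+", "kduI"),
                             mkgene("r", 1100, 1900, "+", "kduD")), "A")
  expect_equal(classify_pair(mkgene("i", 1400, 1900, "+", "dhuI"),
                             mkgene("r", 100, 1000, "+", "kduD")), "H")
  expect_equal(classify_pair(mkgene("i", 1100, 1900, "-", "kduI"),
                             mkgene("r", 100, 1000, "-", "kduD")), "A")
  expect_equal(classify_pair(mkgene("i", 100, 1000, "+", "dhuI"),
                             mkgene("r", 1100, 1900, "+", "dhuD")), "C")
  expect_error(classify_pair(mkgene("i", 1, 10, "+", "ugl"),
                             mkgene("r", 20, 30, "+", "kduD")),
               "not an isomerase")
})

test_that("pairing respects the gap cutoff boundary exactly", {
  for (gap in c(0, 1, 250, 499, 500, 501)) {
    genes <- toy_pair_genes(gap = gap)
    ann <- toy_annotation(genes = genes)
    fams <- data.frame(gene_id = c("g1", "g2"), family = c("kduI", "kduD"))
    calls <- find_pairs(ann, fams)
    if (gap <= 500) {
      expect_equal(nrow(calls), 1, info = paste("gap", gap))
      expect_equal(calls$gap_bp, gap)
      expect_equal(calls$label, "A")
    } else {
      expect_equal(nrow(calls), 0, info = paste("gap", gap))
    }
  }
})

test_that("one gene can serve in two calls and intervening genes are recorded", {
  genes <- data.frame(
    gene_id = c("iso1", "red", "iso2", "cupin"),
    contig_id = "c1",
    start = c(1000, 2000, 3400, 3000),
    end = c(1900, 2900, 4000, 3300),
    strand = c("+", "+", "+", "+"),
    protein = "M", stringsAsFactors = FALSE)
  ann <- toy_annotation(genes = genes)
  fams <- data.frame(gene_id = c("iso1", "red", "iso2"),
                     family = c("kduI", "kduD", "dhuI"))
  calls <- find_pairs(ann, fams)
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$label, c("A", "H"))
  expect_equal(calls$intervening[calls$label == "H"], "cupin")
  expect_equal(calls$intervening[calls$label == "A"], "")
  # input order invariance
  ann2 <- toy_annotation(genes = genes[c(3, 1, 4, 2), ])
  expect_identical(find_pairs(ann2, fams), calls)
})

test_that("tandem chains keep their constituent pair calls", {
  mk3 <- function(f1, f2, f3) {
    genes <- data.frame(gene_id = c("g1", "g2", "g3"), contig_id = "c1",
                        start = c(1000, 2000, 3000),
                        end = c(1900, 2900, 3900), strand = "+",
                        protein = "M", stringsAsFactors = FALSE)
    ann <- toy_annotation(genes = genes)
    fams <- data.frame(gene_id = c("g1", "g2", "g3"),
                       family = c(f1, f2, f3))
    calls <- find_pairs(ann, fams)
    list(calls = calls, tandem = merge_tandem(calls))
  }
  r1 <- mk3("kduI", "kduD", "dhuI")
  expect_equal(nrow(r1$calls), 2)      # pair calls retained
  expect_equal(nrow(r1$tandem), 1)
  expect_equal(r1$tandem$chain_string, "kduI-kduD-dhuI")
  expect_equal(r1$tandem$constituent_labels, "A,H")

  r2 <- mk3("kduI", "dhuD", "dhuI")
  expect_equal(r2$tandem$chain_string, "kduI-dhuD-dhuI")
  expect_equal(r2$tandem$constituent_labels, "D,E")

  r3 <- mk3("kduD", "kduI", "dhuD")
  expect_equal(r3$tandem$chain_string, "kduD-kduI-dhuD")
  expect_equal(r3$tandem$constituent_labels, "B,E")
})

test_that("isolated and antiparallel calls never form tandem chains", {
  genes <- toy_pair_genes(gap = 99)
  ann <- toy_annotation(genes = genes)
  fams <- data.frame(gene_id = c("g1", "g2"), family = c("kduI", "kduD"))
  expect_equal(nrow(merge_tandem(find_pairs(ann, fams))), 0)
  # divergent pair sharing a gene with a parallel call: the antiparallel
  # call must not join a chain
  genes2 <- data.frame(gene_id = c("g1", "g2", "g3"), contig_id = "c1",
                       start = c(1000, 2000, 3000),
                       end = c(1900, 2900, 3900),
                       strand = c("-", "+", "+"), protein = "M",
                       stringsAsFactors = FALSE)
  ann2 <- toy_annotation(genes = genes2)
  fams2 <- data.frame(gene_id = c("g1", "g2", "g3"),
                      family = c("kduI", "kduD", "dhuI"))
  calls2 <- find_pairs(ann2, fams2)
  expect_equal(nrow(calls2), 2) # one antiparallel (g1-g2), one parallel (g2-g3)
  expect_equal(nrow(merge_tandem(calls2)), 0)
})

test_that("distance summaries: medians, histogram conservation, empty input", {
  genes <- toy_pair_genes(gap = 0)
  ann <- toy_annotation(genes = genes)
  fams <- data.frame(gene_id = c("g1", "g2"), family = c("kduI", "kduD"))
  calls <- do.call(rbind, lapply(c(0, 99, 480), function(g) {
    ann <- toy_annotation(genes = toy_pair_genes(gap = g))
    find_pairs(ann, fams)
  }))
  dt <- distance_table(calls)
  expect_equal(dt$summary$n, 3)
  expect_equal(dt$summary$median_gap, 99)
  expect_equal(sum(dt$histogram$count), 3)
  expect_equal(dt$histogram$count[dt$histogram$bin_start == 0], 1)
  e <- distance_table(calls[0, ])
  expect_equal(nrow(e$summary), 0)
})

test_that("reverse-complementing contigs changes no call or tandem chain", {
  seeds <- default_family_seeds()
  sub_seeds <- derive_seeds(404, 20)
  labels <- enumerate_configurations()
  for (k in 1:20) {
    picks <- with_seed(sub_seeds[k], sample(labels, 3))
    gaps <- with_seed(sub_seeds[k] + 1, sample(0:500, 3))
    plans <- do.call(rbind, Map(cluster_plan, picks, gaps))
    g <- synth_genome(plans, seeds, decoy_count = 0, rng_seed = sub_seeds[k],
                      genome_id = "rc")
    fams <- g$truth$families
    calls <- find_pairs(g$annotation, fams)
    td <- merge_tandem(calls)
    # mirror every contig
    genes <- g$annotation$genes
    L <- g$annotation$contigs[genes$contig_id]
    genes2 <- genes
    genes2$start <- as.integer(L - genes$end + 1)
    genes2$end <- as.integer(L - genes$start + 1)
    genes2$strand <- ifelse(genes$strand == "+", "-", "+")
    ann2 <- genome_annotation("rc", g$annotation$contigs, genes2)
    calls2 <- find_pairs(ann2, fams)
    key <- function(d) d[order(d$iso_gene_id, d$red_gene_id),
                         c("iso_gene_id", "red_gene_id", "label", "gap_bp")]
    expect_equal(key(calls2), key(calls), ignore_attr = TRUE)
    td2 <- merge_tandem(calls2)
    expect_setequal(td2$chain_string, td$chain_string)
    expect_setequal(td2$constituent_labels, td$constituent_labels)
  }
})
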
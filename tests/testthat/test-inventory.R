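test_that("best-hit assignment keeps the minimum E-value family", {
  hits <- data.frame(
    genome_id = "g",
    gene_id = c("x", "x", "y", "z", "z"),
    family = c("kduD", "dhuD", "ugl", "dhuD", "kduD"),
    score = c(200, 80, 50, 90, 90),
    evalue = c(1e-20, 1e-8, 1e-4, 1e-12, 1e-12),
    stringsAsFactors = FALSE)
  asg <- assign_families(hits)
  expect_equal(asg$family[asg$gene_id == "x"], "kduD")   # min E wins
  expect_false("y" %in% asg$gene_id)                      # 1e-4 >= 1e-5 dropped
  # exact tie on E and score: fixed priority puts kduD before dhuD
  expect_equal(asg$family[asg$gene_id == "z"], "kduD")
  expect_equal(anyDuplicated(asg$gene_id), 0)
})

test_that("possession matrix rolls calls and families up to strains", {
  asg <- data.frame(genome_id = c("s1", "s1", "s2", "s2"),
                    gene_id = c("a1", "a2", "b1", "b2"),
                    family = c("kduI", "kduD", "kduI", "kduD"),
                    score = 100, evalue = 1e-30, stringsAsFactors = FALSE)
  # s1 has a type-A call; s2 holds the genes 10 kb apart (no call)
  calls <- data.frame(genome_id = "s1", contig_id = "c1",
                      iso_gene_id = "a1", iso_family = "kduI", iso_start = 1,
                      red_gene_id = "a2", red_family = "kduD", red_start = 2,
                      iso_strand = "+", red_strand = "+", label = "A",
                      gap_bp = 10L, intervening = "", stringsAsFactors = FALSE)
  pm <- possession_matrix(asg, calls, c("s1", "s2", "s3"))
  expect_true(pm$presence["s1", "A"])
  expect_true(pm$presence["s1", "any_cluster"])
  expect_true(pm$presence["s2", "kduI"] && pm$presence["s2", "kduD"])
  expect_false(pm$presence["s2", "any_cluster"])
  expect_false(any(unlist(pm$presence["s3", ])))          # empty strain
  expect_equal(pm$copies["s1", "kduI"], 1)
  # label column true implies both member families present
  expect_true(all(!pm$presence$A | (pm$presence$kduI & pm$presence$kduD)))
})

test_that("duplicated families produce copy counts, not extra presence", {
  asg <- data.frame(genome_id = "s1", gene_id = paste0("g", 1:5),
                    family = "kduD", score = 100, evalue = 1e-30,
                    stringsAsFactors = FALSE)
  pm <- possession_matrix(asg, data.frame(), "s1")
  expect_equal(pm$copies["s1", "kduD"], 5)
  expect_true(pm$presence["s1", "kduD"])
})

test_that("co-occurrence ratios report numerator, denominator and undefined cases", {
  pres <- data.frame(matrix(FALSE, 5, 0))
  asg <- data.frame(genome_id = c("s1", "s2", "s3", "s4", "s1", "s2", "s3"),
                    gene_id = paste0("g", 1:7),
                    family = c(rep("ugl", 4), rep("kdgA", 3)),
                    score = 100, evalue = 1e-30, stringsAsFactors = FALSE)
  asg$family[4] <- "kdgK" # s4: kdgK not ugl
  calls <- do.call(rbind, lapply(paste0("s", 1:4), function(s) {
    data.frame(genome_id = s, contig_id = "c1", iso_gene_id = "i",
               iso_family = "kduI", iso_start = 1, red_gene_id = "r",
               red_family = "dhuD", red_start = 2, iso_strand = "+",
               red_strand = "+", label = "E", gap_bp = 0L, intervening = "",
               stringsAsFactors = FALSE)
  }))
  pm <- possession_matrix(asg, calls, paste0("s", 1:4))
  cc <- cooccurrence_ratios(pm)
  e_ugl <- cc[cc$label == "E" & cc$family == "ugl", ]
  expect_equal(e_ugl$n, 3); expect_equal(e_ugl$N, 4)
  expect_equal(e_ugl$ratio, 0.75)
  # a label with no positive strains has an undefined ratio, not 0
  a_ugl <- cc[cc$label == "A" & cc$family == "ugl", ]
  expect_true(is.na(a_ugl$ratio))
  expect_true(all(cc$n <= cc$N))
  expect_true(all(is.na(cc$ratio) | (cc$ratio >= 0 & cc$ratio <= 1)))
  # per-cluster unit: denominators count calls
  cc2 <- cooccurrence_ratios(pm, unit = "cluster", calls = calls)
  expect_equal(cc2[cc2$label == "E" & cc2$family == "ugl", "N"], 4)
})

test_that("separate-loci accounting excludes cluster-positive strains", {
  asg <- data.frame(
    genome_id = c("neg1", "neg1", "pos", "pos", "neg2"),
    gene_id = paste0("g", 1:5),
    family = c("kduI", "kduD", "kduI", "kduD", "ugl"),
    score = 100, evalue = 1e-30, stringsAsFactors = FALSE)
  calls <- data.frame(genome_id = "pos", contig_id = "c1",
                      iso_gene_id = "g3", iso_family = "kduI", iso_start = 1,
                      red_gene_id = "g4", red_family = "kduD", red_start = 2,
                      iso_strand = "+", red_strand = "+", label = "A",
                      gap_bp = 0L, intervening = "", stringsAsFactors = FALSE)
  pm <- possession_matrix(asg, calls, c("neg1", "neg2", "pos"))
  sl <- separate_loci(pm)
  expect_equal(sl$n_cluster_negative, 2)
  expect_equal(unname(sl$family_counts["kduI"]), 1)    # pos strain excluded
  ct <- sl$crosstab
  expect_equal(ct$n[ct$condition == "kduI_with_kduD"], 1)
  expect_equal(ct$N[ct$condition == "kduI_with_kduD"], 1)
  expect_equal(sl$lacks_all_core, 1)                    # neg2 has only ugl
})
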
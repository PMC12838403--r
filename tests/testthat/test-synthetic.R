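ungapped_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  100 * mean(ca == cb)
}

test_that("mutate_protein hits its target identity exactly and deterministically", {
  s <- random_protein(100, 1)
  expect_identical(mutate_protein(s, 100, 5), s)
  m90 <- mutate_protein(s, 90, 5)
  expect_equal(sum(strsplit(s, "")[[1]] != strsplit(m90, "")[[1]]), 10)
  expect_identical(mutate_protein(s, 90, 5), m90)
  expect_false(identical(mutate_protein(s, 90, 6), m90))
  expect_error(mutate_protein(random_protein(10, 2), 93, 1), "unreachable")
})

test_that("synth_family spans the requested identity ladder within a point", {
  s <- random_protein(200, 3)
  fam <- synth_family(s, 10, c(50, 95), rng_seed = 4)
  expect_length(fam, 10)
  measured <- vapply(fam, ungapped_identity, numeric(1), a = s)
  expect_true(all(abs(measured - attr(fam, "target_identity")) <= 1))
  expect_length(synth_family(s, 1, c(60, 60), rng_seed = 1), 1)
  expect_identical(synth_family(s, 5, c(50, 90), rng_seed = 9),
                   synth_family(s, 5, c(50, 90), rng_seed = 9))
})

test_that("planted genomes classify back to their plans, decoys stay out", {
  seeds <- default_family_seeds()
  plans <- rbind(cluster_plan("A", 99), cluster_plan("Fc", 200),
                 cluster_plan("H", 480, intervening = 300L))
  g <- synth_genome(plans, seeds, decoy_count = 4, rng_seed = 12,
                    genome_id = "pg")
  calls <- find_pairs(g$annotation, g$truth$families)
  expect_equal(nrow(calls), 3)
  expect_setequal(paste(calls$label, calls$gap_bp),
                  paste(g$truth$calls$label, g$truth$calls$gap_bp))
  called_genes <- c(calls$iso_gene_id, calls$red_gene_id)
  expect_length(intersect(called_genes, g$truth$decoys), 0)
  # truth families reference real genes
  expect_true(all(g$truth$families$gene_id %in% g$annotation$genes$gene_id))
  # generated genomes satisfy the annotation invariants (constructor ran)
  expect_s3_class(g$annotation, "genome_annotation")
})

test_that("decoys are composition-matched but remote from every family seed", {
  seeds <- default_family_seeds()
  g <- synth_genome(cluster_plan("A", 50), seeds, decoy_count = 3,
                    rng_seed = 8, genome_id = "dk")
  dec <- g$annotation$genes[g$annotation$genes$gene_id %in% g$truth$decoys, ]
  for (p in dec$protein) {
    idents <- vapply(seeds, function(s) global_identity(p, s), numeric(1))
    expect_true(all(idents <= 35))
  }
})

test_that("overlapping explicit anchors are rejected", {
  seeds <- default_family_seeds()
  plans <- rbind(cluster_plan("A", 50, anchor = 1000),
                 cluster_plan("B", 50, anchor = 1500))
  expect_error(synth_genome(plans, seeds, rng_seed = 1), "overlapping plans")
})

test_that("cohort possession frequencies recover their generating probabilities", {
  co <- synth_cohort(n_strains = 200, rng_seed = 17)
  poss <- co$truth$possession
  for (l in c("A", "B", "D", "E", "F", "G", "H")) {
    k <- sum(poss[[l]])
    # exact binomial 99.9% acceptance band around p = 0.15
    expect_gte(k, qbinom(5e-4, 200, 0.15))
    expect_lte(k, qbinom(1 - 5e-4, 200, 0.15))
  }
  # zero frequency means the label never appears
  co0 <- synth_cohort(n_strains = 30, label_frequencies = c(A = 0.5, G = 0),
                      rng_seed = 2)
  expect_false(any(co0$truth$possession$G))
  # determinism
  co2 <- synth_cohort(n_strains = 30, label_frequencies = c(A = 0.5, G = 0),
                      rng_seed = 2)
  expect_identical(co0$truth$possession, co2$truth$possession)
  expect_identical(co0$genomes[[1]]$genes, co2$genomes[[1]]$genes)
})

test_that("cohort truth is consistent with the emitted genomes", {
  co <- synth_cohort(n_strains = 25, rng_seed = 23)
  asg <- co$truth$families
  asg$evalue <- 1e-30; asg$score <- 100
  calls <- do.call(rbind, lapply(co$genomes, function(a) {
    find_pairs(a, asg[asg$genome_id == a$genome_id, ])
  }))
  pm <- possession_matrix(asg, calls, names(co$genomes))
  for (l in c("A", "B", "D", "E", "F", "G", "H")) {
    expect_identical(unname(pm$presence[[l]]),
                     unname(co$truth$possession[[l]]), label = l)
  }
})

test_that("abundance tables normalize per sample and respect the seed", {
  co <- synth_cohort(n_strains = 20, rng_seed = 5)
  ab <- synth_abundance(co, n_samples = 8, rng_seed = 6)
  sums <- tapply(ab$abundance, ab$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(ab$abundance >= 0))
  expect_identical(ab, synth_abundance(co, n_samples = 8, rng_seed = 6))
  expect_false(identical(ab$abundance,
                         synth_abundance(co, n_samples = 8,
                                         rng_seed = 7)$abundance))
})
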
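test_that("noiseless counts equal library-normalized expectations", {
  g <- build_genome(100, seed = 1)
  gt <- genotype(c("3L" = 3))
  a <- assign_effect_classes(g, gt, c(compensation = 1), c(no_change = 1),
                             seed = 2)
  sim <- simulate_counts(g, a, gt, n_replicates = 2, library_size = 1e6,
                         dispersion = 0, seed = 3)
  expect_equal(sim$size_factor, 1)
  # every sample totals the library size and aneuploid == control exactly
  for (s in sim$samples$sample_id) {
    expect_equal(sum(sim$counts[[s]]), 1e6)
  }
  expect_identical(sim$counts$aneuploid_1, sim$counts$control_1)
})

test_that("recorded size factor follows the abundance-weighted closed form", {
  # two arms; the cis arm holds exactly 5% of baseline expression, all of it
  # with a trisomic dosage effect -> T = 1 + 0.05 * 0.5 = 1.025
  g <- build_genome(200, arm_fractions = c("3L" = 0.1, "7S" = 0.9), seed = 4)
  g$baseline_mu <- ifelse(g$arm == "3L", 0.05 / 20, 0.95 / 180)
  gt <- genotype(c("3L" = 3))
  a <- assign_effect_classes(g, gt, c(dosage_effect = 1), c(no_change = 1),
                             seed = 5)
  sim <- simulate_counts(g, a, gt, dispersion = 0, seed = 6)
  expect_equal(sim$size_factor, 1.025)
  # and in general T = sum(mu * r) / sum(mu) to machine precision
  g2 <- build_genome(500, seed = 7)
  a2 <- assign_effect_classes(g2, gt, seed = 8)
  sim2 <- simulate_counts(g2, a2, gt, dispersion = 0, seed = 9)
  r <- a2$expected_ratio[match(g2$gene_id, a2$gene_id)]
  expect_equal(sim2$size_factor,
               sum(g2$baseline_mu * r) / sum(g2$baseline_mu),
               tolerance = 1e-15)
})

test_that("a global abundance scaling leaves the counts byte-identical", {
  g <- build_genome(500, seed = 10)
  gt <- genotype(c("3L" = 3))
  a <- assign_effect_classes(g, gt, seed = 11)
  sim <- simulate_counts(g, a, gt, dispersion = 0, seed = 12)
  sim_scaled <- simulate_counts(g, scale_expected_ratios(a, 0.5), gt,
                                dispersion = 0, seed = 12)
  expect_identical(sim$counts, sim_scaled$counts)
  expect_equal(sim_scaled$size_factor, sim$size_factor * 0.5)
  # the same holds under overdispersion with a fixed seed
  simn <- simulate_counts(g, a, gt, dispersion = 0.1, seed = 12)
  simn_scaled <- simulate_counts(g, scale_expected_ratios(a, 0.5), gt,
                                 dispersion = 0.1, seed = 12)
  expect_identical(simn$counts, simn_scaled$counts)
})

test_that("simulation output is deterministic in the seed and dispersed when asked", {
  g <- build_genome(200, seed = 13)
  gt <- genotype(c("4L" = 1))
  a <- assign_effect_classes(g, gt, seed = 14)
  s1 <- simulate_counts(g, a, gt, dispersion = 0.1, seed = 15)
  s2 <- simulate_counts(g, a, gt, dispersion = 0.1, seed = 15)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_counts(g, a, gt, dispersion = 0.1, seed = 16)
  expect_false(identical(s1$counts, s3$counts))
  # overdispersed draws are integers and vary across replicates
  expect_true(all(s1$counts$aneuploid_1 == round(s1$counts$aneuploid_1)))
  expect_false(identical(s1$counts$aneuploid_1, s1$counts$aneuploid_2))
})

test_that("noiseless ddPCR panels reproduce per-genome expectations", {
  g <- build_genome(300, seed = 20)
  gt <- genotype(c("3L" = 3))
  a1 <- assign_effect_classes(g, gt, c(compensation = 1), c(no_change = 1),
                              seed = 21)

  # all ratios 1: the aneuploid panel equals the control panel
  p1 <- simulate_ddpcr(g, a1, gt, cv = 0, seed = 22)
  expect_equal(per_genome_expression(p1)$per_genome, rep(1, 10))

  # a pure global halving shows up in full on the per-genome scale
  p2 <- simulate_ddpcr(g, scale_expected_ratios(a1, 0.5), gt, cv = 0, seed = 23)
  expect_equal(per_genome_expression(p2)$per_genome, rep(0.5, 10))
})

test_that("a single doubled panel gene reads per-genome ratio 2 when total abundance is held", {
  g <- build_genome(120, seed = 24)
  gt <- genotype(c("3L" = 3))
  a <- assign_effect_classes(g, gt, c(compensation = 1), c(no_change = 1),
                             seed = 25)
  panel_genes <- g$gene_id[order(-g$baseline_mu)][1:10]
  target <- panel_genes[1]
  # double the target, absorb the abundance change across non-panel genes
  # so that total abundance (and hence T) stays exactly 1
  others <- setdiff(g$gene_id, panel_genes)
  extra <- g$baseline_mu[g$gene_id == target]
  r_other <- 1 - extra / sum(g$baseline_mu[g$gene_id %in% others])
  stopifnot(r_other > 0)
  a$expected_ratio[a$gene_id == target] <- 2
  a$expected_ratio[a$gene_id %in% others] <- r_other
  p <- simulate_ddpcr(g, a, gt, panel_genes = panel_genes, cv = 0, seed = 26)
  pg <- per_genome_expression(p)
  expect_equal(pg$per_genome[pg$gene_id == target], 2)
})

test_that("gDNA amplicons must sit on unvaried arms and carry 10+6 structure", {
  g <- build_genome(300, seed = 27)
  gt <- genotype(c("3L" = 3))
  a <- assign_effect_classes(g, gt, seed = 28)
  expect_error(
    simulate_ddpcr(g, a, gt, gdna_arms = c("3L", "1S", "1L", "2S", "2L", "4S")),
    "unvaried"
  )
  p <- simulate_ddpcr(g, a, gt, cv = 0.2, seed = 29)
  counts <- dplyr::count(p$aneuploid, sample, type)
  expect_true(all(counts$n[counts$type == "cDNA"] == 10))
  expect_true(all(counts$n[counts$type == "gDNA"] == 6))
  expect_true(all(p$aneuploid$concentration >= 0))
})
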
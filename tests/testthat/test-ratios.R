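test_that("RPKM normalization follows the reads-per-kilobase-per-million formula", {
  m <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(100, 0), s2 = c(100, 50))
  len <- c(g1 = 1000, g2 = 500)
  lib <- c(s1 = 1e6, s2 = 2e6)
  out <- normalize_rpkm(m, len, lib)
  expect_equal(out$s1, c(100, 0))
  expect_equal(out$s2, c(50, 50))  # doubling the library size halves values
  expect_error(normalize_rpkm(m, len, c(s1 = 0, s2 = 1e6)), "positive")
  expect_error(normalize_rpkm(m, c(g1 = 1000), lib), "cover")
})

test_that("replicate averaging is the arithmetic group mean", {
  m <- tibble::tibble(gene_id = c("g1", "g2"),
                      a1 = c(1, 10), a2 = c(3, 20), a3 = c(5, 60),
                      c1 = c(2, 8), c2 = c(4, 12))
  s <- tibble::tibble(sample_id = c("a1", "a2", "a3", "c1", "c2"),
                      group = c(rep("aneuploid", 3), rep("control", 2)))
  av <- average_replicates(m, s)
  expect_equal(av$mean_aneuploid, c(3, 30))
  expect_equal(av$mean_control, c(3, 10))
  # single replicate is the identity
  av1 <- average_replicates(m[c("gene_id", "a1", "c1")], s)
  expect_equal(av1$mean_aneuploid, m$a1)
  expect_error(
    average_replicates(m[c("gene_id", "a1", "a2")], s),
    "no samples in group 'control'"
  )
})

test_that("low-expression filter removes sums strictly below the threshold", {
  means <- tibble::tibble(
    gene_id = c("kept_boundary", "removed", "silent", "kept"),
    mean_aneuploid = c(0.5, 0.4, 0, 30),
    mean_control = c(0.5, 0.5, 0, 20)
  )
  kept <- filter_low_expression(means, threshold = 1)
  expect_setequal(kept$gene_id, c("kept_boundary", "kept"))
})

test_that("ratio computation flags non-finite and non-positive ratios", {
  means <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    mean_aneuploid = c(15, 7, 2, 0),
    mean_control = c(10, 7, 0, 5)
  )
  rt <- compute_ratios(means)
  expect_equal(rt$ratio[1:2], c(1.5, 1.0))
  expect_false(any(rt$flag[1:2]))
  expect_true(rt$flag[3])  # division by zero control mean
  expect_true(rt$flag[4])  # zero ratio cannot enter a median
  expect_equal(median_ratio(rt$ratio[!rt$flag]), 1.25)
})

test_that("cis/trans partition is per varied arm, exhaustive and exclusive", {
  g <- build_genome(600, seed = 30)
  gt <- genotype(c("3L" = 3, "4L" = 1))
  part <- partition_cis_trans(g, gt)
  expect_equal(part$partition[part$arm == "3L"][1], "cis:3L")
  expect_equal(part$partition[part$arm == "4L"][1], "cis:4L")
  expect_equal(part$partition[part$arm == "5S"][1], "trans")
  # arm granularity: the other arm of a varied chromosome is trans
  expect_equal(part$partition[part$arm == "3S"][1], "trans")
  expect_equal(nrow(part), nrow(g))
  expect_equal(sum(part$partition == "trans") +
                 sum(part$partition != "trans"), nrow(g))
  expect_error(partition_cis_trans(g, genotype(c("4L" = 2))), "vary at least")

  # joining a gene that the genome does not know is an error
  rt <- tibble::tibble(gene_id = c(g$gene_id[1], "alien"),
                       mean_aneuploid = c(1, 1), mean_control = c(1, 1)) |>
    compute_ratios()
  expect_error(add_partition(rt, g, gt), "unknown arm")
})

test_that("ratio binning uses half-open 0.05 bins and conserves counts", {
  rt <- tibble::tibble(
    ratio = c(1.02, 1.05, 1.049999, 0, 2.9999, 3.0, 7, Inf),
    flag = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE)
  )
  bins <- bin_ratios(rt, bin_width = 0.05, cap = 3)
  b <- as.data.frame(bins)
  pick <- function(left) b$n[abs(b$bin_left - left) < 1e-9 & is.finite(b$bin_right)]
  expect_equal(pick(1.00), 2L)  # 1.02 and 1.049999
  expect_equal(pick(1.05), 1L)  # 1.05 sits in the right-hand bin
  expect_equal(pick(2.95), 1L)
  overflow <- b$n[!is.finite(b$bin_right)]
  expect_equal(overflow, 4L)    # 3.0, 7, and the two flagged genes
  expect_equal(sum(b$n), nrow(rt))
  expect_error(bin_ratios(rt, bin_width = 0), "> 0")
})

test_that("median_ratio follows the standard even/odd conventions", {
  expect_equal(median_ratio(c(1.4, 1.5, 1.6)), 1.5)
  expect_equal(median_ratio(c(1.0, 2.0)), 1.5)
  expect_equal(median_ratio(c(Inf, 1, 3)), 2)  # non-finite values excluded
  expect_error(median_ratio(numeric(0)), "no finite")
})

test_that("noiseless ratios are compositional: every gene reads r/T", {
  g <- build_genome(800, seed = 31)
  gt <- genotype(c("3L" = 3))
  a <- assign_effect_classes(g, gt, c(dosage_effect = 0.5, compensation = 0.5),
                             c(inverse = 0.3, no_change = 0.7), seed = 32)
  pipe <- sim_ratio_pipeline(g, a, gt, dispersion = 0, seed = 33)
  truth <- a$expected_ratio[match(pipe$ratios$gene_id, a$gene_id)]
  expect_equal(pipe$ratios$ratio, truth / pipe$sim$size_factor,
               tolerance = 1e-12)
  # consequence: the cis median times T recovers the class ratio structure
  med <- pipe$medians
  cis_med <- med$median[med$partition == "cis:3L"]
  cis_truth <- truth[pipe$ratios$partition == "cis:3L"]
  expect_equal(cis_med * pipe$sim$size_factor, median(cis_truth),
               tolerance = 1e-9)
})

test_that("scatter table mirrors ratios and the DE caller's classes", {
  g <- build_genome(300, seed = 34)
  gt <- genotype(c("3L" = 3))
  a <- assign_effect_classes(g, gt, c(dosage_effect = 1), c(no_change = 1),
                             seed = 35)
  sim <- simulate_counts(g, a, gt, dispersion = 0.05, seed = 36)
  means <- average_replicates(sim$counts, sim$samples) |>
    filter_low_expression()
  rt <- compute_ratios(means) |> add_partition(g, gt)
  de <- call_de(dplyr::semi_join(sim$counts, rt, by = "gene_id"), sim$samples)
  sc <- scatter_table(rt, de)
  expect_equal(sc$lfc, log2(rt$ratio))
  expect_equal(sc$mean_expr, (rt$mean_aneuploid + rt$mean_control) / 2)
  expect_equal(sum(sc$class == "up"), sum(de$call == "up"))
  expect_equal(sum(sc$class == "down"), sum(de$call == "down"))
  expect_equal(attr(sc, "ref_ratios"), c(0.5, 0.67, 1.0, 1.5, 2.0))
})
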
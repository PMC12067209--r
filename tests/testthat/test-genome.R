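test_that("build_genome allocates genes to arms proportionally and reproducibly", {
  g <- build_genome(1000, arm_fractions = c(a = 0.05, b = 0.95), seed = 3)
  expect_equal(sum(g$arm == "a"), 50)
  expect_equal(sum(g$arm == "b"), 950)
  expect_false(anyDuplicated(g$gene_id) > 0)
  expect_true(all(is.finite(g$baseline_mu)) && all(g$baseline_mu > 0))
  expect_true(all(g$length > 0))

  expect_identical(g, build_genome(1000, c(a = 0.05, b = 0.95), seed = 3))
  g2 <- build_genome(1000, c(a = 0.05, b = 0.95), seed = 4)
  expect_false(identical(g$baseline_mu, g2$baseline_mu))
})

test_that("build_genome rejects bad arm tables", {
  expect_error(build_genome(10, c(a = 0.6, b = 0.6)), "sum to 1")
  expect_error(build_genome(10, setNames(rep(0.05, 20), paste0("arm", 1:20))),
               "at least the number of arms")
  expect_error(build_genome(100, c(0.5, 0.5)), "named")
})

test_that("genotype validates doses and reports varied arms", {
  gt <- genotype(c("3L" = 3, "5S" = 1))
  expect_setequal(varied_arms(gt), c("3L", "5S"))
  expect_equal(unname(arm_dose(gt, c("3L", "5S", "9L"))), c(3L, 1L, 2L))
  expect_error(genotype(c("3L" = 0)), "positive")
  expect_error(genotype(c("3L" = 5)), "1..4")
  expect_error(genotype(numeric(0)), "named")
})

test_that("expected_ratio reproduces the canonical dosage-response ratios", {
  expect_equal(expected_ratio("dosage_effect", 3), 1.5)
  expect_equal(expected_ratio("dosage_effect", 1), 0.5)
  expect_equal(expected_ratio("inverse", 3), 2 / 3)
  expect_equal(expected_ratio("inverse", 4), 1 / 2)
  expect_equal(expected_ratio("inverse", 1), 2)
  expect_equal(expected_ratio("direct", 3), 1.5)
  expect_equal(expected_ratio("compensation", 3), 1)
  # unvaried dose: every class sits at 1
  for (cl in c("dosage_effect", "compensation", "inverse", "direct", "no_change")) {
    expect_equal(expected_ratio(cl, 2), 1)
  }
  # the inverse effect exactly offsets a dosage effect at every dose
  for (d in 1:4) {
    expect_equal(expected_ratio("dosage_effect", d) * expected_ratio("inverse", d), 1)
  }
  expect_error(expected_ratio("dosage_effect", -1), "positive")
  expect_error(expected_ratio("mystery", 2), "unknown")
})

test_that("compose_trans_ratio implements the three composition rules", {
  expect_equal(compose_trans_ratio(c(2 / 3, 2 / 3)), 4 / 9)
  expect_equal(compose_trans_ratio(c(2 / 3, 2 / 3), mode = "additive"), 1 / 3)
  expect_equal(compose_trans_ratio(c(0.5, 1.2), mode = "dominant"), 0.5)
  expect_equal(compose_trans_ratio(c(0.9, 1.5), mode = "dominant"), 1.5)
  # a single ratio passes through every mode unchanged
  for (m in c("multiplicative", "additive", "dominant")) {
    expect_equal(compose_trans_ratio(0.8, mode = m), 0.8)
  }
  # additive composition never goes non-positive
  expect_gt(compose_trans_ratio(c(0.2, 0.2), mode = "additive"), 0)
  expect_error(compose_trans_ratio(numeric(0)), "non-empty")
})

test_that("assign_effect_classes honors degenerate mixtures and legality", {
  g <- build_genome(400, seed = 5)
  gt <- genotype(c("3L" = 3))
  a <- assign_effect_classes(g, gt, cis_proportions = c(dosage_effect = 1),
                             trans_proportions = c(no_change = 1), seed = 6)
  cis <- a[a$partition == "cis:3L", ]
  trans <- a[a$partition == "trans", ]
  expect_true(all(cis$effect_class == "dosage_effect"))
  expect_true(all(cis$expected_ratio == 1.5))
  expect_true(all(trans$expected_ratio == 1))
  expect_setequal(a$gene_id, g$gene_id)

  expect_error(
    assign_effect_classes(g, gt, cis_proportions = c(inverse = 1),
                          trans_proportions = c(no_change = 1)),
    "illegal"
  )
  expect_error(
    assign_effect_classes(g, gt, cis_proportions = c(dosage_effect = 0.5),
                          trans_proportions = c(no_change = 1)),
    "sum to 1"
  )
  expect_error(
    assign_effect_classes(g, genotype(c("3L" = 2)),
                          cis_proportions = c(dosage_effect = 1),
                          trans_proportions = c(no_change = 1)),
    "vary at least one arm"
  )
})

test_that("mixture sampling respects binomial bounds at large n", {
  # 50/50 inverse vs no_change over ~10^4 trans genes: the inverse count
  # must fall inside the 99% binomial interval around n/2
  g <- build_genome(10200, arm_fractions = c("3L" = 200 / 10200,
                                             other = 10000 / 10200), seed = 8)
  gt <- genotype(c("3L" = 3))
  a <- assign_effect_classes(g, gt, cis_proportions = c(compensation = 1),
                             trans_proportions = c(inverse = 0.5, no_change = 0.5),
                             seed = 9)
  n_trans <- sum(a$partition == "trans")
  n_inv <- sum(a$effect_class == "inverse")
  bounds <- qbinom(c(0.005, 0.995), n_trans, 0.5)
  expect_gte(n_inv, bounds[1])
  expect_lte(n_inv, bounds[2])
})

test_that("multi-arm trans ratios compose across the varied arms", {
  g <- build_genome(300, seed = 10)
  gt <- genotype(c("3L" = 1, "4L" = 3))
  a <- assign_effect_classes(g, gt, cis_proportions = c(compensation = 1),
                             trans_proportions = c(inverse = 1), seed = 11)
  trans <- a[a$partition == "trans", ]
  # inverse response: 2/1 from the monosomic arm times 2/3 from the trisomic
  expect_true(all(trans$expected_ratio == 2 * (2 / 3)))
  cis3 <- a[a$partition == "cis:3L", ]
  expect_true(all(cis3$expected_ratio == 1))
})
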
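# Shared fixtures and independent oracles, built in code at test time.

# Full ratio pipeline on a simulated experiment: RPKM -> replicate means ->
# low-expression filter -> ratios -> cis/trans partition -> medians.
sim_ratio_pipeline <- function(genome, assignment, gt, n_replicates = 3,
                               dispersion = 0, seed = 1, threshold = 1) {
  sim <- simulate_counts(genome, assignment, gt, n_replicates = n_replicates,
                         dispersion = dispersion, seed = seed)
  norm <- normalize_rpkm(sim$counts, stats::setNames(genome$length, genome$gene_id))
  ratios <- average_replicates(norm, sim$samples) |>
    filter_low_expression(threshold) |>
    compute_ratios() |>
    add_partition(genome, gt)
  list(sim = sim, ratios = ratios, medians = ratio_medians(ratios))
}

# One noisy transcriptome-size measurement: counts + ddPCR -> mean estimate
# and p-value of the size-change test.
size_sim_once <- function(genome, assignment, gt, dispersion, cv, seed) {
  sim <- simulate_counts(genome, assignment, gt, dispersion = dispersion,
                         seed = seed)
  panels <- simulate_ddpcr(genome, assignment, gt, cv = cv,
                           seed = seed + 100000L)
  means <- average_replicates(sim$counts, sim$samples) |>
    filter_low_expression()
  est <- size_estimates(
    per_genome_expression(panels),
    per_transcriptome_expression(means, panels$panel_genes)
  ) |>
    filter_outlier_estimates() |>
    estimate_size()
  c(mean = est$mean, p = est$p_value, size_factor = sim$size_factor)
}

# Brute-force two-sample K-S statistic: maximize |ECDF_x - ECDF_y| over all
# sample points (independent of the sorted-merge route in the package).
ks_d_brute <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# Direct evaluation of the classical Bartlett chi-square statistic.
bartlett_stat_formula <- function(groups) {
  ni <- lengths(groups)
  k <- length(groups)
  N <- sum(ni)
  vi <- vapply(groups, stats::var, numeric(1))
  sp2 <- sum((ni - 1) * vi) / (N - k)
  num <- (N - k) * log(sp2) - sum((ni - 1) * log(vi))
  den <- 1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1))
  num / den
}
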
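#' Run the simulation stage
#'
#' Builds the genome, genotype and effect assignment, simulates the RNA-seq
#' count matrix and the paired ddPCR panels, and writes every artifact plus
#' a ground-truth manifest (per-gene classes and expected ratios, the true
#' size factor T, per-stage row counts and the config) to `outdir`. All
#' randomness derives from `config$seed`; the same config yields a
#' byte-identical output tree.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the simulated objects (`genome`,
#'   `genotype`, `assignment`, `sim`, `panels`) and the written `paths`.
#' @export
run_simulate <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  genome <- build_genome(
    config$n_genes, config$arm_fractions,
    baseline_meanlog = config$baseline_meanlog,
    baseline_sdlog = config$baseline_sdlog,
    length_meanlog = config$length_meanlog,
    length_sdlog = config$length_sdlog,
    seed = seed + 1L
  )
  gt <- config_genotype(config)
  assignment <- assign_effect_classes(
    genome, gt,
    cis_proportions = config$cis_proportions,
    trans_proportions = config$trans_proportions,
    composition_mode = config$composition_mode,
    seed = seed + 2L
  )
  sim <- simulate_counts(
    genome, assignment, gt,
    n_replicates = config$n_replicates,
    library_size = config$library_size,
    dispersion = config$dispersion,
    seed = seed + 3L
  )
  panels <- simulate_ddpcr(
    genome, assignment, gt,
    cv = config$ddpcr_cv, n_samples = config$ddpcr_replicates,
    seed = seed + 4L
  )

  paths <- list(
    genome = file.path(outdir, "genome.tsv"),
    arms_bed = file.path(outdir, "arms.bed"),
    counts = file.path(outdir, "counts.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    ddpcr_aneuploid = file.path(outdir, "ddpcr_aneuploid.csv"),
    ddpcr_control = file.path(outdir, "ddpcr_control.csv"),
    manifest = file.path(outdir, "manifest.json")
  )
  write_gene_table(genome, paths$genome)
  write_arm_bed(genome, paths$arms_bed)
  write_count_matrix(sim$counts, paths$counts)
  write_sample_table(sim$samples, paths$samples)
  readr::write_tsv(assignment, paths$truth)
  write_ddpcr_panel(panels$aneuploid, paths$ddpcr_aneuploid)
  write_ddpcr_panel(panels$control, paths$ddpcr_control)

  manifest <- list(
    size_factor = sim$size_factor,
    n_genes = nrow(genome),
    n_samples = nrow(sim$samples),
    panel_genes = panels$panel_genes,
    gdna_arms = panels$gdna_arms,
    rows = list(counts = nrow(sim$counts), truth = nrow(assignment),
                ddpcr = nrow(panels$aneuploid)),
    config = config_for_json(config)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(genome = genome, genotype = gt, assignment = assignment,
                 sim = sim, panels = panels, paths = paths))
}

#' Run the ratio / statistics stage
#'
#' Reads the simulated (or user-supplied) count matrix, sample metadata and
#' gene table from `dir`, applies RPKM normalization, replicate averaging,
#' the low-expression filter, ratio computation, cis/trans partitioning,
#' 0.05 binning and per-partition medians, then the distribution tests
#' (each cis arm vs trans: Kolmogorov-Smirnov; all partitions: Bartlett),
#' the Welch-t differential-expression caller with BH adjustment, the
#' modulation summary, and the scatter table. All outputs are written next
#' to the inputs.
#'
#' @param config A [run_config()].
#' @param dir Directory holding `counts.tsv`, `samples.tsv`, `genome.tsv`.
#' @return Invisibly, a list with `ratio_table`, `bins`, `medians`, `tests`,
#'   `de_calls`, `modulation`, `scatter` and the written `paths`.
#' @export
run_analyze <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  counts <- read_count_matrix(file.path(dir, "counts.tsv"))
  samples <- read_sample_table(file.path(dir, "samples.tsv"))
  genome <- read_gene_table(file.path(dir, "genome.tsv"))
  gt <- config_genotype(config)

  norm <- normalize_rpkm(counts, setNames(genome$length, genome$gene_id))
  means <- average_replicates(norm, samples)
  kept <- filter_low_expression(means, config$filter_threshold)
  ratios <- compute_ratios(kept) %>% add_partition(genome, gt)

  bins <- bin_ratios(ratios, bin_width = config$bin_width, cap = config$bin_cap)
  medians <- ratio_medians(ratios)

  # distribution tests: each cis arm against trans, variances across all
  # partitions; degenerate (zero-variance) noiseless inputs are recorded as NA
  finite <- filter(ratios, !.data$flag)
  trans_r <- finite$ratio[finite$partition == "trans"]
  cis_parts <- sort(setdiff(unique(finite$partition), "trans"))
  ks <- bind_rows(lapply(cis_parts, function(p) {
    tryCatch(
      ks_two_sample(finite$ratio[finite$partition == p], trans_r,
                    label_x = p, label_y = "trans"),
      error = function(e) tibble(label_x = p, label_y = "trans",
                                 statistic = NA_real_, p_value = NA_real_,
                                 n_x = sum(finite$partition == p),
                                 n_y = length(trans_r))
    )
  }))
  bart <- tryCatch(
    bartlett_groups(split(finite$ratio, finite$partition)),
    error = function(e) tibble(statistic = NA_real_, df = NA_real_,
                               p_value = NA_real_,
                               k = length(unique(finite$partition)),
                               n = nrow(finite))
  )
  tests <- list(ks_cis_vs_trans = ks, bartlett_partitions = bart)

  de <- call_de(dplyr::semi_join(norm, kept, by = "gene_id"), samples,
                q_threshold = config$q_threshold)
  modulation <- summarize_modulation(de, select(ratios, "gene_id", "partition"))
  scat <- scatter_table(ratios, de)

  paths <- list(
    ratio_table = file.path(dir, "ratio_table.tsv"),
    bins = file.path(dir, "ratio_bins.tsv"),
    medians = file.path(dir, "medians.tsv"),
    tests = file.path(dir, "tests.json"),
    de_calls = file.path(dir, "de_calls.tsv"),
    modulation = file.path(dir, "modulation.json"),
    scatter = file.path(dir, "scatter.tsv")
  )
  readr::write_tsv(ratios, paths$ratio_table)
  readr::write_tsv(as_tibble(bins), paths$bins)
  readr::write_tsv(medians, paths$medians)
  jsonlite::write_json(tests, paths$tests, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  readr::write_tsv(de, paths$de_calls)
  jsonlite::write_json(modulation, paths$modulation, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  readr::write_tsv(as_tibble(scat), paths$scatter)

  invisible(list(ratio_table = ratios, bins = bins, medians = medians,
                 tests = tests, de_calls = de, modulation = modulation,
                 scatter = scat, paths = paths))
}

#' Run the transcriptome-size stage
#'
#' Reads the paired ddPCR panels, the count matrix and the manifest's panel
#' gene list from `dir`, forms the per-genome and per-transcriptome relative
#' expression, the ten per-gene size estimates, applies the 2-SD outlier
#' rule and reports mean, SE and the significance of the size change.
#'
#' @param config A [run_config()].
#' @param dir Directory holding the simulation outputs.
#' @return Invisibly, the `"size_estimate"` object (also written as
#'   `size_estimate.json` plus a bar-table `size_table.tsv`).
#' @export
run_size <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  counts <- read_count_matrix(file.path(dir, "counts.tsv"))
  samples <- read_sample_table(file.path(dir, "samples.tsv"))
  genome <- read_gene_table(file.path(dir, "genome.tsv"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  aneu <- read_ddpcr_panel(file.path(dir, "ddpcr_aneuploid.csv"))
  ctl <- read_ddpcr_panel(file.path(dir, "ddpcr_control.csv"))

  norm <- normalize_rpkm(counts, setNames(genome$length, genome$gene_id))
  means <- average_replicates(norm, samples) %>%
    filter_low_expression(config$filter_threshold)

  pg <- per_genome_expression(aneu, ctl)
  pt <- per_transcriptome_expression(means, manifest$panel_genes)
  est <- size_estimates(pg, pt) %>%
    filter_outlier_estimates(multiplier = config$outlier_multiplier) %>%
    estimate_size()

  report <- c(list(estimates = est$estimates), glance(est))
  jsonlite::write_json(report, file.path(dir, "size_estimate.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  readr::write_tsv(
    tibble(combination = genotype_label(config_genotype(config)),
           mean = est$mean, se = est$se, p_value = est$p_value),
    file.path(dir, "size_table.tsv"))
  invisible(est)
}

#' Assemble the run report
#'
#' Collects the medians, test results, modulation summary and size estimate
#' written by the earlier stages into a single `report.json`.
#'
#' @param config A [run_config()].
#' @param dir Directory holding the stage outputs.
#' @return Invisibly, the report list.
#' @export
run_report <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  report <- list(
    combination = genotype_label(config_genotype(config)),
    size_factor_true = jsonlite::read_json(
      file.path(dir, "manifest.json"), simplifyVector = TRUE)$size_factor,
    medians = readr::read_tsv(file.path(dir, "medians.tsv"),
                              col_types = "cid"),
    tests = jsonlite::read_json(file.path(dir, "tests.json"),
                                simplifyVector = TRUE),
    modulation = jsonlite::read_json(file.path(dir, "modulation.json"),
                                     simplifyVector = TRUE),
    size_estimate = jsonlite::read_json(file.path(dir, "size_estimate.json"),
                                        simplifyVector = TRUE)
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}

genotype_label <- function(gt) {
  varied <- varied_arms(gt)
  if (length(varied) == 0) return("euploid")
  d <- arm_dose(gt, varied)
  word <- c("mono", "di", "tri", "tetra")[d]
  paste(paste0(word, varied), collapse = "+")
}

config_for_json <- function(config) {
  x <- unclass(config)
  x$arm_fractions <- as.list(x$arm_fractions)
  x$cis_proportions <- as.list(x$cis_proportions)
  x$trans_proportions <- as.list(x$trans_proportions)
  x
}
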
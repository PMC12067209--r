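#' Pipeline run configuration
#'
#' Bundles every knob of the simulate/analyze/size pipeline with its
#' default. Thresholds default to the values of the published procedure:
#' low-expression filter 1, q threshold 0.05, ratio bin width 0.05, outlier
#' SD multiplier 2. The single `seed` governs the whole run; each stage
#' derives a fixed sub-seed from it.
#'
#' @param n_genes Genome size.
#' @param arm_fractions Named per-arm gene fractions (see
#'   [default_arm_fractions()]).
#' @param baseline_meanlog,baseline_sdlog,length_meanlog,length_sdlog
#'   Genome log-normal parameters (see [build_genome()]).
#' @param genotype_doses Named list/vector, arm -> dose.
#' @param background_ploidy Background ploidy.
#' @param cis_proportions,trans_proportions Effect-class mixtures.
#' @param composition_mode Trans composition rule for multi-arm genotypes.
#' @param dispersion,library_size,n_replicates RNA-seq simulation noise,
#'   depth and replication.
#' @param panel_size Number of ddPCR cDNA amplicons (10 in the assay).
#' @param ddpcr_cv,ddpcr_replicates ddPCR measurement noise and replicate
#'   samples per genotype.
#' @param filter_threshold,q_threshold,bin_width,bin_cap,outlier_multiplier
#'   Analysis thresholds.
#' @param seed Master seed.
#' @return A list of class `"run_config"`.
#' @export
#' @examples
#' cfg <- run_config(n_genes = 500, seed = 7)
#' cfg$genotype_doses
run_config <- function(n_genes = 2000,
                       arm_fractions = default_arm_fractions(),
                       baseline_meanlog = log(20), baseline_sdlog = 1,
                       length_meanlog = log(2000), length_sdlog = 0.5,
                       genotype_doses = list("3L" = 1, "4L" = 3),
                       background_ploidy = 2,
                       cis_proportions = c(dosage_effect = 0.4,
                                           compensation = 0.6),
                       trans_proportions = c(inverse = 0.35, direct = 0.10,
                                             no_change = 0.55),
                       composition_mode = "multiplicative",
                       dispersion = 0.05, library_size = 1e7,
                       n_replicates = 3,
                       panel_size = 10, ddpcr_cv = 0.1, ddpcr_replicates = 3,
                       filter_threshold = 1, q_threshold = 0.05,
                       bin_width = 0.05, bin_cap = 3,
                       outlier_multiplier = 2,
                       seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    arm_fractions = unlist(arm_fractions),
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    genotype_doses = as.list(setNames(as.integer(unlist(genotype_doses)),
                                      names(unlist(genotype_doses)))),
    background_ploidy = as.integer(background_ploidy),
    cis_proportions = unlist(cis_proportions),
    trans_proportions = unlist(trans_proportions),
    composition_mode = composition_mode,
    dispersion = dispersion, library_size = library_size,
    n_replicates = as.integer(n_replicates),
    panel_size = as.integer(panel_size),
    ddpcr_cv = ddpcr_cv, ddpcr_replicates = as.integer(ddpcr_replicates),
    filter_threshold = filter_threshold, q_threshold = q_threshold,
    bin_width = bin_width, bin_cap = bin_cap,
    outlier_multiplier = outlier_multiplier,
    seed = as.integer(seed)
  )
  # validate eagerly so a config error surfaces before any stage runs
  genotype(cfg$genotype_doses, cfg$background_ploidy)
  check_mixture(cfg$cis_proportions, cis_classes, "cis_proportions")
  check_mixture(cfg$trans_proportions, trans_classes, "trans_proportions")
  if (cfg$panel_size != 10L) abort("the ddPCR assay uses exactly 10 cDNA amplicons.")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  gt <- paste(sprintf("%s=%d", names(x$genotype_doses),
                      unlist(x$genotype_doses)), collapse = ", ")
  cat(sprintf("<run_config> %d genes, genotype {%s}, phi = %g, cv = %g, seed = %d\n",
              x$n_genes, gt, x$dispersion, x$ddpcr_cv, x$seed))
  invisible(x)
}

#' Write / read a run configuration (YAML)
#'
#' Configurations round-trip losslessly: `read_run_config(write_run_config(cfg))`
#' reproduces `cfg`.
#'
#' @param config A [run_config()] object.
#' @param path YAML file path.
#' @return `write_run_config` the path invisibly; `read_run_config` a
#'   `"run_config"`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$arm_fractions <- as.list(x$arm_fractions)
  x$cis_proportions <- as.list(x$cis_proportions)
  x$trans_proportions <- as.list(x$trans_proportions)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' Genotype encoded by a run configuration
#' @param config A [run_config()] object.
#' @return A [genotype()].
#' @export
config_genotype <- function(config) {
  genotype(config$genotype_doses, config$background_ploidy)
}
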
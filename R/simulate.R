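#' Simulate library-normalized RNA-seq counts for an aneuploid and its control
#'
#' True per-cell abundance of gene *g* is `A_g = baseline_mu_g * r_g`, with
#' `r_g` the assigned expected ratio. Sequencing sees only relative
#' abundance: the expected count of gene *g* in an aneuploid sample is
#' `library_size * A_g / sum(A)` and in a control sample
#' `library_size * baseline_mu_g / sum(baseline_mu)`. The true
#' transcriptome-size factor `T = sum(A) / sum(baseline_mu)` is recorded but
#' leaves the counts invariant (a global scaling of all `A_g` cancels), which
#' is exactly why ratio distributions cannot detect transcriptome-size
#' change. Counts are gamma-Poisson with dispersion `phi`
#' (`var = mu + phi * mu^2`); `dispersion = 0` returns the expectations.
#'
#' @param genome Genome tibble from [build_genome()].
#' @param assignment Tibble with `gene_id` and `expected_ratio` covering the
#'   genome, typically from [assign_effect_classes()].
#' @param genotype Optional [genotype()] recorded for provenance; if given,
#'   its varied arms must match the assignment's cis partitions.
#' @param n_replicates Biological replicates per group (>= 1).
#' @param library_size Reads per sample.
#' @param dispersion Gamma-Poisson dispersion `phi >= 0`.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return An object of class `"aneuploid_sim"`: a list with `counts` (tibble,
#'   `gene_id` plus one column per sample), `samples` (tibble `sample_id`,
#'   `group`, `replicate`), `size_factor` (the true `T`), `truth` (the
#'   assignment) and `genotype`.
#' @export
#' @examples
#' g <- build_genome(100, seed = 1)
#' gt <- genotype(c("3L" = 3))
#' a <- assign_effect_classes(g, gt, c(dosage_effect = 1), c(no_change = 1))
#' sim <- simulate_counts(g, a, gt, dispersion = 0)
#' sim$size_factor
simulate_counts <- function(genome, assignment, genotype = NULL,
                            n_replicates = 3L, library_size = 1e7,
                            dispersion = 0, seed = 1L) {
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  if (library_size <= 0) abort("`library_size` must be positive.")
  r <- align_ratios(genome, assignment)
  if (!is.null(genotype)) {
    stopifnot(inherits(genotype, "genotype"))
    if ("partition" %in% names(assignment)) {
      cis_arms <- sort(unique(sub("^cis:", "",
        assignment$partition[assignment$partition != "trans"])))
      if (!identical(cis_arms, sort(varied_arms(genotype)))) {
        abort("assignment cis partitions do not match the genotype's varied arms.")
      }
    }
  }

  mu0 <- genome$baseline_mu
  A <- mu0 * r
  size_factor <- sum(A) / sum(mu0)
  mu_aneu <- library_size * A / sum(A)
  mu_ctl <- library_size * mu0 / sum(mu0)

  samples <- tibble(
    sample_id = c(paste0("aneuploid_", seq_len(n_replicates)),
                  paste0("control_", seq_len(n_replicates))),
    group = rep(c("aneuploid", "control"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2L)
  )

  set.seed(seed)
  draw <- function(mu) {
    if (dispersion == 0) mu else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  mats <- lapply(seq_len(nrow(samples)), function(i) {
    draw(if (samples$group[i] == "aneuploid") mu_aneu else mu_ctl)
  })
  counts <- tibble(gene_id = genome$gene_id)
  for (i in seq_len(nrow(samples))) counts[[samples$sample_id[i]]] <- mats[[i]]

  structure(
    list(counts = counts, samples = samples, size_factor = size_factor,
         truth = assignment, genotype = genotype),
    class = "aneuploid_sim"
  )
}

#' @export
print.aneuploid_sim <- function(x, ...) {
  cat(sprintf("<aneuploid_sim> %d genes x %d samples, true size factor T = %.6g\n",
              nrow(x$counts), nrow(x$samples), x$size_factor))
  invisible(x)
}

#' Simulate paired ddPCR panels for an aneuploid and its control
#'
#' Total nucleic acid preparations preserve the in vivo mRNA/gDNA ratio, so
#' the cDNA signal of a panel gene is proportional to its per-cell abundance
#' `A_g = baseline_mu_g * r_g`, while each gDNA amplicon reports the copy
#' number of its arm (constant when placed on unvaried arms, as required
#' here so the per-genome normalization is dose neutral). Every measured
#' concentration carries mean-preserving log-normal noise with coefficient
#' of variation `cv`; `cv = 0` returns exact expectations. Droplet-level
#' Poisson statistics are not modeled: the analysis consumes concentrations.
#'
#' @param genome Genome tibble from [build_genome()].
#' @param assignment Tibble with `gene_id` and `expected_ratio`.
#' @param genotype A [genotype()].
#' @param panel_genes Ten panel gene ids; default: the 10 genes with highest
#'   baseline expression.
#' @param gdna_arms Six arm labels hosting the gDNA amplicons; must be
#'   unvaried in the genotype. Default: the first six unvaried arms.
#' @param cv Fractional measurement noise per concentration.
#' @param n_samples Replicate samples per genotype.
#' @param seed Integer seed.
#' @return An object of class `"ddpcr_panels"`: a list with `aneuploid` and
#'   `control` tibbles (`sample`, `amplicon_id`, `type` in cDNA/gDNA,
#'   `target`, `concentration`), plus `panel_genes`, `gdna_arms`, `cv`.
#' @export
simulate_ddpcr <- function(genome, assignment, genotype,
                           panel_genes = NULL, gdna_arms = NULL,
                           cv = 0, n_samples = 3L, seed = 1L) {
  stopifnot(inherits(genotype, "genotype"))
  if (cv < 0) abort("`cv` must be >= 0.")
  if (n_samples < 1) abort("`n_samples` must be >= 1.")
  r <- align_ratios(genome, assignment)
  varied <- varied_arms(genotype)

  if (is.null(panel_genes)) {
    panel_genes <- genome$gene_id[order(-genome$baseline_mu)][1:10]
  }
  if (length(panel_genes) != 10 || any(!panel_genes %in% genome$gene_id)) {
    abort("`panel_genes` must name 10 genes present in the genome.")
  }
  idx <- match(panel_genes, genome$gene_id)
  if (any(genome$baseline_mu[idx] <= 0)) {
    abort("panel genes must be expressed (baseline_mu > 0).")
  }
  if (is.null(gdna_arms)) {
    unvaried <- setdiff(unique(genome$arm), varied)
    if (length(unvaried) < 6) abort("fewer than 6 unvaried arms available.")
    gdna_arms <- sort(unvaried)[1:6]
  }
  if (length(gdna_arms) != 6 || any(!gdna_arms %in% genome$arm)) {
    abort("`gdna_arms` must name 6 arms present in the genome.")
  }
  if (any(gdna_arms %in% varied)) {
    abort("gDNA amplicons must be placed on arms unvaried in the genotype.")
  }

  p <- genotype$background_ploidy
  cdna_aneu <- genome$baseline_mu[idx] * r[idx]
  cdna_ctl <- genome$baseline_mu[idx]
  gdna_dose <- arm_dose(genotype, gdna_arms)  # == p for unvaried arms

  sdlog <- sqrt(log1p(cv^2))
  noise <- function(n) {
    if (cv == 0) rep(1, n) else exp(rnorm(n, -sdlog^2 / 2, sdlog))
  }
  one_panel <- function(expected_cdna, expected_gdna) {
    bind_rows(lapply(seq_len(n_samples), function(s) {
      tibble(
        sample = paste0("s", s),
        amplicon_id = c(paste0("c_", panel_genes), paste0("g_", gdna_arms)),
        type = rep(c("cDNA", "gDNA"), c(10L, 6L)),
        target = c(panel_genes, gdna_arms),
        concentration = c(expected_cdna, expected_gdna) * noise(16L)
      )
    }))
  }

  set.seed(seed)
  aneu <- one_panel(cdna_aneu, as.numeric(gdna_dose))
  ctl <- one_panel(cdna_ctl, rep(p, 6L))

  structure(
    list(aneuploid = aneu, control = ctl,
         panel_genes = panel_genes, gdna_arms = gdna_arms, cv = cv),
    class = "ddpcr_panels"
  )
}

#' @export
print.ddpcr_panels <- function(x, ...) {
  cat(sprintf(
    "<ddpcr_panels> 10 cDNA + 6 gDNA amplicons, %d sample(s)/genotype, cv = %g\n",
    length(unique(x$aneuploid$sample)), x$cv))
  invisible(x)
}

# Align assignment expected ratios to genome gene order; validates coverage.
align_ratios <- function(genome, assignment) {
  if (!all(c("gene_id", "expected_ratio") %in% names(assignment))) {
    abort("`assignment` needs columns `gene_id` and `expected_ratio`.")
  }
  i <- match(genome$gene_id, assignment$gene_id)
  if (anyNA(i)) abort("`assignment` does not cover every gene in `genome`.")
  r <- assignment$expected_ratio[i]
  if (any(!is.finite(r)) || any(r <= 0)) {
    abort("expected ratios must be finite and positive.")
  }
  r
}
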
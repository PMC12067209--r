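#' Default chromosome-arm layout
#'
#' Twenty arms (short and long arm of ten chromosomes, maize-style labels
#' `"1S"`, `"1L"`, ..., `"10L"`), each holding an equal fraction of the gene
#' complement. A single arm therefore carries 5% of the genes, in line with
#' the few-percent genomic share of a typical translocated arm segment.
#'
#' @return A named numeric vector of per-arm gene fractions summing to 1.
#' @export
#' @examples
#' default_arm_fractions()
default_arm_fractions <- function() {
  arms <- paste0(rep(1:10, each = 2), c("S", "L"))
  setNames(rep(1 / length(arms), length(arms)), arms)
}

#' Build a synthetic genome model
#'
#' Generates a gene table with arm assignments, gene lengths, and baseline
#' expression levels (expected transcripts per cell equivalent, drawn
#' log-normally). Genes are laid out sequentially along each chromosome so
#' that the model can also be expressed as BED intervals (see
#' [write_arm_bed()] and [assign_arms()]).
#'
#' @param n_genes Number of genes; must be at least the number of arms.
#' @param arm_fractions Named vector mapping arm label to the fraction of
#'   genes it carries; must sum to 1. Gene counts per arm are proportional
#'   up to rounding.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   baseline expression `baseline_mu`.
#' @param length_meanlog,length_sdlog Log-normal parameters of gene length
#'   in bases.
#' @param seed Integer seed; the same seed reproduces the genome exactly.
#'
#' @return A tibble with columns `gene_id`, `arm`, `chrom`, `start`, `end`
#'   (0-based half-open coordinates), `length` and `baseline_mu`.
#' @export
#' @examples
#' g <- build_genome(200, seed = 1)
#' dplyr::count(g, arm)
build_genome <- function(n_genes,
                         arm_fractions = default_arm_fractions(),
                         baseline_meanlog = log(20), baseline_sdlog = 1,
                         length_meanlog = log(2000), length_sdlog = 0.5,
                         seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1) {
    abort("`n_genes` must be a single positive number.")
  }
  n_genes <- as.integer(n_genes)
  if (is.null(names(arm_fractions)) || any(!nzchar(names(arm_fractions))) ||
      anyDuplicated(names(arm_fractions))) {
    abort("`arm_fractions` must be a uniquely named vector of arm labels.")
  }
  if (any(arm_fractions < 0)) abort("arm fractions must be non-negative.")
  if (abs(sum(arm_fractions) - 1) > 1e-6) {
    abort("arm fractions must sum to 1.")
  }
  if (n_genes < length(arm_fractions)) {
    abort("`n_genes` must be at least the number of arms.")
  }

  # proportional allocation (+/- rounding), conserving n_genes exactly
  alloc <- diff(c(0L, as.integer(round(cumsum(arm_fractions) * n_genes))))
  arm <- rep(names(arm_fractions), alloc)

  set.seed(seed)
  len <- pmax(200, round(exp(rnorm(n_genes, length_meanlog, length_sdlog))))
  mu <- exp(rnorm(n_genes, baseline_meanlog, baseline_sdlog))

  genome <- tibble(
    gene_id = sprintf("g%05d", seq_len(n_genes)),
    arm = arm,
    chrom = sub("[SL]$", "", arm),
    length = as.numeric(len),
    baseline_mu = mu
  )

  # sequential 0-based half-open coordinates along each chromosome,
  # short arm first, with a fixed intergenic gap
  gap <- 1000
  genome <- genome %>%
    group_by(.data$chrom) %>%
    mutate(
      end = cumsum(.data$length + gap),
      start = .data$end - .data$length
    ) %>%
    ungroup() %>%
    select("gene_id", "arm", "chrom", "start", "end", "length", "baseline_mu")
  genome
}

#' Specify an aneuploid genotype
#'
#' A genotype is a map from chromosome-arm label to integer copy number
#' (dose) on a diploid background; arms absent from the map carry the
#' background ploidy. The varied unit is the translocated arm segment, so
#' the other arm of the same chromosome remains unvaried (trans).
#'
#' @param arm_doses Named numeric vector or list, arm label -> dose in 1..4,
#'   e.g. `c("3L" = 3)` for trisomy 3L or `c("3L" = 1, "4L" = 3)` for
#'   monosomy 3L + trisomy 4L.
#' @param background_ploidy Background ploidy, 2 for the diploid series.
#' @return An object of class `"genotype"`.
#' @export
#' @examples
#' genotype(c("3L" = 3))
#' genotype(c("3L" = 1, "4L" = 3))
genotype <- function(arm_doses, background_ploidy = 2L) {
  doses <- unlist(arm_doses)
  if (length(doses) == 0 || is.null(names(doses)) || any(!nzchar(names(doses)))) {
    abort("`arm_doses` must be a non-empty named vector (arm -> dose).")
  }
  if (anyDuplicated(names(doses))) abort("duplicated arm labels in `arm_doses`.")
  if (any(doses <= 0)) abort("doses must be positive integers.")
  if (any(doses != round(doses)) || any(!doses %in% 1:4)) {
    abort("doses must be integers in 1..4.")
  }
  background_ploidy <- as.integer(background_ploidy)
  if (length(background_ploidy) != 1L || background_ploidy < 1L) {
    abort("`background_ploidy` must be a single positive integer.")
  }
  structure(
    list(arm_doses = setNames(as.integer(doses), names(doses)),
         background_ploidy = background_ploidy),
    class = "genotype"
  )
}

#' @export
print.genotype <- function(x, ...) {
  varied <- varied_arms(x)
  cat("<genotype> background ploidy", x$background_ploidy, "\n")
  if (length(varied) == 0) {
    cat("  no varied arms (euploid)\n")
  } else {
    for (a in varied) {
      cat(sprintf("  %s: dose %d\n", a, x$arm_doses[[a]]))
    }
  }
  invisible(x)
}

#' Arms whose dose differs from the background ploidy
#'
#' @param genotype A [genotype()] object.
#' @return Character vector of varied arm labels (possibly empty).
#' @export
varied_arms <- function(genotype) {
  stopifnot(inherits(genotype, "genotype"))
  names(genotype$arm_doses)[genotype$arm_doses != genotype$background_ploidy]
}

#' Dose of one or more arms under a genotype
#'
#' @param genotype A [genotype()] object.
#' @param arms Character vector of arm labels.
#' @return Integer vector of doses; arms absent from the genotype map get
#'   the background ploidy.
#' @export
arm_dose <- function(genotype, arms) {
  stopifnot(inherits(genotype, "genotype"))
  d <- genotype$arm_doses[arms]
  d[is.na(d)] <- genotype$background_ploidy
  setNames(as.integer(d), arms)
}
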
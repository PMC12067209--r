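#' Relative expression per genome from paired ddPCR panels
#'
#' For each panel gene the cDNA concentration is normalized to each of the
#' six gDNA amplicons and the resulting six ratios are averaged (this
#' minimizes gDNA primer-efficiency effects); the averaged normalization is
#' then compared aneuploid over control. Replicate samples within a panel
#' are averaged on the normalized scale before the between-genotype ratio is
#' formed.
#'
#' @param panel_aneu Either a `"ddpcr_panels"` object from
#'   [simulate_ddpcr()] (in which case `panel_ctl` is taken from it) or the
#'   aneuploid panel tibble (`sample`, `amplicon_id`, `type`, `target`,
#'   `concentration`).
#' @param panel_ctl Control panel tibble (ignored when `panel_aneu` is a
#'   `"ddpcr_panels"` object).
#' @return Tibble `gene_id`, `per_genome`.
#' @export
per_genome_expression <- function(panel_aneu, panel_ctl = NULL) {
  if (inherits(panel_aneu, "ddpcr_panels")) {
    panel_ctl <- panel_aneu$control
    panel_aneu <- panel_aneu$aneuploid
  }
  if (is.null(panel_ctl)) abort("`panel_ctl` is missing.")
  na <- panel_norm(panel_aneu)
  nc <- panel_norm(panel_ctl)
  if (!setequal(na$gene_id, nc$gene_id)) {
    abort("panels do not share the same cDNA amplicons.")
  }
  out <- inner_join(na, nc, by = "gene_id", suffix = c("_aneu", "_ctl"))
  tibble(gene_id = out$gene_id,
         per_genome = out$norm_aneu / out$norm_ctl)
}

# mean over the 6 gDNA amplicons of cDNA_g / gDNA_j, averaged over samples
panel_norm <- function(panel) {
  need <- c("sample", "amplicon_id", "type", "target", "concentration")
  if (!all(need %in% names(panel))) {
    abort(paste0("panel needs columns: ", paste(need, collapse = ", ")))
  }
  per_sample <- lapply(split(panel, panel$sample), function(p) {
    cdna <- p[p$type == "cDNA", ]
    gdna <- p[p$type == "gDNA", ]
    if (nrow(cdna) != 10 || nrow(gdna) != 6) {
      abort("each sample must carry exactly 10 cDNA and 6 gDNA amplicons.")
    }
    if (any(gdna$concentration <= 0)) abort("zero or negative gDNA signal.")
    tibble(gene_id = cdna$target,
           norm = vapply(cdna$concentration,
                         function(c0) mean(c0 / gdna$concentration), numeric(1)))
  })
  ord <- unique(panel$target[panel$type == "cDNA"])
  bind_rows(per_sample) %>%
    group_by(.data$gene_id) %>%
    summarise(norm = mean(.data$norm), .groups = "drop") %>%
    arrange(match(.data$gene_id, ord))
}

#' Relative expression per transcriptome from RNA-seq
#'
#' The library-normalized RNA-seq counterpart of the ddPCR measurement: the
#' aneuploid/control ratio of averaged normalized expression for each panel
#' gene. A global transcriptome scaling cancels here, which is the
#' asymmetry the size estimator exploits.
#'
#' @param means Tibble from [average_replicates()] (after the
#'   low-expression filter used for the ratio analysis).
#' @param panel_genes Character vector of panel gene ids; every panel gene
#'   must be present (an error names any gene that was filtered out).
#' @return Tibble `gene_id`, `per_transcriptome`.
#' @export
per_transcriptome_expression <- function(means, panel_genes) {
  missing <- setdiff(panel_genes, means$gene_id)
  if (length(missing) > 0) {
    abort(paste0("panel gene(s) absent from the expression table: ",
                 paste(missing, collapse = ", ")))
  }
  rows <- means[match(panel_genes, means$gene_id), ]
  tibble(gene_id = panel_genes,
         per_transcriptome = rows$mean_aneuploid / rows$mean_control)
}

#' Per-gene transcriptome-size estimates
#'
#' Each panel gene gives one independent estimate of the relative
#' transcriptome size: (relative expression per genome) / (relative
#' expression per transcriptome). With no noise every estimate equals the
#' true size factor T, whatever the gene's own dosage response.
#'
#' @param per_genome Tibble from [per_genome_expression()].
#' @param per_transcriptome Tibble from [per_transcriptome_expression()].
#' @return Tibble `gene_id`, `per_genome`, `per_transcriptome`, `estimate`.
#' @export
size_estimates <- function(per_genome, per_transcriptome) {
  if (!setequal(per_genome$gene_id, per_transcriptome$gene_id)) {
    abort("`per_genome` and `per_transcriptome` must cover the same genes.")
  }
  out <- inner_join(per_genome, per_transcriptome, by = "gene_id")
  if (any(!is.finite(out$per_genome)) || any(out$per_genome <= 0) ||
      any(!is.finite(out$per_transcriptome)) || any(out$per_transcriptome <= 0)) {
    abort("inputs must be finite and positive.")
  }
  mutate(out, estimate = .data$per_genome / .data$per_transcriptome)
}

#' Flag outlier size estimates (2-SD rule)
#'
#' Single pass: with m the mean and s the (n-1) sample standard deviation of
#' all estimates, an estimate is removed iff `|m - estimate| >= multiplier * s`.
#' When s is zero (all estimates equal) nothing is removed. Removing more
#' than half of the panel is reported as a data-quality warning; removing
#' everything is an error.
#'
#' @param estimates Tibble with an `estimate` column (e.g. from
#'   [size_estimates()]) or a bare numeric vector.
#' @param multiplier SD multiplier of the exclusion rule (default 2).
#' @return The estimates tibble with a logical `retained` column.
#' @export
#' @examples
#' filter_outlier_estimates(c(1, 1, 1, 1, 1, 3))  # removes the 3
filter_outlier_estimates <- function(estimates, multiplier = 2) {
  if (is.numeric(estimates)) estimates <- tibble(estimate = estimates)
  x <- estimates$estimate
  if (length(x) < 2) abort("need at least two estimates.")
  m <- mean(x)
  s <- sd(x)
  if (degenerate_spread(s, m)) s <- 0
  retained <- if (s == 0) rep(TRUE, length(x)) else abs(m - x) < multiplier * s
  if (!any(retained)) abort("all estimates removed: degenerate panel.")
  if (sum(!retained) > floor(length(x) / 2)) {
    warn("data-quality: outlier rule removed more than half of the estimates.")
  }
  estimates$retained <- retained
  estimates
}

#' Final transcriptome-size estimate
#'
#' Mean and standard error over the retained per-gene estimates, with a
#' two-sided one-sample t test against 1.0 for the significance of the size
#' change. When the retained estimates have zero spread the t statistic is
#' undefined; the p-value is then 1 if the mean is exactly 1 and 0 otherwise
#' (a noiseless simulation either is or is not at the null).
#'
#' @param estimates Tibble with `estimate` and optionally `retained`
#'   (from [filter_outlier_estimates()]); without a `retained` column all
#'   estimates are used.
#' @return An object of class `"size_estimate"` with fields `estimates`,
#'   `mean`, `se`, `n_retained`, `n_total`, `statistic`, `df`, `p_value`.
#'   [tidy()] returns the per-gene table, [glance()] the one-row summary.
#' @export
estimate_size <- function(estimates) {
  if (is.numeric(estimates)) estimates <- tibble(estimate = estimates)
  if (!"retained" %in% names(estimates)) estimates$retained <- TRUE
  x <- estimates$estimate[estimates$retained]
  if (length(x) < 2) abort("need at least two retained estimates.")
  m <- mean(x)
  s <- sd(x)
  if (degenerate_spread(s, m)) s <- 0
  se <- s / sqrt(length(x))
  if (s > 0) {
    tt <- t.test(x, mu = 1)
    stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  } else {
    stat <- NA_real_; df <- length(x) - 1
    p <- if (isTRUE(all.equal(m, 1))) 1 else 0
  }
  structure(
    list(estimates = estimates, mean = m, se = se,
         n_retained = length(x), n_total = nrow(estimates),
         statistic = stat, df = df, p_value = p),
    class = "size_estimate"
  )
}

#' @export
print.size_estimate <- function(x, ...) {
  cat(sprintf(
    "<size_estimate> mean = %.4g, SE = %.3g (n = %d/%d retained), p vs 1.0 = %.3g\n",
    x$mean, x$se, x$n_retained, x$n_total, x$p_value))
  invisible(x)
}

# spread indistinguishable from floating-point noise on the mean
degenerate_spread <- function(s, m) {
  s <= 100 * .Machine$double.eps * max(abs(m), 1)
}

#' @rdname estimate_size
#' @param x A `"size_estimate"` object.
#' @param ... Unused.
#' @method tidy size_estimate
#' @export
tidy.size_estimate <- function(x, ...) {
  x$estimates
}

#' @rdname estimate_size
#' @method glance size_estimate
#' @export
glance.size_estimate <- function(x, ...) {
  tibble(mean = x$mean, se = x$se, n_retained = x$n_retained,
         n_total = x$n_total, statistic = x$statistic, df = x$df,
         p_value = x$p_value)
}
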
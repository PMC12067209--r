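#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `raw * 1e9 / (library_size * length)`.
#'
#' @param counts Wide tibble: `gene_id` plus one numeric column per sample.
#' @param gene_lengths Named numeric vector (gene_id -> length in bases) or a
#'   tibble with columns `gene_id` and `length`.
#' @param library_sizes Named numeric vector (sample -> mapped reads). If
#'   `NULL`, per-sample column totals are used.
#' @return The counts tibble on the RPKM scale.
#' @export
#' @examples
#' m <- tibble::tibble(gene_id = "g1", s1 = 100)
#' normalize_rpkm(m, c(g1 = 1000), c(s1 = 1e6))  # 100
normalize_rpkm <- function(counts, gene_lengths, library_sizes = NULL) {
  samples <- sample_columns(counts)
  if (is.data.frame(gene_lengths)) {
    gene_lengths <- setNames(gene_lengths$length, gene_lengths$gene_id)
  }
  len <- unname(gene_lengths[counts$gene_id])
  if (anyNA(len)) abort("`gene_lengths` does not cover every gene.")
  if (any(len <= 0)) abort("gene lengths must be positive.")
  if (is.null(library_sizes)) {
    library_sizes <- vapply(counts[samples], sum, numeric(1))
  }
  lib <- library_sizes[samples]
  if (anyNA(lib)) abort("`library_sizes` does not cover every sample.")
  if (any(lib <= 0)) abort("library sizes must be positive.")
  for (s in samples) {
    counts[[s]] <- counts[[s]] * 1e9 / (lib[[s]] * len)
  }
  counts
}

#' Average biological replicates within each group
#'
#' @param counts Wide tibble of normalized expression (`gene_id` + samples).
#' @param samples Tibble with `sample_id` and `group` (values `"aneuploid"`
#'   or `"control"`).
#' @return Tibble `gene_id`, `mean_aneuploid`, `mean_control`.
#' @export
average_replicates <- function(counts, samples) {
  cols <- sample_columns(counts)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    abort("`samples` needs columns `sample_id` and `group`.")
  }
  if (any(!samples$group %in% c("aneuploid", "control"))) {
    abort("sample groups must be 'aneuploid' or 'control'.")
  }
  if (any(!cols %in% samples$sample_id)) {
    abort("every sample column must appear in `samples`.")
  }
  grp <- setNames(samples$group, samples$sample_id)[cols]
  for (g in c("aneuploid", "control")) {
    if (!any(grp == g)) abort(sprintf("no samples in group '%s'.", g))
  }
  m <- as.matrix(counts[cols])
  if (any(m < 0, na.rm = TRUE)) abort("expression values must be non-negative.")
  tibble(
    gene_id = counts$gene_id,
    mean_aneuploid = rowMeans(m[, grp == "aneuploid", drop = FALSE]),
    mean_control = rowMeans(m[, grp == "control", drop = FALSE])
  )
}

#' Remove lowly expressed genes
#'
#' A gene is retained iff the sum of its averaged aneuploid and control
#' expression is at least `threshold` (genes with sum strictly below the
#' threshold are regarded as lowly expressed and dropped). The threshold is
#' on the same normalized scale used for the ratios.
#'
#' @param means Tibble from [average_replicates()].
#' @param threshold Retention threshold (default 1).
#' @return The retained rows of `means`.
#' @export
filter_low_expression <- function(means, threshold = 1) {
  filter(means, .data$mean_aneuploid + .data$mean_control >= threshold)
}

#' Per-gene aneuploid/control expression ratios
#'
#' Adds `ratio = mean_aneuploid / mean_control` and a `flag` column marking
#' genes whose ratio is not finite and positive (e.g. zero control mean).
#' Flagged genes are excluded from medians and counted in the histogram
#' overflow bin rather than dropped silently.
#'
#' @param means Tibble from [average_replicates()], usually after
#'   [filter_low_expression()].
#' @return `means` with `ratio` and `flag` columns.
#' @export
compute_ratios <- function(means) {
  mutate(means,
    ratio = .data$mean_aneuploid / .data$mean_control,
    flag = !(is.finite(.data$ratio) & .data$ratio > 0)
  )
}

#' Partition genes into cis (per varied arm) and trans
#'
#' Genes on a varied arm are labeled `"cis:<arm>"`, kept separate per arm in
#' multi-arm combinations; every other gene is `"trans"`. Trans therefore
#' excludes the cis genes of every varied arm. The varied unit is the arm
#' segment: genes on the other arm of the same chromosome are trans.
#'
#' @param genome Genome tibble (needs `gene_id`, `arm`).
#' @param genotype A [genotype()] with at least one varied arm.
#' @return Tibble `gene_id`, `arm`, `partition`.
#' @export
partition_cis_trans <- function(genome, genotype) {
  stopifnot(inherits(genotype, "genotype"))
  varied <- varied_arms(genotype)
  if (length(varied) == 0) abort("`genotype` must vary at least one arm.")
  if (any(is.na(genome$arm))) abort("gene with unknown arm in `genome`.")
  genome %>%
    select("gene_id", "arm") %>%
    mutate(partition = ifelse(.data$arm %in% varied,
                              paste0("cis:", .data$arm), "trans"))
}

#' Attach partition labels to a ratio table
#'
#' @param ratio_tbl Tibble from [compute_ratios()].
#' @param genome,genotype Passed to [partition_cis_trans()].
#' @return `ratio_tbl` with `partition` (and `arm`) columns.
#' @export
add_partition <- function(ratio_tbl, genome, genotype) {
  part <- partition_cis_trans(genome, genotype)
  out <- left_join(ratio_tbl, part, by = "gene_id")
  if (anyNA(out$partition)) {
    missing <- out$gene_id[is.na(out$partition)]
    abort(paste0("gene(s) with unknown arm: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  out
}

#' Bin ratios into a fixed-width histogram
#'
#' Half-open, left-closed bins `[k*w, (k+1)*w)` of width `w = 0.05` by
#' default; ratios at or above `cap` (and flagged non-finite ratios) are
#' pooled in an overflow bin reported with `bin_right = Inf`. Counts are
#' conserved: bins plus overflow sum to the number of genes per partition.
#'
#' @param ratio_tbl Tibble with a `ratio` column; optional `flag` and
#'   `partition` columns (a single `"all"` partition is assumed otherwise).
#' @param bin_width Bin width `w > 0`.
#' @param cap Display cap pooling large ratios (medians elsewhere always use
#'   uncapped values).
#' @return A tibble of class `"ratio_bins"`: `partition`, `bin_left`,
#'   `bin_right`, `n`.
#' @export
bin_ratios <- function(ratio_tbl, bin_width = 0.05, cap = 3) {
  if (!is.numeric(bin_width) || bin_width <= 0) abort("`bin_width` must be > 0.")
  if (cap <= 0) abort("`cap` must be > 0.")
  if (!"partition" %in% names(ratio_tbl)) ratio_tbl$partition <- "all"
  if (!"flag" %in% names(ratio_tbl)) {
    ratio_tbl$flag <- !(is.finite(ratio_tbl$ratio) & ratio_tbl$ratio > 0)
  }
  k_cap <- as.integer(round(cap / bin_width))
  # floor(x / w) with a one-part-in-1e9 snap so that ratios lying exactly on
  # a bin edge (e.g. 1.05 with w = 0.05) land in the right-hand bin despite
  # floating-point division error
  k <- floor(ratio_tbl$ratio / bin_width + 1e-9)
  overflow <- ratio_tbl$flag | k >= k_cap
  k[overflow] <- NA

  counted <- tibble(partition = ratio_tbl$partition, k = k) %>%
    filter(!is.na(.data$k)) %>%
    count(.data$partition, .data$k)
  grid <- tidyr::crossing(partition = unique(ratio_tbl$partition),
                          k = seq_len(k_cap) - 1)
  bins <- grid %>%
    left_join(counted, by = c("partition", "k")) %>%
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           bin_left = .data$k * bin_width,
           bin_right = (.data$k + 1) * bin_width) %>%
    select("partition", "bin_left", "bin_right", "n")
  over <- tibble(partition = ratio_tbl$partition, flag = overflow) %>%
    group_by(.data$partition) %>%
    summarise(n = sum(.data$flag), .groups = "drop") %>%
    mutate(bin_left = k_cap * bin_width, bin_right = Inf) %>%
    select("partition", "bin_left", "bin_right", "n")
  out <- bind_rows(bins, over) %>% arrange(.data$partition, .data$bin_left)
  structure(out, class = c("ratio_bins", class(out)),
            bin_width = bin_width, cap = cap)
}

#' Median of a set of expression ratios
#'
#' Standard sample median (mean of the central pair for even n) over the
#' finite, positive ratios.
#'
#' @param ratios Numeric vector of ratios.
#' @return A single median.
#' @export
median_ratio <- function(ratios) {
  x <- ratios[is.finite(ratios) & ratios > 0]
  if (length(x) == 0) abort("no finite positive ratios.")
  median(x)
}

#' Per-partition median ratios
#'
#' @param ratio_tbl Tibble with `ratio`, `flag` and `partition` columns.
#' @return Tibble `partition`, `n` (genes entering the median), `median`.
#' @export
ratio_medians <- function(ratio_tbl) {
  ratio_tbl %>%
    filter(!.data$flag) %>%
    group_by(.data$partition) %>%
    summarise(n = dplyr::n(), median = median_ratio(.data$ratio),
              .groups = "drop")
}

#' Differential-expression scatter table
#'
#' One row per gene with `lfc = log2(mean_aneuploid / mean_control)` on the
#' x axis, the mean of the two group means on the y axis, and the
#' significance class taken from the differential-expression calls
#' (magenta/green/black in the original display become `"up"`, `"down"`,
#' `"ns"`). Reference ratios 0.5, 0.67, 1.0, 1.5 and 2.0 are attached as the
#' `ref_ratios` attribute for plotting.
#'
#' @param ratio_tbl Ratio table (with `partition` if available).
#' @param de_calls Tibble from [call_de()].
#' @return A tibble of class `"scatter_table"`: `gene_id`, `lfc`,
#'   `mean_expr`, `class`, `flag` (plus `partition` when present).
#' @export
scatter_table <- function(ratio_tbl, de_calls) {
  out <- ratio_tbl %>%
    left_join(select(de_calls, "gene_id", "call"), by = "gene_id") %>%
    mutate(
      lfc = log2(.data$ratio),
      mean_expr = (.data$mean_aneuploid + .data$mean_control) / 2,
      class = ifelse(is.na(.data$call), "ns", .data$call),
      flag = !is.finite(.data$lfc)
    )
  keep <- intersect(c("gene_id", "partition", "lfc", "mean_expr", "class", "flag"),
                    names(out))
  out <- select(out, dplyr::all_of(keep))
  structure(out, class = c("scatter_table", class(out)),
            ref_ratios = c(0.5, 0.67, 1.0, 1.5, 2.0))
}

sample_columns <- function(counts) {
  if (!"gene_id" %in% names(counts)) abort("`counts` needs a `gene_id` column.")
  cols <- setdiff(names(counts), "gene_id")
  if (length(cols) == 0) abort("`counts` has no sample columns.")
  cols
}
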
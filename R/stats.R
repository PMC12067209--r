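#' Two-sample Kolmogorov-Smirnov test between ratio distributions
#'
#' D is the supremum over the merged sample points of the absolute
#' difference of the two empirical distribution functions; the p-value uses
#' the asymptotic Kolmogorov distribution with effective sample size
#' `n_x * n_y / (n_x + n_y)` (tie warnings from discrete ratio data are
#' suppressed; at the gene-set sizes involved the asymptotic p is the
#' appropriate one).
#'
#' @param x,y Numeric samples of ratios (each non-empty).
#' @param label_x,label_y Optional labels recorded with the result.
#' @return One-row tibble: `label_x`, `label_y`, `statistic` (D), `p_value`,
#'   `n_x`, `n_y`.
#' @export
#' @examples
#' ks_two_sample(c(1, 2, 3), c(4, 5, 6))  # D = 1
ks_two_sample <- function(x, y, label_x = "x", label_y = "y") {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty.")
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  tibble(
    label_x = label_x, label_y = label_y,
    statistic = unname(res$statistic), p_value = res$p.value,
    n_x = length(x), n_y = length(y)
  )
}

#' Bartlett's test for equal variances across groups
#'
#' Classical Bartlett chi-square statistic with k - 1 degrees of freedom and
#' its upper-tail p-value. Each group needs at least two observations and
#' positive variance (the statistic is undefined otherwise).
#'
#' @param groups A named list of numeric vectors, one per group.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `k`, `n`.
#' @export
#' @examples
#' bartlett_groups(list(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8)))
bartlett_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("`groups` must be a list of at least two samples.")
  }
  groups <- lapply(groups, function(g) g[is.finite(g)])
  sizes <- lengths(groups)
  if (any(sizes < 2)) abort("every group needs at least two observations.")
  if (any(vapply(groups, var, numeric(1)) <= 0)) {
    abort("a group has zero variance; Bartlett's statistic is undefined.")
  }
  res <- stats::bartlett.test(groups)
  tibble(
    statistic = unname(res$statistic), df = unname(res$parameter),
    p_value = res$p.value, k = length(groups), n = sum(sizes)
  )
}

#' Call differential expression between aneuploid and control replicates
#'
#' Per-gene unequal-variance (Welch) t test on `log2(x + pseudocount)` of
#' the normalized expression, with Benjamini-Hochberg step-up adjustment
#' across all tested genes. A gene is called `"up"`/`"down"` when its
#' adjusted q is below `q_threshold`, with direction from the sign of the
#' log2 fold change (difference of group means on the log scale). If either
#' group has both zero variance and the same mean as the other the p-value
#' is 1; two constant but different groups give p = 0. With fewer than two
#' replicates in a group no test is possible: all calls are `"ns"` with a
#' warning.
#'
#' @param counts Wide tibble of normalized expression (`gene_id` + samples).
#' @param samples Tibble with `sample_id` and `group`.
#' @param q_threshold Significance threshold on the adjusted q (default 0.05).
#' @param pseudocount Added before the log transform (default 0.5).
#' @return Tibble `gene_id`, `lfc`, `p`, `q`, `call`.
#' @export
call_de <- function(counts, samples, q_threshold = 0.05, pseudocount = 0.5) {
  cols <- sample_columns(counts)
  grp <- setNames(samples$group, samples$sample_id)[cols]
  if (anyNA(grp)) abort("every sample column must appear in `samples`.")
  a_cols <- cols[grp == "aneuploid"]
  c_cols <- cols[grp == "control"]
  logm <- log2(as.matrix(counts[cols]) + pseudocount)
  m1 <- rowMeans(logm[, a_cols, drop = FALSE])
  m2 <- rowMeans(logm[, c_cols, drop = FALSE])
  lfc <- m1 - m2

  if (length(a_cols) < 2 || length(c_cols) < 2) {
    warn("fewer than two replicates in a group: no tests performed, all calls 'ns'.")
    return(tibble(gene_id = counts$gene_id, lfc = lfc,
                  p = NA_real_, q = NA_real_, call = "ns"))
  }

  n1 <- length(a_cols); n2 <- length(c_cols)
  v1 <- apply(logm[, a_cols, drop = FALSE], 1, var)
  v2 <- apply(logm[, c_cols, drop = FALSE], 1, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  # degenerate genes: both groups constant
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  q <- p.adjust(p, method = "BH")
  call <- dplyr::case_when(
    q < q_threshold & lfc > 0 ~ "up",
    q < q_threshold & lfc < 0 ~ "down",
    TRUE ~ "ns"
  )
  tibble(gene_id = counts$gene_id, lfc = lfc, p = p, q = q, call = call)
}

#' Summarize how strongly each partition is modulated
#'
#' For each partition: the percentage of unchanged genes
#' `100 * (N - N_DE) / N` (the dosage-compensation read-out for cis arms),
#' and the percentages of significantly up- (SU), down-regulated (SD) and
#' all differentially expressed genes relative to the partition total (the
#' trans modulation read-out; `pct_de = pct_su + pct_sd` by construction).
#'
#' @param de_calls Tibble from [call_de()].
#' @param partition Tibble with `gene_id` and `partition` covering the same
#'   gene set as `de_calls`.
#' @return Tibble `partition`, `n_genes`, `n_up`, `n_down`, `n_de`,
#'   `pct_unchanged`, `pct_su`, `pct_sd`, `pct_de`.
#' @export
summarize_modulation <- function(de_calls, partition) {
  if (nrow(de_calls) == 0 || nrow(partition) == 0) {
    abort("empty calls or partition.")
  }
  if (!setequal(de_calls$gene_id, partition$gene_id)) {
    abort("`de_calls` and `partition` must cover the same genes.")
  }
  de_calls %>%
    inner_join(select(partition, "gene_id", "partition"), by = "gene_id") %>%
    group_by(.data$partition) %>%
    summarise(
      n_genes = dplyr::n(),
      n_up = sum(.data$call == "up"),
      n_down = sum(.data$call == "down"),
      .groups = "drop"
    ) %>%
    mutate(
      n_de = .data$n_up + .data$n_down,
      pct_unchanged = 100 * (.data$n_genes - .data$n_de) / .data$n_genes,
      pct_su = 100 * .data$n_up / .data$n_genes,
      pct_sd = 100 * .data$n_down / .data$n_genes,
      pct_de = 100 * .data$n_de / .data$n_genes
    )
}
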
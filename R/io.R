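#' Read and write the tabular interchange formats
#'
#' Count matrices travel as TSV with a header row of sample ids and
#' `gene_id` in the first column; sample metadata as TSV with `sample_id`,
#' `group`, `replicate`; ddPCR panels as CSV with `sample`, `amplicon_id`,
#' `type` (cDNA/gDNA), `target`, `concentration`; arm annotation as 4-column
#' BED (0-based, half-open: chrom, start, end, arm label).
#'
#' @param path File path.
#' @param counts,samples,panel,genome Tibbles in the shapes produced by the
#'   simulator.
#' @name aneuploidr-io
NULL

#' @rdname aneuploidr-io
#' @export
read_count_matrix <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()))
}

#' @rdname aneuploidr-io
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname aneuploidr-io
#' @export
read_sample_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), group = readr::col_character(),
    .default = readr::col_guess()))
}

#' @rdname aneuploidr-io
#' @export
write_sample_table <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}

#' @rdname aneuploidr-io
#' @export
read_ddpcr_panel <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    sample = readr::col_character(), amplicon_id = readr::col_character(),
    type = readr::col_character(), target = readr::col_character(),
    concentration = readr::col_double()))
}

#' @rdname aneuploidr-io
#' @export
write_ddpcr_panel <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' @rdname aneuploidr-io
#' @export
read_gene_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), arm = readr::col_character(),
    chrom = readr::col_character(), .default = readr::col_double()))
}

#' @rdname aneuploidr-io
#' @export
write_gene_table <- function(genome, path) {
  readr::write_tsv(genome, path)
  invisible(path)
}

#' Read a 4-column arm annotation BED file
#'
#' BED is 0-based and half-open; column 4 holds the arm label.
#'
#' @param path BED file path.
#' @return Tibble `chrom`, `start`, `end`, `arm`.
#' @export
read_arm_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "arm"),
                  col_types = "ciic")
}

#' Write arm intervals spanned by a genome model as BED
#'
#' One interval per arm, covering the genes assigned to it (0-based,
#' half-open).
#'
#' @param genome Genome tibble with `chrom`, `start`, `end`, `arm`.
#' @param path Output BED path.
#' @return The arm interval tibble, invisibly.
#' @export
write_arm_bed <- function(genome, path) {
  arms <- genome %>%
    group_by(.data$chrom, .data$arm) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") %>%
    arrange(.data$chrom, .data$start) %>%
    select("chrom", "start", "end", "arm")
  readr::write_tsv(arms, path, col_names = FALSE)
  invisible(arms)
}

#' Assign genes to arms by interval containment
#'
#' Maps genes with coordinates onto arm intervals (0-based half-open on
#' both sides); a gene is assigned to the arm containing its start.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`.
#' @param arm_bed Tibble from [read_arm_bed()].
#' @return `genes` with an `arm` column; genes falling outside every arm
#'   interval raise an error.
#' @export
assign_arms <- function(genes, arm_bed) {
  hit <- genes %>%
    left_join(arm_bed, by = "chrom", suffix = c("", "_arm"),
              relationship = "many-to-many") %>%
    filter(.data$start >= .data$start_arm, .data$start < .data$end_arm) %>%
    select("gene_id", "arm")
  out <- left_join(select(genes, -dplyr::any_of("arm")), hit, by = "gene_id")
  if (anyNA(out$arm)) {
    abort(paste0("gene(s) outside every arm interval: ",
                 paste(head(out$gene_id[is.na(out$arm)], 5), collapse = ", ")))
  }
  out
}
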
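cis_classes <- c("dosage_effect", "compensation")
trans_classes <- c("inverse", "direct", "no_change")
all_classes <- c(cis_classes, trans_classes)

#' Expected aneuploid/control expression ratio for an effect class
#'
#' The canonical dosage-response ratios on a background ploidy `p`: a gene
#' with a *dosage effect* scales with its copy number (`d/p`, so 1.5 in
#' trisomy and 0.5 in monosomy); *dosage compensation* leaves expression
#' unchanged (1); the *inverse effect* modulates trans genes opposite to the
#' dose change (`p/d`, about 2/3 in trisomy and 1/2 in tetrasomy, doubled in
#' monosomy); a *direct effect* moves trans genes with the dose (`d/p`);
#' `no_change` is 1.
#'
#' @param effect_class Character vector drawn from `"dosage_effect"`,
#'   `"compensation"`, `"inverse"`, `"direct"`, `"no_change"`.
#' @param dose Integer dose(s) in 1..4.
#' @param ploidy Background ploidy (default 2).
#' @return Numeric vector of positive expected ratios.
#' @export
#' @examples
#' expected_ratio("dosage_effect", 3)  # 1.5
#' expected_ratio("inverse", 3)        # 2/3
#' expected_ratio("inverse", 1)        # 2
expected_ratio <- function(effect_class, dose, ploidy = 2) {
  if (any(!effect_class %in% all_classes)) {
    abort(paste0("unknown effect class: ",
                 paste(setdiff(effect_class, all_classes), collapse = ", ")))
  }
  if (any(dose <= 0)) abort("`dose` must be positive.")
  if (any(!dose %in% 1:4)) abort("`dose` must be an integer in 1..4.")
  n <- max(length(effect_class), length(dose))
  effect_class <- rep_len(effect_class, n)
  dose <- rep_len(dose, n)
  dplyr::case_when(
    effect_class == "dosage_effect" ~ dose / ploidy,
    effect_class == "direct" ~ dose / ploidy,
    effect_class == "inverse" ~ ploidy / dose,
    TRUE ~ 1
  )
}

#' Compose per-arm trans ratios across a multi-arm aneuploid
#'
#' How trans-gene responses to two (or more) simultaneously varied arms
#' combine is an empirical question; all three composition rules are
#' available. `"multiplicative"` takes the product of the per-arm ratios,
#' `"additive"` accumulates deviations from 1 (`1 + sum(r - 1)`, floored at
#' a small positive value), and `"dominant"` keeps the per-arm ratio with
#' the largest magnitude on the log scale.
#'
#' @param per_arm_ratios Non-empty numeric vector of positive per-arm ratios.
#' @param mode One of `"multiplicative"` (default), `"additive"`, `"dominant"`.
#' @param eps Positive floor applied to the additive composition.
#' @return A single positive ratio.
#' @export
#' @examples
#' compose_trans_ratio(c(2/3, 2/3))                     # 4/9
#' compose_trans_ratio(c(2/3, 2/3), mode = "additive")  # 1/3
compose_trans_ratio <- function(per_arm_ratios,
                                mode = c("multiplicative", "additive", "dominant"),
                                eps = 1e-6) {
  mode <- match.arg(mode)
  if (length(per_arm_ratios) == 0) abort("`per_arm_ratios` must be non-empty.")
  if (any(!is.finite(per_arm_ratios)) || any(per_arm_ratios <= 0)) {
    abort("`per_arm_ratios` must be finite and positive.")
  }
  switch(mode,
    multiplicative = prod(per_arm_ratios),
    additive = max(1 + sum(per_arm_ratios - 1), eps),
    dominant = per_arm_ratios[which.max(abs(log(per_arm_ratios)))]
  )
}

#' Assign dosage-response classes and expected ratios to every gene
#'
#' Genes on varied arms (cis) are assigned classes from the cis mixture
#' (`dosage_effect` or `compensation`); all other genes (trans) draw from
#' the trans mixture (`inverse`, `direct`, `no_change`). Each gene's
#' expected aneuploid/control ratio follows from its class and the dose of
#' the relevant arm(s); trans responses to multiple varied arms are combined
#' with [compose_trans_ratio()].
#'
#' @param genome Genome tibble from [build_genome()] (needs `gene_id`, `arm`).
#' @param genotype A [genotype()] with at least one varied arm.
#' @param cis_proportions Named non-negative mixture over
#'   `c("dosage_effect", "compensation")`, summing to 1.
#' @param trans_proportions Named non-negative mixture over
#'   `c("inverse", "direct", "no_change")`, summing to 1.
#' @param composition_mode Passed to [compose_trans_ratio()].
#' @param seed Integer seed for the class sampling.
#' @return A tibble with `gene_id`, `arm`, `partition` (`"cis:<arm>"` or
#'   `"trans"`), `effect_class`, `expected_ratio`.
#' @export
#' @examples
#' g <- build_genome(200, seed = 1)
#' a <- assign_effect_classes(g, genotype(c("3L" = 3)),
#'   cis_proportions = c(dosage_effect = 1),
#'   trans_proportions = c(no_change = 1))
#' dplyr::count(a, partition, effect_class, expected_ratio)
assign_effect_classes <- function(genome, genotype,
                                  cis_proportions = c(dosage_effect = 0.4,
                                                      compensation = 0.6),
                                  trans_proportions = c(inverse = 0.35,
                                                        direct = 0.10,
                                                        no_change = 0.55),
                                  composition_mode = "multiplicative",
                                  seed = 1L) {
  stopifnot(inherits(genotype, "genotype"))
  check_mixture(cis_proportions, cis_classes, "cis_proportions")
  check_mixture(trans_proportions, trans_classes, "trans_proportions")
  varied <- varied_arms(genotype)
  if (length(varied) == 0) {
    abort("`genotype` must vary at least one arm.")
  }
  p <- genotype$background_ploidy
  doses <- arm_dose(genotype, varied)

  set.seed(seed)
  out <- genome %>%
    select("gene_id", "arm") %>%
    mutate(partition = ifelse(.data$arm %in% varied,
                              paste0("cis:", .data$arm), "trans"))

  is_cis <- out$partition != "trans"
  class <- character(nrow(out))
  class[is_cis] <- sample(names(cis_proportions), sum(is_cis),
                          replace = TRUE, prob = cis_proportions)
  class[!is_cis] <- sample(names(trans_proportions), sum(!is_cis),
                           replace = TRUE, prob = trans_proportions)

  # trans ratios depend only on the class: compose the per-arm responses once
  trans_ratio <- vapply(trans_classes, function(cl) {
    if (cl == "no_change") return(1)
    compose_trans_ratio(expected_ratio(cl, doses, p), mode = composition_mode)
  }, numeric(1))

  ratio <- numeric(nrow(out))
  ratio[is_cis] <- expected_ratio(class[is_cis],
                                  arm_dose(genotype, out$arm[is_cis]), p)
  ratio[!is_cis] <- trans_ratio[class[!is_cis]]

  out$effect_class <- class
  out$expected_ratio <- ratio
  out
}

#' Apply a global transcriptome-size scaling to an assignment
#'
#' Multiplies every gene's expected ratio by a constant, emulating a pure
#' change in mRNA per cell with no relative reshuffling. Library-normalized
#' counts are invariant to this scaling; only genome-normalized (ddPCR)
#' measurements can see it.
#'
#' @param assignment Assignment tibble from [assign_effect_classes()].
#' @param factor Positive scalar.
#' @return The assignment with `expected_ratio` scaled.
#' @export
scale_expected_ratios <- function(assignment, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    abort("`factor` must be a single positive number.")
  }
  mutate(assignment, expected_ratio = .data$expected_ratio * factor)
}

check_mixture <- function(props, legal, what) {
  if (length(props) == 0 || is.null(names(props))) {
    abort(sprintf("`%s` must be a named numeric mixture.", what))
  }
  bad <- setdiff(names(props), legal)
  if (length(bad) > 0) {
    abort(sprintf("`%s` names illegal class(es) for its partition: %s",
                  what, paste(bad, collapse = ", ")))
  }
  if (any(props < 0) || abs(sum(props) - 1) > 1e-8) {
    abort(sprintf("`%s` must be non-negative and sum to 1.", what))
  }
  invisible(TRUE)
}
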
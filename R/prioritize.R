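#' Is a variant predicted functional through its coding consequence?
#'
#' TRUE for non-synonymous, stop-gain, stop-loss, frameshift and splicing
#' variants; synonymous and non-coding classes are not coding-functional.
#'
#' @param region_class character vector over [region_classes()].
#' @return logical vector.
#' @export
classify_coding_functional <- function(region_class) {
  region_class %in% c("exonic-nonsynonymous", "stopgain", "stoploss",
                      "frameshift", "splicing")
}

#' Is a variant predicted functional through regulatory evidence?
#'
#' TRUE when the RegulomeDB-style integer class is at most 5 AND the variant
#' overlaps at least one transcription-factor binding site or DNase I
#' hypersensitive site. Score ordering uses the leading integer only, so
#' "3a" ranks as 3. Missing annotations classify as non-functional.
#'
#' @param regulome_class integer class 1-7 (NA = unannotated).
#' @param tf_or_dhs_overlap logical.
#' @return logical vector.
#' @export
classify_regulatory <- function(regulome_class, tf_or_dhs_overlap) {
  out <- !is.na(regulome_class) & regulome_class <= 5 &
    !is.na(tf_or_dhs_overlap) & tf_or_dhs_overlap
  out
}

#' Is a 3'UTR variant predicted functional through Argonaute binding?
#'
#' TRUE when the variant lies in a 3'UTR and at least one CLIP-seq experiment
#' reported Argonaute protein binding over it (a proxy for a microRNA
#' binding site).
#'
#' @param region_class character vector.
#' @param ago_evidence_count nonnegative integer vector (NA = unannotated).
#' @return logical vector.
#' @export
classify_utr3_functional <- function(region_class, ago_evidence_count) {
  region_class == "utr3" & !is.na(ago_evidence_count) &
    ago_evidence_count >= 1
}

#' Assign variants to functional strata
#'
#' Builds the four analysis strata used by the stratified gene-based tests:
#' `all` (every variant), `coding` (coding-functional), `regulatory`
#' (regulatory evidence or 3'UTR Argonaute binding), and `combined`
#' (coding union regulatory). Variants without an annotation record count as
#' non-functional; their number is reported via a message.
#'
#' @param variants variant tibble with `variant` and `region_class`.
#' @param annotations annotation tibble with `variant`, `regulome_class`,
#'   `tf_or_dhs_overlap`, `ago_evidence_count` (may be empty or NULL).
#' @return tibble of class `strata_assignment`: `variant` plus logical
#'   columns `all`, `coding`, `regulatory`, `combined`.
#' @export
build_strata <- function(variants, annotations = NULL) {
  v <- variants[c("variant", "region_class")]
  if (is.null(annotations) || nrow(annotations) == 0) {
    ann <- tibble(variant = character(), regulome_class = integer(),
                  tf_or_dhs_overlap = logical(),
                  ago_evidence_count = integer())
  } else {
    ann <- annotations[c("variant", "regulome_class", "tf_or_dhs_overlap",
                         "ago_evidence_count")]
  }
  joined <- left_join(v, ann, by = "variant")
  n_missing <- sum(is.na(joined$regulome_class))
  if (n_missing > 0) {
    inform(sprintf(
      "%d variant(s) without annotation treated as non-functional", n_missing))
  }
  out <- joined %>%
    mutate(
      all = TRUE,
      coding = classify_coding_functional(.data$region_class),
      regulatory = classify_regulatory(.data$regulome_class,
                                       .data$tf_or_dhs_overlap) |
        classify_utr3_functional(.data$region_class,
                                 .data$ago_evidence_count),
      combined = .data$coding | .data$regulatory
    ) %>%
    select("variant", "all", "coding", "regulatory", "combined") %>%
    arrange(.data$variant)
  class(out) <- c("strata_assignment", class(out))
  out
}

# named list of variant-key sets, one per stratum, clipped to `universe`
strata_sets <- function(strata, universe = NULL) {
  sets <- lapply(c(all = "all", coding = "coding", regulatory = "regulatory",
                   combined = "combined"),
                 function(col) strata$variant[strata[[col]]])
  if (!is.null(universe)) sets <- lapply(sets, intersect, y = universe)
  sets
}

#' Select genotyping candidate variants from a single-variant scan
#'
#' A variant is carried forward to targeted genotyping if it satisfies any
#' of: (a) association p-value below `p_cut`; (b) rare (pooled two-group MAF
#' below `maf_cut`) and enriched in one group (MAF difference beyond
#' `min_diff`); (c) coding-functional with a group MAF difference beyond
#' `min_diff`. The union is deduplicated and returned in deterministic
#' (variant key) order.
#'
#' @param scan a [single_variant_scan()] tibble.
#' @param variants variant tibble supplying `region_class` per variant.
#' @param p_cut significance threshold, default 0.05.
#' @param maf_cut rarity threshold on the pooled MAF, default 0.05.
#' @param min_diff minimal group MAF difference for criteria (b) and (c);
#'   default 0 (any nonzero difference).
#' @param n_cases,n_controls group sizes used to weight the pooled MAF;
#'   equal weights when omitted.
#' @return tibble of selected variants with a `criteria` label column.
#' @export
select_genotyping_candidates <- function(scan, variants,
                                         p_cut = 0.05, maf_cut = 0.05,
                                         min_diff = 0,
                                         n_cases = NULL, n_controls = NULL) {
  w_case <- if (is.null(n_cases)) 0.5 else n_cases / (n_cases + n_controls)
  df <- left_join(as_tibble(scan), variants[c("variant", "region_class")],
                  by = "variant") %>%
    mutate(
      pooled_maf = w_case * .data$maf_cases + (1 - w_case) * .data$maf_controls,
      maf_diff = abs(.data$maf_cases - .data$maf_controls),
      crit_a = !is.na(.data$p_allelic) & .data$p_allelic < p_cut,
      crit_b = !is.na(.data$pooled_maf) & .data$pooled_maf < maf_cut &
        .data$maf_diff > min_diff,
      crit_c = classify_coding_functional(.data$region_class) &
        .data$maf_diff > min_diff
    )
  df %>%
    filter(.data$crit_a | .data$crit_b | .data$crit_c) %>%
    mutate(criteria = paste0(ifelse(.data$crit_a, "a", ""),
                             ifelse(.data$crit_b, "b", ""),
                             ifelse(.data$crit_c, "c", ""))) %>%
    select("variant", "maf_cases", "maf_controls", "p_allelic", "direction",
           "region_class", "criteria") %>%
    distinct(.data$variant, .keep_all = TRUE) %>%
    arrange(.data$variant)
}
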
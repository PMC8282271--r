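#' Genes significant in a gene-based scan
#'
#' @param gene_results a [gene_scan()] tibble (or any tibble with `gene`,
#'   `p`, and optionally `stratum`/`method` columns).
#' @param alpha significance threshold; strictly below (a gene at exactly
#'   `alpha` is excluded).
#' @param stratum,method which scan slice to use when those columns exist.
#' @return character vector of significant genes.
#' @export
significant_genes <- function(gene_results, alpha = 0.05,
                              stratum = "all", method = "SKAT") {
  df <- as_tibble(gene_results)
  if ("stratum" %in% names(df)) df <- filter(df, .data$stratum == !!stratum)
  if ("method" %in% names(df)) df <- filter(df, .data$method == !!method)
  unique(df$gene[!is.na(df$p) & df$p < alpha])
}

#' Sub-pathway over-representation of significant genes
#'
#' One-sided hypergeometric (over-representation) test per gene set: the
#' p-value is the probability of observing at least the seen number of
#' significant genes in a set of its size, given the number significant in
#' the universe. The enrichment ratio is the significant fraction in the set
#' over the significant fraction in the universe. Nominal p-values are the
#' primary output (mirroring the study's convention); a Benjamini-Hochberg
#' column is appended as supplementary information.
#'
#' @param sig character vector of significant genes (clipped to `universe`).
#' @param sets named list of gene sets (clipped to `universe`; clips are
#'   reported via a message).
#' @param universe character vector of all tested genes.
#' @return tibble of class `enrichment_result`, ordered by p-value:
#'   `sub_pathway`, `n_category`, `n_category_significant`, `n_universe`,
#'   `n_universe_significant`, `p`, `enrichment_ratio`, `neg_log10_p`,
#'   `p_adjust`.
#' @export
subpathway_enrichment <- function(sig, sets, universe) {
  if (!length(universe)) stop_validation("empty gene universe")
  universe <- unique(universe)
  sig_out <- setdiff(sig, universe)
  if (length(sig_out)) {
    inform(sprintf("%d significant gene(s) outside the universe dropped",
                   length(sig_out)))
  }
  sig <- intersect(unique(sig), universe)
  N <- length(universe)
  K <- length(sig)

  rows <- purrr::imap(sets, function(genes, name) {
    g <- intersect(unique(genes), universe)
    if (length(g) < length(unique(genes))) {
      inform(sprintf("set '%s': %d gene(s) outside the universe clipped",
                     name, length(unique(genes)) - length(g)))
    }
    m <- length(g)
    k <- length(intersect(g, sig))
    p <- if (m == 0) 1 else phyper(k - 1, K, N - K, m, lower.tail = FALSE)
    tibble(
      sub_pathway = name, n_category = m, n_category_significant = k,
      n_universe = N, n_universe_significant = K, p = p,
      enrichment_ratio = if (m == 0 || K == 0) 0 else (k / m) / (K / N),
      neg_log10_p = -log10(p)
    )
  })
  out <- bind_rows(rows) %>%
    mutate(p_adjust = stats::p.adjust(.data$p, method = "BH")) %>%
    arrange(.data$p, .data$sub_pathway)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' @importFrom stats phyper
NULL
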
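#' Per-variant alternate-allele frequency by phenotype group
#'
#' For genotype data, the group frequency is the alternate-allele count over
#' `2 x` non-missing individuals (complete cases per variant). For pooled
#' data, it is the pool-size-weighted mean of the per-pool frequencies within
#' each phenotype group. Frequencies are alternate-allele frequencies; no
#' minor-allele folding is applied here (folding happens only where a weight
#' function demands a MAF).
#'
#' @param x a `cohort` or `pool_af` object.
#' @return tibble: `variant`, `maf_cases`, `maf_controls` (NA when a group is
#'   entirely missing for a variant).
#' @export
maf_by_group <- function(x) {
  UseMethod("maf_by_group")
}

#' @export
maf_by_group.cohort <- function(x) {
  group_af <- function(G) {
    nn <- rowSums(!is.na(G))
    af <- rowSums(G, na.rm = TRUE) / (2 * nn)
    af[nn == 0] <- NA_real_
    unname(af)
  }
  tibble(
    variant = rownames(x$genotypes),
    maf_cases = group_af(x$genotypes[, x$phenotype == 1L, drop = FALSE]),
    maf_controls = group_af(x$genotypes[, x$phenotype == 0L, drop = FALSE])
  )
}

#' @export
maf_by_group.pool_af <- function(x) {
  wmean <- function(af, w) {
    if (!length(w)) return(rep(NA_real_, nrow(af)))
    as.vector(af %*% w) / sum(w)
  }
  cases <- x$pools$phenotype == 1L
  tibble(
    variant = rownames(x$af),
    maf_cases = wmean(x$af[, cases, drop = FALSE], x$pools$size[cases]),
    maf_controls = wmean(x$af[, !cases, drop = FALSE], x$pools$size[!cases])
  )
}

#' Reconstruct integer allele counts from a printed allele frequency
#'
#' Bridges 3-decimal published MAFs back to count tables: the minor count is
#' round-half-up of `maf * 2n`, the major count is the complement.
#'
#' @param maf allele frequency in [0, 1].
#' @param n_individuals group sample size.
#' @return tibble with `minor` and `major` integer counts.
#' @examples
#' reconstruct_counts(0.012, 450)  # 11 / 889
#' @export
reconstruct_counts <- function(maf, n_individuals) {
  stopifnot(all(maf >= 0 & maf <= 1), all(n_individuals >= 1))
  minor <- round_half_up(maf * 2 * n_individuals)
  tibble(minor = minor, major = 2L * as.integer(n_individuals) - minor)
}

#' Two-sided Fisher exact test on a 2x2 table (point-probability rule)
#'
#' Computes the exact conditional p-value by summing, over the hypergeometric
#' support at fixed margins, the probabilities of all tables whose
#' point probability does not exceed that of the observed table (with a
#' `1e-7` relative tolerance against ties lost to floating point). This is
#' the convention of standard exact-test implementations.
#'
#' @param table 2x2 integer matrix: rows = groups, columns = (minor, major)
#'   allele counts.
#' @return p-value in (0, 1].
#' @examples
#' allelic_fisher(matrix(c(11, 889, 1, 999), 2, byrow = TRUE))
#' @export
allelic_fisher <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(table < 0)) stop_validation("negative counts in 2x2 table")
  if (any(rowSums(table) == 0)) {
    stop_validation("zero row margin: both groups need observed alleles")
  }
  a <- table[1, 1]
  m <- sum(table[1, ]); n2 <- sum(table[2, ]); k <- sum(table[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Exact conditional test on a 2x3 genotype table
#'
#' Full enumeration of all 2x3 tables with the observed margins; the p-value
#' sums the conditional (multivariate hypergeometric) probabilities of tables
#' no more probable than the observed one. Exact only at desk-scale margins:
#' enumeration is guarded by `max_tables`.
#'
#' @param table 2x3 integer matrix: rows = groups, columns = genotype classes
#'   (e.g. 0/1/2 alternate-allele copies).
#' @param max_tables cap on the enumeration size.
#' @return p-value in (0, 1].
#' @export
genotypic_fisher <- function(table, max_tables = 2e6) {
  stopifnot(is.matrix(table), nrow(table) == 2, ncol(table) == 3)
  if (any(table < 0)) stop_validation("negative counts in 2x3 table")
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  if (r1 == 0 || r2 == 0) stop_validation("zero group margin")
  cs <- colSums(table)
  n11_rng <- max(0, r1 - cs[2] - cs[3]):min(r1, cs[1])
  if (length(n11_rng) * (min(r1, cs[2]) + 1) > max_tables) {
    stop_validation(paste0(
      "margins too large for exact 2x3 enumeration; ",
      "use the allelic test instead"))
  }
  # conditional log-probability of a table given margins:
  # prod_j choose(c_j, n1j) / choose(N, r1)
  ldenom <- lchoose(r1 + r2, r1)
  lp_obs <- sum(lchoose(cs, table[1, ])) - ldenom
  p <- 0
  for (n11 in n11_rng) {
    lo <- max(0, r1 - n11 - cs[3]); hi <- min(r1 - n11, cs[2])
    if (lo > hi) next
    for (n12 in lo:hi) {
      n13 <- r1 - n11 - n12
      lp <- lchoose(cs[1], n11) + lchoose(cs[2], n12) +
        lchoose(cs[3], n13) - ldenom
      if (lp <= lp_obs + 1e-7) p <- p + exp(lp)
    }
  }
  min(p, 1)
}

#' Linkage disequilibrium r-squared between two variants
#'
#' Squared Pearson correlation of genotype dosages over pairwise-complete
#' individuals. Perfectly co-inherited variants give 1; a monomorphic variant
#' gives `NA`.
#'
#' @param g1,g2 dosage vectors over the same individuals.
#' @return r-squared in [0, 1], or `NA` if either variant is monomorphic on
#'   the complete-case overlap.
#' @export
ld_r2 <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- complete.cases(g1, g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (length(g1) < 2 || stats::var(g1) == 0 || stats::var(g2) == 0) {
    return(NA_real_)
  }
  cor(g1, g2)^2
}

#' Single-variant association scan
#'
#' One allelic Fisher exact test per variant. For genotype cohorts, allele
#' counts come directly from the genotypes (complete cases per variant); for
#' pooled data, group counts are reconstructed from size-weighted group MAFs
#' via [reconstruct_counts()]. Per-variant failures (e.g. a group entirely
#' missing) are recorded as `NA` rows, never fatal.
#'
#' @param x a `cohort` or `pool_af` object.
#' @param genotypic also run the exact 2x3 genotypic test (genotype cohorts
#'   only).
#' @return tibble of class `single_variant_scan`: `variant`, `maf_cases`,
#'   `maf_controls`, `p_allelic`, optionally `p_genotypic`, `direction`
#'   (case-enriched / control-enriched / equal).
#' @export
single_variant_scan <- function(x, genotypic = FALSE) {
  maf <- maf_by_group(x)

  if (inherits(x, "cohort")) {
    Gc <- x$genotypes[, x$phenotype == 1L, drop = FALSE]
    Gk <- x$genotypes[, x$phenotype == 0L, drop = FALSE]
    counts <- function(G) {
      minor <- rowSums(G, na.rm = TRUE)
      total <- 2 * rowSums(!is.na(G))
      cbind(minor, total - minor)
    }
    cc <- counts(Gc); kk <- counts(Gk)
  } else if (inherits(x, "pool_af")) {
    n_case <- sum(x$pools$size[x$pools$phenotype == 1L])
    n_ctrl <- sum(x$pools$size[x$pools$phenotype == 0L])
    rc <- reconstruct_counts(pmin(pmax(maf$maf_cases, 0), 1), n_case)
    rk <- reconstruct_counts(pmin(pmax(maf$maf_controls, 0), 1), n_ctrl)
    cc <- cbind(rc$minor, rc$major); kk <- cbind(rk$minor, rk$major)
  } else {
    stop_validation("single_variant_scan() needs a cohort or pool_af object")
  }

  m <- nrow(maf)
  p_all <- rep(NA_real_, m)
  p_gen <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    tab <- rbind(cc[j, ], kk[j, ])
    p_all[j] <- tryCatch(allelic_fisher(tab), error = function(e) NA_real_)
    if (genotypic && inherits(x, "cohort")) {
      g_case <- table(factor(Gc[j, ], levels = 0:2))
      g_ctrl <- table(factor(Gk[j, ], levels = 0:2))
      p_gen[j] <- tryCatch(
        genotypic_fisher(rbind(as.integer(g_case), as.integer(g_ctrl))),
        error = function(e) NA_real_)
    }
  }

  out <- maf %>%
    mutate(
      p_allelic = p_all,
      direction = case_when(
        is.na(.data$maf_cases) | is.na(.data$maf_controls) ~ NA_character_,
        .data$maf_cases > .data$maf_controls ~ "case-enriched",
        .data$maf_cases < .data$maf_controls ~ "control-enriched",
        TRUE ~ "equal"
      )
    )
  if (genotypic) out <- mutate(out, p_genotypic = p_gen,
                               .after = "p_allelic")
  class(out) <- c("single_variant_scan", class(out))
  out
}
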
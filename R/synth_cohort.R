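#' Default genomic-region class mix
#'
#' Default probabilities over region classes for simulated variants. The
#' non-coding dominance (about 51% intronic, 13% upstream, 17% 3'UTR, ~10%
#' exonic) mirrors what targeted capture of gene loci — 2 kb upstream, all
#' exons, exon–intron junctions — typically yields in a candidate-gene study.
#'
#' @return named numeric vector over [region_classes()] summing to 1.
#' @export
default_region_fractions <- function() {
  c(
    "intronic"             = 0.5096,
    "upstream"             = 0.1336,
    "utr3"                 = 0.1734,
    "exonic-synonymous"    = 0.0638,
    "exonic-nonsynonymous" = 0.0400,
    "utr5"                 = 0.0596,
    "splicing"             = 0.0150,
    "stopgain"             = 0.0020,
    "stoploss"             = 0.0010,
    "frameshift"           = 0.0020
  )
}

#' Simulation configuration for a synthetic case-control cohort
#'
#' Describes a two-group cohort with per-gene variant sets, a rare-heavy
#' minor-allele-frequency law, a genomic-region mix, and optional
#' group-differential ("causal") variants. Defaults emulate a centenarian
#' study design: 450 cases, 500 controls, and ~81% of variants with
#' MAF < 0.05.
#'
#' @param n_cases,n_controls number of case (centenarian) and control
#'   individuals; both at least 1.
#' @param n_genes number of genes.
#' @param variants_per_gene scalar count, or length-2 integer range from which
#'   each gene's variant count is drawn uniformly.
#' @param maf_law list with `rare_fraction` (probability a variant is rare),
#'   `rare_range` and `common_range` (MAF intervals; rare MAFs are drawn
#'   log-uniformly, common MAFs uniformly). All MAFs must lie in [0, 0.5].
#' @param region_fractions named probability vector over [region_classes()].
#' @param effect_model `NULL` for a null cohort, or a data frame with columns
#'   `gene` (1-based gene index), `variant` (1-based index within the gene),
#'   `maf_case`, `maf_control` giving group-specific population MAFs at
#'   designated causal variants.
#' @param seed integer master seed; three named substreams (genotypes,
#'   pooling, annotations) are derived from it.
#' @return an object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_cases = 40, n_controls = 40, n_genes = 2, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' @export
sim_config <- function(n_cases = 450,
                       n_controls = 500,
                       n_genes = 20,
                       variants_per_gene = 10,
                       maf_law = list(
                         rare_fraction = 0.81,
                         rare_range = c(5e-4, 0.05),
                         common_range = c(0.05, 0.5)
                       ),
                       region_fractions = default_region_fractions(),
                       effect_model = NULL,
                       seed = 1L) {
  if (n_cases < 1 || n_controls < 1) {
    stop_config("`n_cases` and `n_controls` must both be >= 1",
                field = "n_cases")
  }
  if (n_genes < 1) stop_config("`n_genes` must be >= 1", field = "n_genes")
  if (!length(variants_per_gene) %in% 1:2 || any(variants_per_gene < 1)) {
    stop_config("`variants_per_gene` must be a positive count or range",
                field = "variants_per_gene")
  }
  if (is.null(names(region_fractions)) ||
      !all(names(region_fractions) %in% region_classes())) {
    stop_config("`region_fractions` must be named by region_classes()",
                field = "region_fractions")
  }
  check_prob_sum(region_fractions, "region_fractions")
  law <- modifyList(
    list(rare_fraction = 0.81, rare_range = c(5e-4, 0.05),
         common_range = c(0.05, 0.5)),
    maf_law
  )
  mafs <- c(law$rare_range, law$common_range)
  if (any(mafs < 0) || any(mafs > 0.5)) {
    stop_config("`maf_law` MAF ranges must lie within [0, 0.5]",
                field = "maf_law")
  }
  if (law$rare_fraction < 0 || law$rare_fraction > 1) {
    stop_config("`maf_law$rare_fraction` must be in [0, 1]", field = "maf_law")
  }
  if (!is.null(effect_model)) {
    effect_model <- as_tibble(effect_model)
    needed <- c("gene", "variant", "maf_case", "maf_control")
    missing_cols <- setdiff(needed, names(effect_model))
    if (length(missing_cols)) {
      stop_config(paste0("`effect_model` lacks column(s): ",
                         paste(missing_cols, collapse = ", ")),
                  field = "effect_model")
    }
    if (any(effect_model$maf_case < 0 | effect_model$maf_case > 0.5) ||
        any(effect_model$maf_control < 0 | effect_model$maf_control > 0.5)) {
      stop_config("`effect_model` MAFs must lie in [0, 0.5]",
                  field = "effect_model")
    }
  }
  structure(
    list(
      n_cases = as.integer(n_cases),
      n_controls = as.integer(n_controls),
      n_genes = as.integer(n_genes),
      variants_per_gene = as.integer(variants_per_gene),
      maf_law = law,
      region_fractions = region_fractions,
      effect_model = effect_model,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a case-control cohort with known ground truth
#'
#' Draws per-variant population MAFs from the configured rare-heavy law,
#' applies group-differential MAFs at designated causal variants, and samples
#' genotypes per group under Hardy-Weinberg equilibrium (dosage ~
#' Binomial(2, MAF)). The same config and seed reproduce the output
#' bit-identically.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `cohort`: a list with
#'   \describe{
#'     \item{variants}{tibble: `variant` key, `chrom`, `pos`, `id` (NA for
#'       novel variants), `ref`, `alt`, `gene`, `region_class`.}
#'     \item{genotypes}{integer matrix, variants x individuals, values 0/1/2
#'       (NA = missing), rownames = variant keys.}
#'     \item{phenotype}{named integer vector, 1 = case (centenarian),
#'       0 = control.}
#'     \item{truth}{tibble: per-variant true group MAFs and causal flag.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- substream_seeds(config$seed)
  set.seed(seeds[["genotypes"]])

  vpg <- config$variants_per_gene
  n_per_gene <- if (length(vpg) == 2) {
    sample(vpg[1]:vpg[2], config$n_genes, replace = TRUE)
  } else {
    rep(vpg, config$n_genes)
  }
  m <- sum(n_per_gene)
  gene_id <- sprintf("GENE%03d", seq_len(config$n_genes))
  gene_of <- rep(gene_id, n_per_gene)
  idx_in_gene <- unlist(lapply(n_per_gene, seq_len), use.names = FALSE)
  gene_index <- rep(seq_len(config$n_genes), n_per_gene)

  chrom <- paste0("chr", ((gene_index - 1L) %% 22L) + 1L)
  pos <- 1e6L * rep(seq_len(config$n_genes), n_per_gene) +
    150L * (idx_in_gene - 1L)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- unname(vapply(ref, function(r) sample(setdiff(bases, r), 1),
                       character(1)))
  has_id <- runif(m) < 0.7
  id <- ifelse(has_id, paste0("rs", 1e6L + seq_len(m)), NA_character_)

  region <- sample(names(config$region_fractions), m, replace = TRUE,
                   prob = config$region_fractions)

  law <- config$maf_law
  is_rare <- runif(m) < law$rare_fraction
  maf <- numeric(m)
  lr <- log(law$rare_range)
  maf[is_rare] <- exp(runif(sum(is_rare), lr[1], lr[2]))
  maf[!is_rare] <- runif(sum(!is_rare), law$common_range[1],
                         law$common_range[2])

  maf_case <- maf
  maf_control <- maf
  causal <- rep(FALSE, m)
  if (!is.null(config$effect_model)) {
    for (k in seq_len(nrow(config$effect_model))) {
      em <- config$effect_model[k, ]
      hit <- which(gene_index == em$gene & idx_in_gene == em$variant)
      if (!length(hit)) {
        stop_config(sprintf(
          "`effect_model` row %d refers to gene %d variant %d, not simulated",
          k, em$gene, em$variant), field = "effect_model")
      }
      maf_case[hit] <- em$maf_case
      maf_control[hit] <- em$maf_control
      causal[hit] <- TRUE
    }
  }

  key <- variant_key(chrom, pos, ref, alt)
  n <- config$n_cases + config$n_controls
  phenotype <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
  samples <- c(sprintf("case_%04d", seq_len(config$n_cases)),
               sprintf("ctrl_%04d", seq_len(config$n_controls)))
  names(phenotype) <- samples

  # HWE per group: dosage ~ Binomial(2, group MAF), variants in rows
  G <- matrix(0L, nrow = m, ncol = n, dimnames = list(key, samples))
  G[, phenotype == 1L] <- rbinom(m * config$n_cases, 2L, rep(maf_case,
                                 times = config$n_cases))
  G[, phenotype == 0L] <- rbinom(m * config$n_controls, 2L, rep(maf_control,
                                 times = config$n_controls))

  variants <- tibble(
    variant = key, chrom = chrom, pos = as.integer(pos), id = id,
    ref = ref, alt = alt, gene = gene_of, region_class = region
  )
  truth <- tibble(
    variant = key, gene = gene_of, maf_case = maf_case,
    maf_control = maf_control, causal = causal
  )
  structure(
    list(variants = variants, genotypes = G, phenotype = phenotype,
         truth = truth, config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d variants x %d individuals (%d cases / %d controls), %d genes\n",
    nrow(x$genotypes), ncol(x$genotypes), sum(x$phenotype == 1L),
    sum(x$phenotype == 0L), length(unique(x$variants$gene))
  ))
  invisible(x)
}

#' Assign individuals to phenotype-homogeneous sequencing pools
#'
#' Splits each phenotype group into consecutive pools of at most `pool_size`
#' individuals. Pools never mix cases and controls, matching a pooled
#' (Pool-seq) design where each DNA pool is constructed within a group.
#'
#' @param phenotype named binary vector (1 = case) as in a [simulate_cohort()]
#'   result.
#' @param pool_size target individuals per pool (the last pool in a group may
#'   be smaller).
#' @param depth sequencing read depth per pool and variant; `Inf` for the
#'   exact (noise-free) limit.
#' @param seed integer seed for the read-sampling noise.
#' @return an object of class `pooling_plan` with an `assignment` tibble
#'   (individual, pool, phenotype) plus depth and seed.
#' @export
pooling_plan <- function(phenotype, pool_size = 50, depth = 100, seed = 1L) {
  if (is.null(names(phenotype))) {
    names(phenotype) <- sprintf("ind_%04d", seq_along(phenotype))
  }
  if (pool_size < 1) stop_config("`pool_size` must be >= 1", field = "pool_size")
  if (!(is.infinite(depth) || depth >= 1)) {
    stop_config("`depth` must be >= 1 (or Inf)", field = "depth")
  }
  assign_group <- function(ids, label) {
    k <- ceiling(length(ids) / pool_size)
    tibble(
      individual = ids,
      pool = sprintf("%s_pool_%03d", label,
                     rep(seq_len(k), each = pool_size)[seq_along(ids)]),
      phenotype = if (label == "case") 1L else 0L
    )
  }
  assignment <- bind_rows(
    assign_group(names(phenotype)[phenotype == 1L], "case"),
    assign_group(names(phenotype)[phenotype == 0L], "ctrl")
  )
  structure(
    list(assignment = assignment, depth = depth, seed = as.integer(seed)),
    class = "pooling_plan"
  )
}

#' Pool a cohort into per-pool allele-frequency estimates
#'
#' Emulates pooled sequencing at the allele-frequency level: each pool's true
#' alternate-allele frequency is the pooled genotype mean, and the observed
#' frequency is `Binomial(depth, true AF) / depth` — the read-sampling noise of
#' sequencing a DNA pool at finite depth. With `depth = Inf` the exact pool AF
#' is returned.
#'
#' @param genotypes variants x individuals dosage matrix, or a `cohort`.
#' @param phenotype named binary vector (ignored when a `cohort` is given).
#' @param plan a [pooling_plan()].
#' @return an object of class `pool_af`: list with `af` (variants x pools
#'   matrix), and `pools` tibble (pool, phenotype, size, depth).
#' @export
pool_cohort <- function(genotypes, phenotype = NULL, plan) {
  if (inherits(genotypes, "cohort")) {
    phenotype <- genotypes$phenotype
    genotypes <- genotypes$genotypes
  }
  stopifnot(inherits(plan, "pooling_plan"))
  asn <- plan$assignment
  missing_ind <- setdiff(colnames(genotypes), asn$individual)
  if (length(missing_ind)) {
    stop_validation(paste0("pooling plan does not cover individual(s): ",
                           paste(head(missing_ind, 5), collapse = ", ")))
  }
  ph <- phenotype[asn$individual]
  mixed <- tapply(ph, asn$pool, function(v) length(unique(v)) > 1)
  if (any(mixed)) {
    stop_validation(paste0("mixed-phenotype pool(s): ",
                           paste(names(mixed)[mixed], collapse = ", ")))
  }
  pools <- asn %>%
    group_by(.data$pool, .data$phenotype) %>%
    summarise(size = n(), .groups = "drop") %>%
    arrange(.data$pool) %>%
    mutate(depth = plan$depth)

  true_af <- vapply(pools$pool, function(p) {
    ids <- asn$individual[asn$pool == p]
    g <- genotypes[, ids, drop = FALSE]
    rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
  }, numeric(nrow(genotypes)))
  true_af <- matrix(true_af, nrow = nrow(genotypes),
                    dimnames = list(rownames(genotypes), pools$pool))

  if (is.infinite(plan$depth)) {
    af <- true_af
  } else {
    set.seed(plan$seed)
    af <- matrix(
      rbinom(length(true_af), size = plan$depth, prob = as.vector(true_af)) /
        plan$depth,
      nrow = nrow(true_af), dimnames = dimnames(true_af)
    )
  }
  structure(list(af = af, pools = pools), class = "pool_af")
}

#' @export
print.pool_af <- function(x, ...) {
  cat(sprintf("<pool_af> %d variants x %d pools (%d case / %d control pools)\n",
              nrow(x$af), nrow(x$pools), sum(x$pools$phenotype == 1L),
              sum(x$pools$phenotype == 0L)))
  invisible(x)
}

#' Tidy a pooled allele-frequency table into long form
#' @param x a `pool_af` object.
#' @param ... unused.
#' @return tibble with one row per variant x pool.
#' @method tidy pool_af
#' @export
tidy.pool_af <- function(x, ...) {
  out <- as_tibble(x$af, rownames = "variant") %>%
    tidyr::pivot_longer(-"variant", names_to = "pool", values_to = "af")
  left_join(out, x$pools, by = "pool")
}

#' Default RegulomeDB-style score category distribution
#'
#' Scores are ordered categories "1a".."7"; lower integer class means more
#' regulatory evidence. The distribution is parameterized by the prevalence of
#' integer class <= 5 (the functional-candidate side); mass within each side
#' keeps fixed proportions.
#'
#' @param p_le5 probability that a variant scores in integer class 1-5.
#' @return named probability vector over score labels, summing to 1.
#' @export
default_score_probs <- function(p_le5 = 0.4) {
  if (p_le5 < 0 || p_le5 > 1) {
    stop_config("`p_le5` must be in [0, 1]", field = "p_le5")
  }
  low <- c("1a" = 0.02, "1b" = 0.02, "1f" = 0.01, "2a" = 0.05, "2b" = 0.05,
           "3a" = 0.05, "4" = 0.10, "5" = 0.10)
  high <- c("6" = 0.35, "7" = 0.25)
  c(low / sum(low) * p_le5, high / sum(high) * (1 - p_le5))
}

#' Annotation simulation configuration
#'
#' @param score_probs named probability vector over RegulomeDB-style score
#'   labels (integer class 1-7, optional letter subclass); must sum to 1.
#' @param tf_dhs_prob probability that a variant overlaps a transcription
#'   factor binding site or DNase I hypersensitive site.
#' @param ago_rate Poisson mean of the number of CLIP-seq experiments
#'   reporting Argonaute binding over a 3'UTR variant (0 for non-3'UTR).
#' @return object of class `annotation_config`.
#' @export
annotation_config <- function(score_probs = default_score_probs(),
                              tf_dhs_prob = 0.5,
                              ago_rate = 0.7) {
  check_prob_sum(score_probs, "score_probs")
  cls <- suppressWarnings(as.integer(substr(names(score_probs), 1, 1)))
  if (any(is.na(cls)) || any(cls < 1 | cls > 7)) {
    stop_config("score labels must start with an integer class 1-7",
                field = "score_probs")
  }
  if (tf_dhs_prob < 0 || tf_dhs_prob > 1) {
    stop_config("`tf_dhs_prob` must be in [0, 1]", field = "tf_dhs_prob")
  }
  if (ago_rate < 0) stop_config("`ago_rate` must be >= 0", field = "ago_rate")
  structure(list(score_probs = score_probs, tf_dhs_prob = tf_dhs_prob,
                 ago_rate = ago_rate),
            class = "annotation_config")
}

#' Simulate functional annotations for a variant table
#'
#' Draws a RegulomeDB-style ordered score, TF/DHS overlap flag, and Argonaute
#' (CLIP-seq) evidence count per variant. Coding-effect labels are derived
#' from the region class (exonic/splicing classes carry their effect;
#' everything else is "none"), so annotations can never contradict the
#' variant table.
#'
#' @param variants variant tibble as from [simulate_cohort()].
#' @param config an [annotation_config()].
#' @param seed integer seed.
#' @return tibble: variant, regulome_score, regulome_class,
#'   tf_or_dhs_overlap, ago_evidence_count, coding_effect.
#' @export
simulate_annotations <- function(variants, config = annotation_config(),
                                 seed = 1L) {
  stopifnot(inherits(config, "annotation_config"))
  set.seed(substream_seeds(seed)[["annotations"]])
  m <- nrow(variants)
  score <- sample(names(config$score_probs), m, replace = TRUE,
                  prob = config$score_probs)
  effect <- case_when(
    variants$region_class == "exonic-synonymous"    ~ "synonymous",
    variants$region_class == "exonic-nonsynonymous" ~ "nonsynonymous",
    variants$region_class == "stopgain"             ~ "stopgain",
    variants$region_class == "stoploss"             ~ "stoploss",
    variants$region_class == "frameshift"           ~ "frameshift",
    variants$region_class == "splicing"             ~ "splicing",
    TRUE ~ "none"
  )
  ago <- ifelse(variants$region_class == "utr3",
                rpois(m, config$ago_rate), 0L)
  tibble(
    variant = variants$variant,
    regulome_score = score,
    regulome_class = as.integer(substr(score, 1, 1)),
    tf_or_dhs_overlap = runif(m) < config$tf_dhs_prob,
    ago_evidence_count = as.integer(ago),
    coding_effect = effect
  )
}
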
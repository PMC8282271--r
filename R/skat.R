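#' Configuration for gene-based kernel association tests
#'
#' @param weight_beta_rare shape pair (a, b) of the Beta density evaluated at
#'   the sample MAF to weight rare variants; the default (1, 25) up-weights
#'   the rarest variants sharply.
#' @param weight_beta_common shape pair for the common-variant weights in the
#'   combined test; the default (0.5, 0.5) is much flatter.
#' @param rare_common_threshold MAF cutoff separating rare from common
#'   variants (rare means MAF strictly below it), default 0.05 as in the
#'   study design.
#' @param rho_grid mixing grid in [0, 1] for the optimal test; must contain
#'   0 (pure kernel test) and 1 (pure burden test).
#' @return object of class `skat_config`.
#' @export
skat_config <- function(weight_beta_rare = c(1, 25),
                        weight_beta_common = c(0.5, 0.5),
                        rare_common_threshold = 0.05,
                        rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)) {
  if (any(weight_beta_rare <= 0) || any(weight_beta_common <= 0)) {
    stop_config("Beta weight shapes must be positive", field = "weight_beta")
  }
  if (rare_common_threshold <= 0 || rare_common_threshold > 0.5) {
    stop_config("`rare_common_threshold` must be in (0, 0.5]",
                field = "rare_common_threshold")
  }
  if (!length(rho_grid) || any(rho_grid < 0 | rho_grid > 1)) {
    stop_config("`rho_grid` must lie in [0, 1]", field = "rho_grid")
  }
  if (length(rho_grid) > 1 && (!(0 %in% rho_grid) || !(1 %in% rho_grid))) {
    stop_config("a multi-point `rho_grid` must contain 0 and 1",
                field = "rho_grid")
  }
  structure(
    list(weight_beta_rare = weight_beta_rare,
         weight_beta_common = weight_beta_common,
         rare_common_threshold = rare_common_threshold,
         rho_grid = sort(unique(rho_grid))),
    class = "skat_config"
  )
}

#' Fit the covariate-free null model for the score tests
#'
#' Intercept-only logistic null: every individual gets the same fitted case
#' probability (the case fraction), residual `y - mu`, and binomial variance
#' weight `mu * (1 - mu)`. The study design uses no covariates, so this is
#' the exact null model of all kernel tests in the package.
#'
#' @param phenotype binary vector (1 = case) with both classes present.
#' @return object of class `skat_null` with `y`, `mu`, `resid`, `v`, `n`.
#' @export
fit_null <- function(phenotype) {
  y <- as.numeric(phenotype)
  if (!all(y %in% c(0, 1))) stop_validation("phenotype must be binary 0/1")
  mu <- mean(y)
  if (mu <= 0 || mu >= 1) {
    stop_validation("phenotype has a single class; both are required")
  }
  structure(
    list(y = y, mu = mu, resid = y - mu, v = mu * (1 - mu), n = length(y)),
    class = "skat_null"
  )
}

#' @export
print.skat_null <- function(x, ...) {
  cat(sprintf("<skat_null> n = %d, fitted case probability = %.4f\n",
              x$n, x$mu))
  invisible(x)
}

# ---- internal quadratic-form engine ----------------------------------------

# G: individuals x variants dosage matrix (mean-imputed if NA)
# Returns the weighted score vector, Q statistics and projected kernel.
skat_engine <- function(G, null, weights) {
  n <- nrow(G)
  stopifnot(n == null$n)
  if (anyNA(G)) {
    cm <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- cm[idx[, 2]]
  }
  S <- as.vector(crossprod(G, null$resid))
  ws <- weights * S
  Gc <- sweep(G, 2, colMeans(G))
  Z <- sqrt(null$v) * sweep(Gc, 2, weights, `*`)
  list(S = S, ws = ws, Z = Z, q_skat = sum(ws^2), q_burden = sum(ws)^2)
}

trunc_eigen <- function(K) {
  lam <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(lam, 0)
  lam[lam > 1e-10 * mx]
}

# Folded minor-allele frequency over the whole sample (weight convention).
folded_maf <- function(G) {
  af <- colMeans(G, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

new_skat_test <- function(gene, stratum, method, Q, p, lambda, n_variants,
                          flags = character(), extra = list()) {
  structure(
    c(list(gene = gene, stratum = stratum, method = method, Q = Q, p = p,
           lambda = lambda, n_variants = n_variants, flags = flags), extra),
    class = "skat_test"
  )
}

#' @export
print.skat_test <- function(x, ...) {
  cat(sprintf("<skat_test> %s%s [%s]  Q = %.4g, p = %.4g (%d variants)%s\n",
              ifelse(is.na(x$gene), "", paste0(x$gene, " ")),
              paste0("stratum=", x$stratum), x$method, x$Q, x$p,
              x$n_variants,
              if (length(x$flags)) paste0("  flags: ",
                                          paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Tidy a kernel-test result into a one-row tibble
#' @param x a `skat_test`.
#' @param ... unused.
#' @method tidy skat_test
#' @export
tidy.skat_test <- function(x, ...) {
  tibble(
    gene = x$gene, stratum = x$stratum, method = x$method,
    n_variants = x$n_variants, Q = x$Q, p = x$p,
    flag = if (length(x$flags)) paste(x$flags, collapse = ";") else NA_character_
  )
}

#' Model-level summary of a kernel-test result
#' @param x a `skat_test`.
#' @param ... unused.
#' @method glance skat_test
#' @export
glance.skat_test <- function(x, ...) {
  tibble(
    Q = x$Q, p = x$p, n_variants = x$n_variants,
    n_eigenvalues = length(x$lambda),
    lambda_max = if (length(x$lambda)) max(x$lambda) else NA_real_,
    p_method = x$p_method %||% NA_character_
  )
}

#' Sequence kernel association test (SKAT) for one gene region
#'
#' Variance-component score test on the weighted genotype kernel. Per-variant
#' weights are the Beta(a, b) density evaluated at the folded whole-sample
#' MAF; the statistic is `Q = sum_j w_j^2 (sum_i (y_i - mu) g_ij)^2` and the
#' null distribution is the mixture of chi-squares given by the eigenvalues
#' of the weighted, null-variance-projected genotype cross-product
#' (tail probability via [davies_pvalue()]).
#'
#' @param G individuals x variants dosage matrix (0/1/2; NA mean-imputed).
#' @param null a [fit_null()] model for the same individuals.
#' @param cfg a [skat_config()].
#' @param weights optional per-variant weights overriding the Beta defaults.
#' @param gene,stratum labels carried into the result.
#' @return a `skat_test` object. A gene with no polymorphic variants returns
#'   p = 1 with flag `"no_information"`.
#' @export
skat <- function(G, null, cfg = skat_config(), weights = NULL,
                 gene = NA_character_, stratum = "all") {
  G <- as.matrix(G)
  if (ncol(G) < 1) stop_validation("gene region has no variants")
  maf <- folded_maf(G)
  w <- weights %||%
    dbeta(maf, cfg$weight_beta_rare[1], cfg$weight_beta_rare[2])
  eng <- skat_engine(G, null, w)
  lam <- trunc_eigen(crossprod(eng$Z))
  if (!length(lam)) {
    warn("gene region carries no genotype variation; returning p = 1")
    return(new_skat_test(gene, stratum, "SKAT", Q = eng$q_skat, p = 1,
                         lambda = numeric(), n_variants = ncol(G),
                         flags = "no_information"))
  }
  p <- davies_pvalue(eng$q_skat, lam)
  new_skat_test(gene, stratum, "SKAT", Q = eng$q_skat, p = as.numeric(p),
                lambda = lam, n_variants = ncol(G),
                extra = list(p_method = attr(p, "method"), weights = w))
}

# eigenvalues of the rho-mixed kernel Phi^{1/2} K Phi^{1/2} with
# Phi = (1-rho) I + rho J  (J = all-ones). Phi^{1/2} has closed form.
rho_kernel_eigen <- function(K, rho) {
  m <- ncol(K)
  if (rho >= 1) return(sum(K))
  s1 <- sqrt(1 - rho)
  s2 <- sqrt(1 - rho + m * rho)
  one <- rep(1, m)
  # Phi^{1/2} = s1 (I - J/m) + s2 J/m
  Jm <- tcrossprod(one) / m
  Ph <- s1 * (diag(m) - Jm) + s2 * Jm
  trunc_eigen(Ph %*% K %*% Ph)
}

#' Optimal kernel/burden combination test (SKAT-O)
#'
#' Computes `Q_rho = (1 - rho) Q_kernel + rho Q_burden` over the mixing grid,
#' takes the minimum per-rho p-value as the statistic, and evaluates its null
#' distribution by the one-dimensional mixing integral over the shared
#' chi-square(1) factor. The result records the grid and the minimizing rho.
#' A single-element grid short-circuits to the exact per-rho test, so
#' `rho_grid = c(0)` is identical to [skat()] and `rho_grid = c(1)` to the
#' weighted burden score test.
#'
#' @inheritParams skat
#' @return a `skat_test` with extra fields `rho_grid`, `rho_min`, `p_rho`.
#' @export
skat_o <- function(G, null, cfg = skat_config(), weights = NULL,
                   gene = NA_character_, stratum = "all") {
  G <- as.matrix(G)
  if (ncol(G) < 1) stop_validation("gene region has no variants")
  maf <- folded_maf(G)
  w <- weights %||%
    dbeta(maf, cfg$weight_beta_rare[1], cfg$weight_beta_rare[2])
  eng <- skat_engine(G, null, w)
  K <- crossprod(eng$Z)
  if (max(diag(K)) <= 0) {
    warn("gene region carries no genotype variation; returning p = 1")
    return(new_skat_test(gene, stratum, "SKAT-O", Q = eng$q_skat, p = 1,
                         lambda = numeric(), n_variants = ncol(G),
                         flags = "no_information"))
  }
  grid <- cfg$rho_grid
  q_rho <- (1 - grid) * eng$q_skat + grid * eng$q_burden
  p_rho <- numeric(length(grid))
  lam_rho <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    lam_rho[[i]] <- rho_kernel_eigen(K, grid[i])
    p_rho[i] <- as.numeric(davies_pvalue(q_rho[i], lam_rho[[i]]))
  }
  i_min <- which.min(p_rho)

  if (length(grid) == 1L) {
    return(new_skat_test(gene, stratum, "SKAT-O", Q = q_rho[1],
                         p = p_rho[1], lambda = lam_rho[[1]],
                         n_variants = ncol(G),
                         extra = list(rho_grid = grid, rho_min = grid[1],
                                      p_rho = p_rho)))
  }

  p_min <- min(p_rho)
  p <- skat_o_combined_p(p_min, eng$Z, grid, lam_rho)
  # the min-p statistic can never be less significant than Bonferroni over
  # the grid, nor more significant than its own minimum
  p <- min(max(p, p_min), p_min * length(grid), 1)
  new_skat_test(gene, stratum, "SKAT-O", Q = q_rho[i_min], p = p,
                lambda = lam_rho[[i_min]], n_variants = ncol(G),
                extra = list(rho_grid = grid, rho_min = grid[i_min],
                             p_rho = p_rho))
}

# Null distribution of the minimum-p statistic: decompose Z into the
# component along the average variant vector (which carries the shared
# chi-square(1) burden factor) and its orthogonal remainder, then integrate
# the conditional survivor over the chi-square(1) density.
skat_o_combined_p <- function(p_min, Z, grid, lam_rho) {
  m <- ncol(Z)
  zbar <- rowMeans(Z)
  zb2 <- sum(zbar^2)
  if (zb2 <= 0) return(p_min * length(grid))
  cof1 <- as.vector(crossprod(zbar, Z)) / zb2
  Zi1 <- outer(zbar, cof1)
  Zi2 <- Z - Zi1
  lam2 <- trunc_eigen(crossprod(Zi2))
  if (!length(lam2)) return(p_min * length(grid))
  var_remain <- 4 * sum(crossprod(Zi1) * crossprod(Zi2))
  mu_q <- sum(lam2)
  var_q <- 2 * sum(lam2^2) + var_remain
  rr <- pmin(grid, 0.999)
  tau <- (m^2 * rr + (1 - rr) * sum(cof1^2)) * zb2
  # per-rho quantiles of Q_rho at upper-tail probability p_min
  q_min <- vapply(lam_rho, function(l) moment_match_quantile(p_min, l),
                  numeric(1))

  integrand <- function(x) {
    vapply(x, function(xi) {
      qcond <- min((q_min - tau * xi) / (1 - rr))
      tail <- if (qcond <= 0) {
        1
      } else if (qcond > mu_q * 1e4) {
        0
      } else {
        adj <- (qcond - mu_q) * sqrt((var_q - var_remain) / var_q) + mu_q
        # moment-matched survivor: the fast published variant of this
        # integral; CF inversion here would cost ~100x for <1% difference
        if (adj <= 0) 1 else moment_match_tail(adj, lam2)
      }
      (1 - tail) * dchisq(xi, df = 1)
    }, numeric(1))
  }
  int <- integrate(integrand, 0, 40, subdivisions = 1000L,
                   rel.tol = 1e-6, stop.on.error = FALSE)
  1 - int$value
}

#' Combined common-and-rare variant kernel test (SKAT-C)
#'
#' Variants are partitioned at the rare/common MAF threshold; rare variants
#' get the rare Beta weights and common variants the common Beta weights, and
#' the test statistic is the sum of the two weighted kernel statistics —
#' equivalently one kernel test with class-specific weights, whose combined
#' eigenvalue spectrum feeds [davies_pvalue()].
#'
#' @inheritParams skat
#' @return a `skat_test` with extra field `n_rare`.
#' @export
skat_c <- function(G, null, cfg = skat_config(), gene = NA_character_,
                   stratum = "all") {
  G <- as.matrix(G)
  if (ncol(G) < 1) stop_validation("gene region has no variants")
  maf <- folded_maf(G)
  rare <- maf < cfg$rare_common_threshold
  w <- ifelse(rare,
              dbeta(maf, cfg$weight_beta_rare[1], cfg$weight_beta_rare[2]),
              dbeta(maf, cfg$weight_beta_common[1], cfg$weight_beta_common[2]))
  res <- skat(G, null, cfg, weights = w, gene = gene, stratum = stratum)
  res$method <- "SKAT-C"
  res$n_rare <- sum(rare)
  res
}

#' Kernel association test on pooled allele frequencies
#'
#' The pooled-sequencing adaptation: each phenotype-homogeneous pool becomes
#' one observational unit with per-variant dosage `2 x pool AF`, the pool
#' phenotype is the response, and variant weights come from the
#' size-weighted across-pool MAF. The usual kernel machinery then runs on
#' the pool-level matrix. Because individual genotype information is lost in
#' a pool, p-values from this test are known to be anti-conservative
#' (under-estimated); results carry the flag `"pooled_anti_conservative"`.
#' With pools of size 1 and exact (infinite-depth) frequencies the test is
#' identical to individual-level [skat()].
#'
#' @param pool_table a `pool_af` object (at least two pools, both phenotypes
#'   present).
#' @param cfg a [skat_config()].
#' @param variants optional character vector restricting to a subset of
#'   variants (e.g. one gene).
#' @param gene,stratum labels carried into the result.
#' @return a `skat_test` with method `"pooled-SKAT"`.
#' @export
pooled_skat <- function(pool_table, cfg = skat_config(), variants = NULL,
                        gene = NA_character_, stratum = "all") {
  stopifnot(inherits(pool_table, "pool_af"))
  af <- pool_table$af
  if (!is.null(variants)) af <- af[variants, , drop = FALSE]
  pools <- pool_table$pools
  if (nrow(pools) < 2) stop_validation("need at least two pools")
  if (length(unique(pools$phenotype)) < 2) {
    stop_validation("pools cover a single phenotype; both are required")
  }
  D <- t(af) * 2                      # pools x variants dosage
  null <- fit_null(pools$phenotype)
  af_w <- as.vector(af %*% pools$size) / sum(pools$size)
  maf <- pmin(af_w, 1 - af_w)
  w <- dbeta(maf, cfg$weight_beta_rare[1], cfg$weight_beta_rare[2])
  res <- skat(D, null, cfg, weights = w, gene = gene, stratum = stratum)
  res$method <- "pooled-SKAT"
  res$flags <- union(res$flags, "pooled_anti_conservative")
  res
}

#' Gene-by-gene kernel association scan
#'
#' Runs the requested kernel tests per gene and stratum. Strata with no
#' variants for a gene yield an absent-marker record (NA p, flag
#' `"absent"`), mirroring the grey cells of a stratified association
#' heatmap.
#'
#' @param x a `cohort` or `pool_af` object.
#' @param gene_map tibble with `variant` and `gene`; defaults to the cohort's
#'   variant table. Required for `pool_af` input.
#' @param strata optional strata assignment from [build_strata()]; when NULL
#'   only the `all` stratum is run.
#' @param cfg a [skat_config()].
#' @param methods subset of `"SKAT"`, `"SKAT-O"`, `"SKAT-C"` (genotype input)
#'   or `"pooled-SKAT"` (pooled input).
#' @return tibble of class `gene_scan`: one row per (gene, stratum, method).
#' @export
gene_scan <- function(x, gene_map = NULL, strata = NULL,
                      cfg = skat_config(), methods = "SKAT") {
  pooled <- inherits(x, "pool_af")
  if (is.null(gene_map)) {
    if (pooled) stop_validation("`gene_map` is required for pooled input")
    gene_map <- x$variants[c("variant", "gene")]
  }
  if (anyDuplicated(gene_map$variant)) {
    stop_validation("`gene_map` maps some variant to more than one gene")
  }
  if (pooled) {
    methods <- "pooled-SKAT"
    all_vars <- rownames(x$af)
  } else {
    all_vars <- rownames(x$genotypes)
    null <- fit_null(x$phenotype)
    Gt <- t(x$genotypes)
  }
  stratum_sets <- list(all = all_vars)
  if (!is.null(strata)) stratum_sets <- strata_sets(strata, all_vars)

  rows <- list()
  for (g in unique(gene_map$gene)) {
    gvars <- intersect(gene_map$variant[gene_map$gene == g], all_vars)
    for (st in names(stratum_sets)) {
      svars <- intersect(gvars, stratum_sets[[st]])
      for (mth in methods) {
        if (!length(svars)) {
          rows[[length(rows) + 1L]] <- tibble(
            gene = g, stratum = st, method = mth, n_variants = 0L,
            Q = NA_real_, p = NA_real_, flag = "absent")
          next
        }
        fit <- tryCatch({
          if (pooled) {
            pooled_skat(x, cfg, variants = svars, gene = g, stratum = st)
          } else {
            Gsub <- Gt[, svars, drop = FALSE]
            switch(mth,
                   "SKAT"   = skat(Gsub, null, cfg, gene = g, stratum = st),
                   "SKAT-O" = skat_o(Gsub, null, cfg, gene = g, stratum = st),
                   "SKAT-C" = skat_c(Gsub, null, cfg, gene = g, stratum = st),
                   stop_config(paste0("unknown method: ", mth)))
          }
        }, error = function(e) e)
        rows[[length(rows) + 1L]] <- if (inherits(fit, "error")) {
          tibble(gene = g, stratum = st, method = mth, n_variants = 0L,
                 Q = NA_real_, p = NA_real_,
                 flag = paste0("error: ", conditionMessage(fit)))
        } else {
          suppressWarnings(tidy(fit))
        }
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("gene_scan", class(out))
  out
}
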
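test_that("the null model is the intercept-only logistic fit", {
  null <- fit_null(rep(c(1, 0), each = 50))
  expect_equal(null$mu, 0.5)
  expect_equal(sum(null$resid), 0, tolerance = 1e-9)
  null2 <- fit_null(rep(c(1L, 0L), c(450, 500)))
  expect_equal(null2$mu, 450 / 950)
  expect_equal(null2$v, (450 / 950) * (500 / 950))
  expect_error(fit_null(rep(1, 10)), class = "centiskat_validation_error")
})

test_that("a no-information gene returns p = 1 with a warning flag", {
  null <- fit_null(rep(c(1, 0), each = 10))
  expect_warning(fit <- skat(matrix(0L, 20, 3), null), "variation")
  expect_equal(fit$p, 1)
  expect_true("no_information" %in% fit$flags)
})

test_that("a single-variant gene reduces to the analytic score test", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 200
    y <- rep(c(1, 0), each = n / 2)
    g <- rbinom(n, 2, runif(1, 0.05, 0.3))
    null <- fit_null(y)
    fit <- skat(matrix(g, ncol = 1), null)
    U <- sum((y - mean(y)) * g)
    V <- null$v * sum((g - mean(g))^2)
    expect_equal(fit$p, pchisq(U^2 / V, 1, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("davies p matches the Gaussian quadratic-form Monte-Carlo oracle", {
  set.seed(62)
  n <- 50
  y <- rep(c(1, 0), each = 25)
  G <- matrix(rbinom(n * 10, 2, rep(runif(10, 0.02, 0.2), each = n)), n)
  null <- fit_null(y)
  fit <- skat(G, null)
  w <- fit$weights
  B <- 50000
  qs <- vapply(seq_len(B), function(b) {
    r <- rnorm(n, 0, sqrt(null$v))
    r <- r - mean(r)
    sum((w * as.vector(crossprod(G, r)))^2)
  }, numeric(1))
  mc <- mean(qs >= fit$Q)
  se <- sqrt(mc * (1 - mc) / B)
  expect_lt(abs(fit$p - mc), 2.576 * se)
  # permutation oracle deviates only through the small-sample
  # non-Gaussianity of binary residuals; agreement is loose at n=50
  perm <- mean(vapply(seq_len(20000), function(b) {
    r <- sample(y) - mean(y)
    sum((w * as.vector(crossprod(G, r)))^2)
  }, numeric(1)) >= fit$Q)
  expect_lt(abs(fit$p - perm), 0.1)
})

test_that("Q is invariant to variant order and allele flips", {
  set.seed(63)
  n <- 120
  y <- rep(c(1, 0), each = 60)
  null <- fit_null(y)
  G <- matrix(rbinom(n * 6, 2, rep(runif(6, 0.05, 0.4), each = n)), n)
  f0 <- skat(G, null)
  f_perm <- skat(G[, sample(6)], null)
  expect_equal(f_perm$Q, f0$Q, tolerance = 1e-12)
  expect_equal(f_perm$p, f0$p, tolerance = 1e-9)
  Gf <- G
  Gf[, 2] <- 2L - Gf[, 2]  # ref/alt flip; folded-MAF weights recompute
  f_flip <- skat(Gf, null)
  expect_equal(f_flip$Q, f0$Q, tolerance = 1e-10)
  expect_equal(f_flip$p, f0$p, tolerance = 1e-9)
})

test_that("SKAT-O reduces to SKAT at rho 0 and to burden at rho 1", {
  set.seed(64)
  n <- 300
  y <- rep(c(1, 0), each = 150)
  null <- fit_null(y)
  for (rep in 1:5) {
    G <- matrix(rbinom(n * 10, 2, rep(runif(10, 0.005, 0.08), each = n)), n)
    s <- skat(G, null)
    so0 <- skat_o(G, null, skat_config(rho_grid = 0))
    expect_lt(abs(so0$p - s$p), 1e-10)
    # independent burden score-test oracle
    w <- s$weights
    b <- as.vector(G %*% w)
    U <- sum((y - mean(y)) * b)
    V <- null$v * sum((b - mean(b))^2)
    p_burden <- pchisq(U^2 / V, 1, lower.tail = FALSE)
    so1 <- skat_o(G, null, skat_config(rho_grid = 1))
    expect_lt(abs(so1$p - p_burden), 1e-8)
  }
})

test_that("full-grid SKAT-O obeys the Bonferroni sandwich", {
  set.seed(65)
  n <- 200
  y <- rep(c(1, 0), each = 100)
  null <- fit_null(y)
  for (rep in 1:10) {
    G <- matrix(rbinom(n * 8, 2, rep(runif(8, 0.01, 0.2), each = n)), n)
    fit <- skat_o(G, null)
    pmin_rho <- min(fit$p_rho)
    expect_gte(fit$p, pmin_rho - 1e-12)
    expect_lte(fit$p, length(fit$rho_grid) * pmin_rho + 1e-12)
  }
})

test_that("SKAT-C reduces to class-specific SKAT and handles mixtures", {
  set.seed(66)
  n <- 300
  y <- rep(c(1, 0), each = 150)
  null <- fit_null(y)
  cfg <- skat_config()
  repeat {  # condition on every sample MAF landing in the rare class
    G_rare <- matrix(rbinom(n * 8, 2, rep(runif(8, 0.005, 0.035),
                                          each = n)), n)
    if (all(colMeans(G_rare) / 2 < 0.05)) break
  }
  expect_lt(abs(skat_c(G_rare, null)$p - skat(G_rare, null)$p), 1e-10)
  G_com <- matrix(rbinom(n * 8, 2, rep(runif(8, 0.1, 0.4), each = n)), n)
  maf <- pmin(colMeans(G_com) / 2, 1 - colMeans(G_com) / 2)
  w_com <- dbeta(maf, 0.5, 0.5)
  expect_lt(abs(skat_c(G_com, null)$p -
                  skat(G_com, null, weights = w_com)$p), 1e-10)

  # mixed instance: Gaussian quadratic-form MC oracle at 50k draws
  G_mix <- cbind(G_rare[, 1:4], G_com[, 1:4])
  fit <- skat_c(G_mix, null)
  maf_m <- pmin(colMeans(G_mix) / 2, 1 - colMeans(G_mix) / 2)
  w_m <- ifelse(maf_m < 0.05, dbeta(maf_m, 1, 25), dbeta(maf_m, 0.5, 0.5))
  B <- 50000
  qs <- vapply(seq_len(B), function(b) {
    r <- rnorm(n, 0, sqrt(null$v)); r <- r - mean(r)
    sum((w_m * as.vector(crossprod(G_mix, r)))^2)
  }, numeric(1))
  mc <- mean(qs >= fit$Q)
  se <- sqrt(mc * (1 - mc) / B)
  expect_lt(abs(fit$p - mc), 2.576 * se + 1e-4)
})

test_that("unit pools with exact AFs reproduce individual-level SKAT", {
  for (seed in 1:10) {
    coh <- null_cohort(n_cases = 40, n_controls = 40, variants_per_gene = 10,
                       seed = seed)
    pa <- pool_cohort(coh, plan = pooling_plan(coh$phenotype, pool_size = 1,
                                               depth = Inf))
    p_pool <- pooled_skat(pa)$p
    p_ind <- skat(t(coh$genotypes), fit_null(coh$phenotype))$p
    expect_lt(abs(p_pool - p_ind), 1e-10)
  }
})

test_that("identical pool AFs across groups give a no-signal p", {
  af <- matrix(rep(c(0.1, 0.02, 0.3), 4), nrow = 3,
               dimnames = list(c("v1", "v2", "v3"), paste0("p", 1:4)))
  pa <- structure(list(
    af = af,
    pools = tibble::tibble(pool = paste0("p", 1:4),
                           phenotype = c(1L, 1L, 0L, 0L),
                           size = 10L, depth = Inf)
  ), class = "pool_af")
  expect_warning(fit <- pooled_skat(pa), "variation")
  expect_gte(fit$p, 0.5)
  expect_true("pooled_anti_conservative" %in% fit$flags)
})

test_that("doubling the sample at fixed effect lowers the median p", {
  em <- tibble::tibble(gene = 1, variant = 1:3,
                       maf_case = c(0.04, 0.05, 0.03),
                       maf_control = c(0.015, 0.02, 0.01))
  p_at_n <- function(n, seed) {
    coh <- simulate_cohort(sim_config(n_cases = n, n_controls = n,
                                      n_genes = 1, variants_per_gene = 8,
                                      effect_model = em, seed = seed))
    suppressWarnings(skat(t(coh$genotypes), fit_null(coh$phenotype))$p)
  }
  p_small <- vapply(1:50, function(s) p_at_n(150, s), numeric(1))
  p_large <- vapply(1:50, function(s) p_at_n(300, s + 500), numeric(1))
  expect_lt(median(p_large), median(p_small))
})

test_that("gene_scan stratifies, marks absent strata, and matches direct skat", {
  coh <- null_cohort(n_cases = 60, n_controls = 60, n_genes = 4,
                     variants_per_gene = 8, seed = 71)
  ann <- simulate_annotations(coh$variants, seed = 71)
  strata <- suppressMessages(build_strata(coh$variants, ann))
  res <- suppressWarnings(gene_scan(coh, strata = strata,
                                    methods = c("SKAT", "SKAT-O")))
  expect_setequal(unique(res$stratum),
                  c("all", "coding", "regulatory", "combined"))
  # absent strata are marked, not dropped
  absent <- res[res$n_variants == 0, ]
  expect_true(all(is.na(absent$p)) && all(absent$flag == "absent"))
  # stratum "all" equals direct skat on the gene's variants
  g1 <- coh$variants$gene[1]
  direct <- skat(t(coh$genotypes[coh$variants$gene == g1, , drop = FALSE]),
                 fit_null(coh$phenotype))
  row <- res[res$gene == g1 & res$stratum == "all" & res$method == "SKAT", ]
  expect_equal(row$p, direct$p, tolerance = 1e-12)

  # tidiers return well-formed rows
  expect_named(tidy(direct),
               c("gene", "stratum", "method", "n_variants", "Q", "p", "flag"))
  expect_equal(glance(direct)$p_method, "davies")
})
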
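test_that("group MAFs come out right for genotype and pooled data", {
  g <- matrix(c(0L, 1L, 2L, 0L, 0L, 0L), nrow = 1,
              dimnames = list("v", sprintf("i%d", 1:6)))
  ph <- setNames(c(1L, 1L, 1L, 0L, 0L, 0L), colnames(g))
  coh <- structure(list(genotypes = g, phenotype = ph), class = "cohort")
  maf <- maf_by_group(coh)
  expect_equal(maf$maf_cases, 0.5)   # 3 alt alleles / 6
  expect_equal(maf$maf_controls, 0)

  # two equal-size pools with AF 0.1 and 0.3 -> group AF 0.2
  pa <- structure(list(
    af = matrix(c(0.1, 0.3), nrow = 1,
                dimnames = list("v", c("p1", "p2"))),
    pools = tibble::tibble(pool = c("p1", "p2"), phenotype = c(1L, 1L),
                           size = c(10L, 10L), depth = Inf)
  ), class = "pool_af")
  pa$pools <- dplyr::bind_rows(pa$pools,
                               tibble::tibble(pool = "p3", phenotype = 0L,
                                              size = 10L, depth = Inf))
  pa$af <- cbind(pa$af, p3 = 0.05)
  expect_equal(maf_by_group(pa)$maf_cases, 0.2)

  # simulated cohort: estimate within 4 binomial SD of configured MAF
  em <- tibble::tibble(gene = 1, variant = 1, maf_case = 0.05,
                       maf_control = 0.05)
  coh2 <- simulate_cohort(sim_config(n_cases = 2500, n_controls = 2500,
                                     n_genes = 1, variants_per_gene = 2,
                                     effect_model = em, seed = 31))
  est <- maf_by_group(coh2)$maf_cases[1]
  expect_lt(abs(est - 0.05), 4 * sqrt(0.05 * 0.95 / 5000))
})

test_that("count reconstruction rounds half up", {
  expect_equal(reconstruct_counts(0.012, 450)$minor, 11L)  # round(10.8)
  expect_equal(reconstruct_counts(0.001, 500)$minor, 1L)
  expect_equal(reconstruct_counts(0.050, 450)$minor, 45L)
  expect_equal(reconstruct_counts(0.012, 450)$major, 889L)
})

test_that("allelic Fisher matches enumeration oracle and known values", {
  # identical proportions -> 1; balanced 3/3 diagonal -> 2/20 = 0.1
  expect_equal(allelic_fisher(matrix(c(5, 5, 5, 5), 2, byrow = TRUE)), 1)
  expect_equal(allelic_fisher(matrix(c(3, 0, 0, 3), 2, byrow = TRUE)), 0.1,
               tolerance = 1e-12)

  # 500 random tables with margins <= 60: equality with the lgamma oracle
  set.seed(41)
  for (i in 1:500) {
    tab <- matrix(rpois(4, sample(1:15, 1)), 2)
    if (any(rowSums(tab) == 0)) tab <- tab + 1
    expect_equal(allelic_fisher(tab), oracle_fisher_2x2(tab),
                 tolerance = 1e-12)
  }

  # cross-check against the standard implementation on a handful
  set.seed(42)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    expect_equal(allelic_fisher(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }

  expect_error(allelic_fisher(matrix(c(0, 0, 3, 3), 2, byrow = TRUE)),
               class = "centiskat_validation_error")
})

test_that("allelic Fisher is invariant to row and column swaps", {
  set.seed(43)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    p <- allelic_fisher(tab)
    expect_equal(allelic_fisher(tab[2:1, ]), p, tolerance = 1e-12)
    expect_equal(allelic_fisher(tab[, 2:1]), p, tolerance = 1e-12)
  }
})

test_that("p is monotone non-increasing outward along the support", {
  # fixed margins: moving the observed table away from expectation
  r1 <- 30; r2 <- 40; c1 <- 20
  expectation <- r1 * c1 / (r1 + r2)
  support <- max(0, c1 - r2):min(c1, r1)
  upper <- support[support >= expectation]
  ps <- vapply(upper, function(a) {
    allelic_fisher(matrix(c(a, r1 - a, c1 - a, r2 - c1 + a), 2,
                          byrow = TRUE))
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("genotypic Fisher agrees with collapse and reference oracles", {
  # identical genotype distributions -> 1
  tab <- matrix(c(5, 3, 2, 5, 3, 2), 2, byrow = TRUE)
  expect_equal(genotypic_fisher(tab), 1, tolerance = 1e-9)

  # extreme table equals the standard exact network algorithm
  tab2 <- matrix(c(10, 0, 0, 0, 0, 10), 2, byrow = TRUE)
  expect_equal(genotypic_fisher(tab2), fisher.test(tab2)$p.value,
               tolerance = 1e-9)
  set.seed(44)
  for (i in 1:20) {
    t3 <- matrix(rpois(6, 5), 2, byrow = TRUE)
    if (any(rowSums(t3) == 0)) t3 <- t3 + 1
    expect_equal(genotypic_fisher(t3), fisher.test(t3)$p.value,
                 tolerance = 1e-7)
  }

  # one empty genotype class in both groups collapses to the 2x2 test
  t4 <- matrix(c(8, 4, 0, 3, 9, 0), 2, byrow = TRUE)
  expect_equal(genotypic_fisher(t4),
               allelic_fisher(t4[, 1:2]), tolerance = 1e-12)

  expect_error(genotypic_fisher(matrix(c(0, 0, 0, 1, 2, 3), 2, byrow = TRUE)),
               class = "centiskat_validation_error")
})

test_that("LD r2 behaves on duplicates, independence and degenerate input", {
  set.seed(45)
  g <- rbinom(200, 2, 0.3)
  expect_equal(ld_r2(g, g), 1)
  expect_equal(ld_r2(g, 2L - g), 1)  # relabeling 0<->2 leaves r2 at 1
  g2 <- rbinom(10000, 2, 0.3)
  g3 <- rbinom(10000, 2, 0.3)
  expect_lt(ld_r2(g2, g3), 0.01)
  expect_equal(ld_r2(g2, g3), ld_r2(g3, g2))
  expect_true(is.na(ld_r2(rep(0L, 50), rbinom(50, 2, 0.3))))
})

test_that("the single-variant scan sets directions and calibrates under the null", {
  coh <- null_cohort(n_cases = 250, n_controls = 250, n_genes = 10,
                     variants_per_gene = 20, seed = 46)
  scan <- single_variant_scan(coh)
  expect_equal(nrow(scan), nrow(coh$variants))
  up <- scan$maf_cases > scan$maf_controls
  expect_true(all(scan$direction[up] == "case-enriched"))
  expect_true(all(scan$direction[scan$maf_cases == scan$maf_controls] ==
                    "equal"))

  # null calibration: Fisher is conservative for sparse tables, so test on
  # the commoner variants where the exact test has resolution
  common <- !is.na(scan$p_allelic) & pmin(scan$maf_cases +
    scan$maf_controls, 2 - scan$maf_cases - scan$maf_controls) / 2 > 0.05
  frac <- mean(scan$p_allelic[common] < 0.05)
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / sum(common)))
})

test_that("pooled scans reconstruct Fisher tables from group MAFs", {
  coh <- null_cohort(n_cases = 100, n_controls = 100, seed = 47)
  pa <- pool_cohort(coh, plan = pooling_plan(coh$phenotype, pool_size = 50,
                                             depth = Inf))
  scan <- single_variant_scan(pa)
  maf <- maf_by_group(pa)
  j <- which.max(abs(maf$maf_cases - maf$maf_controls))
  cc <- reconstruct_counts(maf$maf_cases[j], 100)
  kk <- reconstruct_counts(maf$maf_controls[j], 100)
  expect_equal(scan$p_allelic[j],
               allelic_fisher(rbind(as.matrix(cc), as.matrix(kk))))
})
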
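test_that("graph construction drops self-loops and merges duplicates", {
  edges <- tibble::tibble(from = c("A", "A", "B", "A"),
                          to   = c("A", "B", "A", "C"))
  g <- build_graph(edges)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)  # (A,A) dropped; (A,B)=(B,A) merged

  fx <- read_table(system.file("extdata", "ppi_edges.tsv",
                               package = "centiskat"), "edges")
  gf <- build_graph(fx)
  expect_equal(igraph::vcount(gf), 10)
  expect_equal(igraph::ecount(gf), 11)  # 12 lines, one self-loop
})

test_that("seed distances are breadth-first lengths with infinities", {
  # path graph A-b-C plus isolated D
  g <- build_graph(tibble::tibble(from = c("A", "b", "D"),
                                  to = c("b", "C", "E")))
  D <- suppressWarnings(seed_distances(g, c("A", "C", "D", "missing")))
  expect_equal(D["A", "C"], 2)
  expect_equal(D["A", "A"], 0)
  expect_true(is.infinite(D["A", "D"]))
  expect_equal(attr(D, "missing_seeds"), "missing")
  expect_error(seed_distances(g, c("x", "y")),
               class = "centiskat_validation_error")

  # random graphs: agree with a matrix-power all-pairs oracle
  set.seed(101)
  for (rep in 1:20) {
    edges <- random_edges(sample(4:9, 1), 0.4)
    if (nrow(edges) < 2) next
    g <- build_graph(edges)
    nodes <- igraph::V(g)$name
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    # multiply adjacency powers to find first reach
    Dref <- matrix(Inf, length(nodes), length(nodes),
                   dimnames = list(nodes, nodes))
    diag(Dref) <- 0
    Pw <- diag(length(nodes))
    for (l in seq_len(length(nodes))) {
      Pw <- Pw %*% A
      Dref[Pw > 0 & !is.finite(Dref)] <- l
    }
    D <- seed_distances(g, nodes)
    expect_equal(matrix(D, nrow(D)),
                 matrix(Dref[rownames(D), colnames(D)], nrow(D)))
  }
})

test_that("the inclusion cutoff is the per-seed nearest-partner maximum", {
  # all pairwise adjacent -> L* = 1
  g1 <- build_graph(tibble::tibble(from = c("A", "A", "B"),
                                   to = c("B", "C", "C")))
  expect_equal(as.integer(inclusion_cutoff(seed_distances(g1, c("A", "B", "C")))), 1L)

  # path A-b-C-d-E, seeds {A,C,E}: pairwise 2,2,4 -> L* = 2
  g2 <- build_graph(tibble::tibble(from = c("A", "b", "C", "d"),
                                   to = c("b", "C", "d", "E")))
  D2 <- seed_distances(g2, c("A", "C", "E"))
  expect_equal(as.integer(inclusion_cutoff(D2)), 2L)
  expect_equal(as.integer(inclusion_cutoff(D2, mode = "max-pairwise")), 4L)

  # two 2-seed clusters at distance 5, within-cluster distance 1 -> L* = 1
  g3 <- build_graph(tibble::tibble(
    from = c("A", "C", "A", "x1", "x2", "x3", "x4"),
    to   = c("B", "D", "x1", "x2", "x3", "x4", "C")))
  D3 <- seed_distances(g3, c("A", "B", "C", "D"))
  expect_equal(as.integer(inclusion_cutoff(D3)), 1L)

  expect_error(inclusion_cutoff(matrix(0, 1, 1)),
               class = "centiskat_validation_error")
})

test_that("subnetworks keep all tied shortest paths and drop the rest", {
  # diamond: two equal shortest paths between A and D, both retained
  g <- build_graph(tibble::tibble(from = c("A", "A", "B", "C"),
                                  to = c("B", "C", "D", "D")))
  net <- extract_subnetwork(g, c("A", "D"))
  expect_setequal(net$nodes, c("A", "B", "C", "D"))
  expect_equal(nrow(net$edges), 4)

  # two adjacent seeds: the subnetwork is that single edge
  g2 <- build_graph(tibble::tibble(from = c("A", "B"), to = c("B", "C")))
  net2 <- extract_subnetwork(g2, c("A", "B"))
  expect_setequal(net2$nodes, c("A", "B"))
  expect_equal(nrow(net2$edges), 1)
})

test_that("subnetwork equals the exhaustive path-enumeration oracle", {
  set.seed(102)
  tested <- 0
  while (tested < 200) {
    edges <- random_edges(sample(5:10, 1), runif(1, 0.25, 0.6))
    if (nrow(edges) < 3) next
    g <- build_graph(edges)
    nodes <- igraph::V(g)$name
    if (length(nodes) < 3) next
    seeds <- sample(nodes, 3)
    ref <- oracle_subnetwork(edges, seeds)
    if (is.null(ref)) {
      expect_error(suppressWarnings(extract_subnetwork(g, seeds)),
                   class = "centiskat_validation_error")
      tested <- tested + 1
      next
    }
    net <- suppressWarnings(extract_subnetwork(g, seeds))
    expect_equal(net$nodes, ref$nodes)
    expect_equal(as.data.frame(net$edges), ref$edges)
    expect_equal(net$cutoff, ref$cutoff)
    tested <- tested + 1
  }
})

test_that("subnetworks are seed-order invariant and monotone in the cutoff", {
  set.seed(103)
  for (rep in 1:20) {
    edges <- random_edges(8, 0.45)
    if (nrow(edges) < 4) next
    g <- build_graph(edges)
    nodes <- igraph::V(g)$name
    if (length(nodes) < 4) next
    seeds <- sample(nodes, 3)
    n1 <- tryCatch(suppressWarnings(extract_subnetwork(g, seeds)),
                   error = function(e) NULL)
    if (is.null(n1)) next
    n2 <- suppressWarnings(extract_subnetwork(g, rev(seeds)))
    expect_equal(n1$nodes, n2$nodes)
    expect_equal(n1$edges, n2$edges)
    # max-pairwise cutoff >= nearest-partner cutoff, and only adds paths
    n3 <- suppressWarnings(extract_subnetwork(g, seeds,
                                              mode = "max-pairwise"))
    expect_true(all(n1$nodes %in% n3$nodes))
  }
})

test_that("retained non-seed nodes are path interiors", {
  set.seed(104)
  for (rep in 1:20) {
    edges <- random_edges(9, 0.35)
    if (nrow(edges) < 4) next
    g <- build_graph(edges)
    nodes <- igraph::V(g)$name
    if (length(nodes) < 4) next
    seeds <- sample(nodes, 3)
    net <- tryCatch(suppressWarnings(extract_subnetwork(g, seeds)),
                    error = function(e) NULL)
    if (is.null(net) || nrow(net$edges) == 0) next
    deg <- table(c(net$edges$from, net$edges$to))
    interior <- setdiff(net$nodes, net$seeds)
    for (v in interior) expect_gte(deg[[v]], 2)
  }
})

test_that("subnetwork export writes nodes, edges and GraphML", {
  g <- build_graph(tibble::tibble(from = c("A", "B"), to = c("B", "C")))
  net <- extract_subnetwork(g, c("A", "C"))
  dir <- withr::local_tempdir()
  paths <- export_subnetwork(net, dir)
  expect_true(all(file.exists(paths)))
  expect_match(readLines(paths[3], n = 2)[2], "graphml")
})
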
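# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: probabilities come from lgamma-based closed forms
# or brute-force enumeration, never from the functions under test.

# Exact two-sided Fisher p for a 2x2 table by direct enumeration with
# log-factorial hypergeometric probabilities.
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lp <- function(x) {
    lgamma(r1 + 1) - lgamma(x + 1) - lgamma(r1 - x + 1) +
      lgamma(r2 + 1) - lgamma(c1 - x + 1) - lgamma(r2 - c1 + x + 1) -
      (lgamma(n + 1) - lgamma(c1 + 1) - lgamma(n - c1 + 1))
  }
  support <- max(0, c1 - r2):min(c1, r1)
  logs <- vapply(support, lp, numeric(1))
  obs <- lp(a)
  sum(exp(logs[logs <= obs + 1e-7]))
}

# Upper hypergeometric tail by explicit term-by-term summation.
oracle_hyper_tail <- function(k, K, N, m) {
  js <- k:min(m, K)
  if (!length(js) || k > min(m, K)) return(if (k <= 0) 1 else 0)
  sum(exp(lchoose(K, js) + lchoose(N - K, m - js) - lchoose(N, m)))
}

# All simple paths between two nodes of an undirected graph given as an
# edge list (data frame from/to). Pure R depth-first search.
oracle_simple_paths <- function(edges, from, to) {
  adj <- list()
  adde <- function(a, b) adj[[a]] <<- union(adj[[a]] %||% character(), b)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    if (a == b) next
    adde(a, b); adde(b, a)
  }
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == to) { out[[length(out) + 1L]] <<- path; return() }
    for (nb in adj[[last]] %||% character()) {
      if (!nb %in% path) walk(c(path, nb))
    }
  }
  if (!is.null(adj[[from]])) walk(from)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reference subnetwork by exhaustive enumeration: all simple paths between
# every seed pair, keep only those of minimal length for the pair, apply the
# nearest-partner cutoff rule, union nodes/edges.
oracle_subnetwork <- function(edges, seeds) {
  pairs <- utils::combn(sort(seeds), 2)
  dist <- matrix(Inf, length(seeds), length(seeds),
                 dimnames = list(sort(seeds), sort(seeds)))
  shortest <- list()
  for (j in seq_len(ncol(pairs))) {
    s <- pairs[1, j]; t <- pairs[2, j]
    paths <- oracle_simple_paths(edges, s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1)) - 1L
    dmin <- min(lens)
    dist[s, t] <- dist[t, s] <- dmin
    shortest[[paste(s, t)]] <- paths[lens == dmin]
  }
  D <- dist; diag(D) <- Inf
  nearest <- apply(D, 1, min)
  reachable <- rownames(D)[is.finite(nearest)]
  if (length(reachable) < 2) return(NULL)
  lstar <- max(apply(D[reachable, reachable, drop = FALSE], 1, min))
  nodes <- character(); ef <- character(); et <- character()
  for (j in seq_len(ncol(pairs))) {
    s <- pairs[1, j]; t <- pairs[2, j]
    if (!s %in% reachable || !t %in% reachable) next
    if (!is.finite(dist[s, t]) || dist[s, t] > lstar) next
    for (p in shortest[[paste(s, t)]]) {
      nodes <- c(nodes, p)
      if (length(p) > 1) {
        a <- p[-length(p)]; b <- p[-1]
        ef <- c(ef, pmin(a, b)); et <- c(et, pmax(a, b))
      }
    }
  }
  ed <- unique(data.frame(from = ef, to = et, stringsAsFactors = FALSE))
  ed <- ed[order(ed$from, ed$to), , drop = FALSE]
  rownames(ed) <- NULL
  list(nodes = sort(unique(nodes)), edges = ed, cutoff = as.integer(lstar))
}

# Random small graph edge list for subnetwork property tests.
random_edges <- function(n_nodes, p_edge) {
  nodes <- LETTERS[seq_len(n_nodes)]
  cmb <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(cmb)) < p_edge
  data.frame(from = cmb[1, keep], to = cmb[2, keep],
             stringsAsFactors = FALSE)
}

# Small null cohort builder shared by the association tests.
null_cohort <- function(n_cases = 100, n_controls = 100, n_genes = 1,
                        variants_per_gene = 20, seed = 1) {
  simulate_cohort(sim_config(
    n_cases = n_cases, n_controls = n_controls, n_genes = n_genes,
    variants_per_gene = variants_per_gene, seed = seed))
}
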
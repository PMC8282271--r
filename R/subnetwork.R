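#' Build a background protein-protein interaction graph
#'
#' Undirected simple graph from a two-column edge list: self-interactions
#' are ignored and duplicate edges (in either orientation) merged.
#'
#' @param edges data frame with columns `from` and `to` (extra columns
#'   dropped).
#' @return an undirected simple `igraph` graph.
#' @export
build_graph <- function(edges) {
  edges <- as_tibble(edges)
  if (nrow(edges) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    edges[c("from", "to")], directed = FALSE)
  igraph::simplify(g, remove.loops = TRUE, remove.multiple = TRUE)
}

#' Pairwise shortest-path distances between seed genes
#'
#' Unweighted (breadth-first) shortest-path lengths between every pair of
#' seeds. Seeds absent from the graph are reported and excluded; unreachable
#' pairs are `Inf`.
#'
#' @param graph an `igraph` graph.
#' @param seeds character vector of seed node names.
#' @return numeric matrix of distances over the present seeds, with
#'   attribute `missing_seeds`.
#' @export
seed_distances <- function(graph, seeds) {
  seeds <- unique(seeds)
  present <- intersect(seeds, igraph::V(graph)$name)
  missing <- setdiff(seeds, present)
  if (!length(present)) {
    stop_validation("none of the seeds are present in the graph")
  }
  if (length(missing)) {
    warn(paste0("seed(s) not in graph, excluded: ",
                paste(missing, collapse = ", ")))
  }
  D <- igraph::distances(graph, v = present, to = present)
  attr(D, "missing_seeds") <- missing
  D
}

#' Adaptive path-length inclusion cutoff
#'
#' The smallest shortest-path length `L*` at which every (reachable) seed
#' joins the subnetwork: for each seed, take its distance to the nearest
#' other seed; `L*` is the maximum of those nearest-partner distances.
#' Seeds unreachable from every other seed are excluded and reported.
#' The alternative reading — the maximum over all pairwise seed distances —
#' is available via `mode = "max-pairwise"`.
#'
#' @param distances square seed-distance matrix from [seed_distances()].
#' @param mode `"nearest-partner"` (default) or `"max-pairwise"`.
#' @return integer `L*` with attribute `excluded_seeds`.
#' @export
inclusion_cutoff <- function(distances,
                             mode = c("nearest-partner", "max-pairwise")) {
  mode <- match.arg(mode)
  D <- as.matrix(distances)
  diag(D) <- Inf
  nearest <- apply(D, 1, min)
  reachable <- is.finite(nearest)
  if (sum(reachable) < 2) {
    stop_validation("fewer than two seeds are mutually reachable")
  }
  Dr <- D[reachable, reachable, drop = FALSE]
  lstar <- if (mode == "nearest-partner") {
    max(apply(Dr, 1, min))
  } else {
    max(Dr[is.finite(Dr)])
  }
  structure(as.integer(lstar),
            excluded_seeds = rownames(D)[!reachable])
}

#' Extract the seed subnetwork by the all-shortest-paths rule
#'
#' The subnetwork is the union of ALL shortest paths between every pair of
#' (reachable) seeds whose distance does not exceed the adaptive cutoff
#' `L*` from [inclusion_cutoff()]; when two or more equally short paths
#' connect a pair, all of them are retained. Nodes and edges on no retained
#' path are excluded. Output ordering is deterministic (sorted node names,
#' sorted edge endpoint pairs).
#'
#' @param graph an `igraph` graph.
#' @param seeds character vector of seed node names.
#' @param mode cutoff mode passed to [inclusion_cutoff()].
#' @return object of class `subnetwork`: list with `seeds` (present),
#'   `nodes`, `edges` (tibble from/to), `distances`, `cutoff`,
#'   `excluded_seeds` (unreachable or absent).
#' @export
extract_subnetwork <- function(graph, seeds,
                               mode = c("nearest-partner", "max-pairwise")) {
  mode <- match.arg(mode)
  D <- seed_distances(graph, seeds)
  lstar <- inclusion_cutoff(D, mode)
  excluded <- c(attr(D, "missing_seeds"), attr(lstar, "excluded_seeds"))
  use <- setdiff(rownames(D), excluded)

  nodes <- character()
  edge_from <- character(); edge_to <- character()
  if (length(use) >= 2) {
    pairs <- utils::combn(sort(use), 2)
    for (j in seq_len(ncol(pairs))) {
      s <- pairs[1, j]; t <- pairs[2, j]
      if (!is.finite(D[s, t]) || D[s, t] > lstar) next
      asp <- igraph::all_shortest_paths(graph, from = s, to = t)$vpaths
      for (pth in asp) {
        nm <- igraph::V(graph)$name[as.integer(pth)]
        nodes <- c(nodes, nm)
        if (length(nm) > 1) {
          a <- nm[-length(nm)]; b <- nm[-1]
          lo <- pmin(a, b); hi <- pmax(a, b)
          edge_from <- c(edge_from, lo); edge_to <- c(edge_to, hi)
        }
      }
    }
  }
  edges <- distinct(tibble(from = edge_from, to = edge_to)) %>%
    arrange(.data$from, .data$to)
  structure(
    list(
      seeds = sort(use),
      nodes = sort(unique(nodes)),
      edges = edges,
      distances = D,
      cutoff = as.integer(lstar),
      excluded_seeds = sort(unique(excluded))
    ),
    class = "subnetwork"
  )
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf(
    "<subnetwork> %d seeds, %d nodes, %d edges, cutoff L* = %d%s\n",
    length(x$seeds), length(x$nodes), nrow(x$edges), x$cutoff,
    if (length(x$excluded_seeds))
      paste0(" (excluded: ", paste(x$excluded_seeds, collapse = ", "), ")")
    else ""))
  invisible(x)
}

#' Tidy a subnetwork into a node table
#' @param x a `subnetwork`.
#' @param ... unused.
#' @return tibble with `node` and `is_seed`.
#' @method tidy subnetwork
#' @export
tidy.subnetwork <- function(x, ...) {
  tibble(node = x$nodes, is_seed = x$nodes %in% x$seeds)
}

#' Write a subnetwork as node/edge TSVs and GraphML
#'
#' @param x a `subnetwork`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return character vector of written paths, invisibly.
#' @export
export_subnetwork <- function(x, dir, stem = "subnetwork") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  node_path <- file.path(dir, paste0(stem, "_nodes.tsv"))
  edge_path <- file.path(dir, paste0(stem, "_edges.tsv"))
  gml_path <- file.path(dir, paste0(stem, ".graphml"))
  readr::write_tsv(tidy(x), node_path, progress = FALSE)
  readr::write_tsv(x$edges, edge_path, progress = FALSE)
  g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                     vertices = tidy(x))
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(node_path, edge_path, gml_path))
}
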
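## Directed-graph complexity measures and pairwise edge overlap for comparing
## learned rule graphs across algorithms and dataset sizes.

#' Six complexity measures of a directed rule graph
#'
#' Computes the number of nodes, number of edges (self-loops included),
#' density `E / (n (n - 1))`, average clustering coefficient, number of
#' strongly connected components, and flow hierarchy (the fraction of edges
#' not lying on any directed cycle; an edge u -> v lies on a cycle exactly
#' when u and v share a strongly connected component, self-loops counting as
#' cyclic). For graphs with at most one node, density, clustering and flow
#' hierarchy are defined as 0.
#'
#' The default clustering coefficient is the directed all-triangle
#' generalization (Fagiolo): per node, the count of directed triangles in any
#' orientation through the node over the number of possible such triangles
#' `d_tot (d_tot - 1) - 2 d_bidir`, averaged over nodes (self-loops are
#' ignored for clustering). `clustering = "undirected"` instead averages the
#' local clustering of the underlying undirected simple graph.
#'
#' @param graph a [RuleGraph-class] (may be empty).
#' @param clustering `"directed"` (default) or `"undirected"`.
#' @return One-row data.frame with columns `n_nodes`, `n_edges`, `density`,
#'   `avg_clustering`, `n_scc`, `flow_hierarchy`.
#' @export
graphComplexity <- function(graph, clustering = c("directed", "undirected")) {
  clustering <- match.arg(clustering)
  ed <- graph@edges
  n <- nrow(graph@nodes)
  m <- nrow(ed)
  if (n == 0L || m == 0L) {
    return(data.frame(n_nodes = n, n_edges = m, density = 0,
                      avg_clustering = 0, n_scc = as.integer(n),
                      flow_hierarchy = 0))
  }
  ids <- as.character(graph@nodes$concept_id)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$antecedent),
               to = as.character(ed$consequent)),
    directed = TRUE, vertices = ids)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  cyclic <- memb[as.character(ed$antecedent)] ==
    memb[as.character(ed$consequent)]
  density <- if (n > 1L) m / (n * (n - 1)) else 0
  flow <- if (n > 1L) 1 - sum(cyclic) / m else 0
  avg_cl <- if (n > 1L) .avgClustering(ed, ids, clustering) else 0
  data.frame(n_nodes = n, n_edges = m, density = density,
             avg_clustering = avg_cl, n_scc = as.integer(comp$no),
             flow_hierarchy = flow)
}

.avgClustering <- function(ed, ids, type) {
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  keep <- ed$antecedent != ed$consequent   # self-loops ignored for clustering
  A[cbind(as.character(ed$antecedent[keep]),
          as.character(ed$consequent[keep]))] <- 1
  if (type == "undirected") {
    U <- pmax(A, t(A))
    deg <- rowSums(U)
    tri <- diag(U %*% U %*% U) / 2
    denom <- deg * (deg - 1) / 2
    return(mean(ifelse(denom > 0, tri / denom, 0)))
  }
  S <- A + t(A)
  dtot <- rowSums(A) + colSums(A)
  dbi <- diag(A %*% A)
  tri <- diag(S %*% S %*% S) / 2
  denom <- 2 * (dtot * (dtot - 1) - 2 * dbi)
  mean(ifelse(denom > 0, 2 * tri / denom, 0))
}

#' Percentage of identical directed edges between two graphs
#'
#' `100 * |E1 intersect E2| / |E1|`, comparing unweighted directed pairs
#' (antecedent, consequent); 0 when `E1` is empty. The measure is asymmetric:
#' it reads "how much of graph 1 is contained in graph 2".
#'
#' @param g1,g2 [RuleGraph-class] objects.
#' @return A percentage in \[0, 100\].
#' @export
edgeOverlap <- function(g1, g2) {
  e1 <- paste(g1@edges$antecedent, g1@edges$consequent)
  if (length(e1) == 0L) return(0)
  e2 <- paste(g2@edges$antecedent, g2@edges$consequent)
  100 * sum(e1 %in% e2) / length(e1)
}

#' Pairwise edge-overlap matrix over a set of graphs
#'
#' Cell (r, c) is [edgeOverlap()] of graph r with respect to graph c: how
#' much of the row graph's edge set appears in the column graph. The diagonal
#' is 100 for non-empty graphs.
#'
#' @param graphs a named list of [RuleGraph-class] objects (names become the
#'   labels; unnamed lists get `graph<k>` labels).
#' @return A square numeric matrix of percentages with the labels as
#'   dimnames.
#' @export
overlapMatrix <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  labs <- names(graphs)
  if (is.null(labs) || any(!nzchar(labs)))
    labs <- paste0("graph", seq_along(graphs))
  m <- matrix(0, length(graphs), length(graphs), dimnames = list(labs, labs))
  for (r in seq_along(graphs))
    for (cc in seq_along(graphs))
      m[r, cc] <- edgeOverlap(graphs[[r]], graphs[[cc]])
  m
}
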
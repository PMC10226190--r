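#' Proportional thresholding of a connectivity matrix
#'
#' Keeps the `round(p_kept * n * (n-1))` largest off-diagonal weights of a
#' directed connectivity matrix (entry `[i, j]` = flow j -> i) and zeroes
#' the rest. Ties at the cut-off break by fixed lexicographic (row, column)
#' order so the operation is deterministic.
#'
#' @param conn `n x n` nonnegative matrix (e.g. a band connectome),
#'   zero diagonal.
#' @param p_kept Proportion of possible edges to keep, in (0, 1).
#' @return Object of class `adjacency_pair`: list with `weighted`
#'   (thresholded weights), `binary` (0/1), `p_kept`, `n_edges`.
#' @export
proportional_threshold <- function(conn, p_kept) {
  conn <- unclass(as.matrix(conn))
  n <- nrow(conn)
  if (!(p_kept > 0 && p_kept < 1)) stop("p_kept must be in (0, 1)")
  off <- which(row(conn) != col(conn))
  if (all(conn[off] == 0)) stop("all-zero connectivity matrix")
  k <- round(p_kept * n * (n - 1))
  ord <- off[order(-conn[off], row(conn)[off], col(conn)[off])]
  keep <- ord[seq_len(k)]
  weighted <- matrix(0, n, n, dimnames = dimnames(conn))
  weighted[keep] <- conn[keep]
  structure(list(weighted = weighted, binary = (weighted > 0) * 1,
                 p_kept = p_kept, n_edges = k),
            class = "adjacency_pair")
}

# global efficiency of a binary digraph: mean over ordered node pairs of
# the inverse shortest-path length (unreachable pairs contribute 0)
global_efficiency <- function(binary) {
  n <- nrow(binary)
  if (n < 2) return(0)
  g <- igraph::graph_from_adjacency_matrix(t(binary), mode = "directed")
  d <- igraph::distances(g, mode = "out")
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Global cost efficiency of a thresholded graph
#'
#' `E_glob - cost`, where `E_glob` is the global efficiency of the binary
#' digraph (mean inverse shortest-path length over ordered pairs,
#' unreachable pairs counting 0) and cost is the edge density
#' `edges / (n (n - 1))`. Used to pick the binarization threshold.
#'
#' @param adj An [proportional_threshold()] result.
#' @return Scalar global cost efficiency.
#' @export
global_cost_efficiency <- function(adj) {
  stopifnot(inherits(adj, "adjacency_pair"))
  n <- nrow(adj$binary)
  global_efficiency(adj$binary) - sum(adj$binary) / (n * (n - 1))
}

#' Threshold selection by maximum global cost efficiency
#'
#' Evaluates [global_cost_efficiency()] over a grid of kept proportions and
#' returns the adjacency at the argmax (ties break toward the smaller
#' proportion).
#'
#' @param conn `n x n` connectivity matrix.
#' @param grid Candidate proportions; default 0.05 to 0.50 in 0.05 steps.
#' @return The selected `adjacency_pair`, with attribute `gce` (its global
#'   cost efficiency) and `gce_grid` (the full profile).
#' @export
select_threshold <- function(conn, grid = seq(0.05, 0.50, by = 0.05)) {
  adjs <- lapply(grid, function(p) proportional_threshold(conn, p))
  gce <- vapply(adjs, global_cost_efficiency, 0)
  best <- which.max(gce)          # first maximum -> smaller p on ties
  out <- adjs[[best]]
  attr(out, "gce") <- gce[best]
  attr(out, "gce_grid") <- stats::setNames(gce, grid)
  out
}

#' Directed node degrees
#'
#' On the binary matrix (row = target): in-degree of node i is the i-th row
#' sum (flows into i), out-degree the i-th column sum, total their sum.
#'
#' @param adj An `adjacency_pair`.
#' @return data.frame with `in_degree`, `out_degree`, `total_degree`.
#' @export
node_degree <- function(adj) {
  stopifnot(inherits(adj, "adjacency_pair"))
  data.frame(in_degree = rowSums(adj$binary),
             out_degree = colSums(adj$binary),
             total_degree = rowSums(adj$binary) + colSums(adj$binary))
}

#' Node strength
#'
#' Sum of thresholded incoming and outgoing edge weights per node.
#'
#' @param adj An `adjacency_pair`.
#' @return Numeric vector of total strengths.
#' @export
node_strength <- function(adj) {
  stopifnot(inherits(adj, "adjacency_pair"))
  rowSums(adj$weighted) + colSums(adj$weighted)
}

# undirected skeleton of the binary digraph
skeleton <- function(adj) ((adj$binary + t(adj$binary)) > 0) * 1

#' Clustering coefficient
#'
#' Per-node clustering `C_i = 2 n_i / (k_i (k_i - 1))` computed on the
#' undirected skeleton of the binarized graph, where `k_i` is the number of
#' distinct neighbors and `n_i` the number of edges among them. Nodes with
#' fewer than two neighbors have `C_i = 0`.
#'
#' @param adj An `adjacency_pair`.
#' @return Numeric vector of per-node clustering coefficients in `[0, 1]`.
#' @export
clustering_coefficient <- function(adj) {
  B <- skeleton(adj)
  vapply(seq_len(nrow(B)), function(i) {
    nb <- which(B[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    ni <- sum(B[nb, nb]) / 2
    2 * ni / (k * (k - 1))
  }, 0)
}

#' Local efficiency
#'
#' Per-node fault tolerance: the global efficiency of the binary subgraph
#' induced by the node's neighbors (the node itself removed). Nodes with
#' fewer than two neighbors score 0.
#'
#' @param adj An `adjacency_pair`.
#' @return Numeric vector of per-node local efficiencies in `[0, 1]`.
#' @export
local_efficiency <- function(adj) {
  B <- skeleton(adj)
  vapply(seq_len(nrow(B)), function(i) {
    nb <- which(B[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(adj$binary[nb, nb, drop = FALSE])
  }, 0)
}

#' Modularity by Louvain community detection
#'
#' Louvain community detection on the symmetrized binarized graph, returning
#' the Newman modularity `Q = (1/L) sum_ij [A_ij - k_i k_j / L]
#' delta(c_i, c_j)` of the found partition (undirected convention; L twice
#' the undirected edge count). The heuristic is made deterministic by a
#' fixed RNG seed.
#'
#' @param adj An `adjacency_pair`.
#' @param seed Integer seed for the Louvain heuristic (default 42).
#' @return List with `Q` (scalar) and `membership` (integer community ids).
#' @export
graph_modularity <- function(adj, seed = 42L) {
  B <- skeleton(adj)
  g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  comm <- with_seed(seed, igraph::cluster_louvain(g))
  list(Q = igraph::modularity(g, igraph::membership(comm)),
       membership = as.integer(igraph::membership(comm)))
}

#' All graph-theory measures of one band connectome
#'
#' Thresholds the connectome by [select_threshold()] and computes the five
#' measures: per-node clustering coefficient, local efficiency, total node
#' degree and node strength (n each) plus the scalar modularity, i.e.
#' `4 n + 1` values per band.
#'
#' @param conn `n x n` band connectome.
#' @param seed Louvain seed (default 42).
#' @param grid Threshold proportion grid for [select_threshold()].
#' @return Object of class `graph_metrics`: list of the per-node vectors,
#'   `modularity`, `membership`, the selected `p_kept`, and `band`
#'   (taken from the connectome's attribute if present).
#' @export
compute_graph_metrics <- function(conn, seed = 42L,
                                  grid = seq(0.05, 0.50, by = 0.05)) {
  adj <- select_threshold(conn, grid)
  deg <- node_degree(adj)
  mod <- graph_modularity(adj, seed)
  structure(list(clustering = clustering_coefficient(adj),
                 local_efficiency = local_efficiency(adj),
                 in_degree = deg$in_degree, out_degree = deg$out_degree,
                 total_degree = deg$total_degree,
                 strength = node_strength(adj),
                 modularity = mod$Q, membership = mod$membership,
                 p_kept = adj$p_kept, seed = as.integer(seed),
                 band = attr(conn, "band")),
            class = "graph_metrics")
}

#' Flatten graph metrics to the canonical feature layout
#'
#' Concatenates clustering coefficients, local efficiencies, total node
#' degrees, node strengths (n values each) and the scalar modularity into
#' one vector of `4 n + 1` values.
#'
#' @param gm A [compute_graph_metrics()] result.
#' @return Named numeric vector of length `4 n + 1`.
#' @export
metrics_vector <- function(gm) {
  stopifnot(inherits(gm, "graph_metrics"))
  n <- length(gm$clustering)
  stats::setNames(
    c(gm$clustering, gm$local_efficiency, gm$total_degree, gm$strength,
      gm$modularity),
    c(sprintf("cc_%02d", 1:n), sprintf("le_%02d", 1:n),
      sprintf("nd_%02d", 1:n), sprintf("ns_%02d", 1:n), "modularity"))
}
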